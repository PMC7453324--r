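#' Load a statistician-provided randomization table
#'
#' The engine never generates allocation sequences; it consumes a preloaded
#' table in strict order. CSV columns: `sequence_no` (strictly increasing
#' from 1, no gaps), `color_group` (must appear in the study's
#' color-to-arm map), and optionally `midline_visit` (the visit designated
#' for midline serial sampling, blank when none). The color-to-arm map
#' comes from the compiled definition's randomization config, keeping the
#' arm concealed from the table handled by field staff.
#'
#' @param path CSV file path (or a data frame with the same columns).
#' @param defn compiled study definition with a randomization config.
#' @return an `edc_rand_table`.
#' @export
loadRandomizationTable <- function(path, defn) {
  if (is.null(defn$randomization)) {
    edcStop("edc_definition_error", "study has no randomization config")
  }
  df <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.csv(path, colClasses = "character", na.strings = character(0))
  }
  n <- nrow(df)
  rows <- list()
  if (n > 0) {
    seqs <- as.integer(df$sequence_no)
    if (anyNA(seqs) || any(seqs != seq_len(n))) {
      edcStop("edc_table_error",
              "sequence_no must be exactly 1..%d with no gaps or duplicates", n)
    }
    colors <- as.character(df$color_group)
    unknown <- setdiff(unique(colors), names(defn$randomization$color_to_arm))
    if (length(unknown) > 0) {
      edcStop("edc_mapping_error", "color group(s) not in the color-to-arm map: %s",
              paste(unknown, collapse = ", "))
    }
    midline <- if ("midline_visit" %in% names(df)) {
      as.character(df$midline_visit)
    } else {
      rep("", n)
    }
    bad_visits <- setdiff(setdiff(unique(midline), ""), names(defn$visits))
    if (length(bad_visits) > 0) {
      edcStop("edc_definition_error", "midline_visit names unknown visit(s): %s",
              paste(bad_visits, collapse = ", "))
    }
    rows <- lapply(seq_len(n), function(i) {
      list(sequence_no = i, color_group = colors[[i]],
           midline_visit = if (nzchar(midline[[i]])) midline[[i]] else NULL)
    })
  }
  structure(list(rows = rows, n = n,
                 color_to_arm = defn$randomization$color_to_arm,
                 blocks = NULL),
            class = "edc_rand_table")
}

#' @export
print.edc_rand_table <- function(x, ...) {
  cat(sprintf("<edc_rand_table> %d row(s), %d color group(s) -> %d arm(s)%s\n",
              x$n, length(unique(vapply(x$rows, function(r) r$color_group, character(1)))),
              length(unique(unlist(x$color_to_arm))),
              if (is.null(x$blocks)) "" else sprintf(", %d device block(s)", length(x$blocks))))
  invisible(x)
}

#' Pre-partition table rows into per-device blocks
#'
#' Offline devices cannot coordinate row consumption; assigning disjoint
#' blocks of consecutive rows to each device up front makes concurrent
#' offline allocation conflict-free by construction. Blocks are dealt
#' round-robin so early enrollment draws evenly from the sequence.
#'
#' @param table an `edc_rand_table`.
#' @param device_codes character vector of allocating devices.
#' @param block_size rows per block.
#' @return the table with a `blocks` map (device -> sequence numbers).
#' @export
assignDeviceBlocks <- function(table, device_codes, block_size = 4) {
  stopifnot(inherits(table, "edc_rand_table"))
  blocks <- stats::setNames(vector("list", length(device_codes)), device_codes)
  i <- 1L; d <- 1L
  while (i <= table$n) {
    take <- seq(i, min(i + block_size - 1L, table$n))
    dev <- device_codes[[d]]
    blocks[[dev]] <- c(blocks[[dev]], take)
    i <- i + block_size
    d <- if (d == length(device_codes)) 1L else d + 1L
  }
  table$blocks <- blocks
  table
}

consumedSequences <- function(store) {
  vapply(store$state$allocations, function(a) a$sequence_no, integer(1))
}

#' Allocate the next randomization row to an eligible participant
#'
#' Consumes the next unconsumed row in table order (within the store's
#' device block when blocks are assigned). Preconditions: the participant
#' is eligible, the routed blocking consent forms are signed, the table has
#' capacity, and the participant has no prior allocation. The allocation is
#' immutable once written; when the study's id scheme carries a
#' group-letter component, the participant's final enrollment id
#' (registration id + color letter) is set here and the participant becomes
#' enrolled.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param table an `edc_rand_table`.
#' @param session session with `enter-data` privilege.
#' @param pid participant id.
#' @return the allocation record.
#' @export
allocateParticipant <- function(store, defn, table, session, pid) {
  requirePrivilege(store, session, "enter-data")
  p <- store$state$participants[[pid]]
  if (is.null(p)) edcStop("edc_reference_error", "unknown participant '%s'", pid)
  elig <- store$state$eligibility[[pid]]$overall %||% "pending"
  if (!identical(elig, "eligible") && !identical(p$status, "eligible")) {
    edcStop("edc_state_error",
            "participant '%s' is %s, not eligible; cannot allocate", pid, elig)
  }
  if (!consentSatisfied(store, defn, pid)) {
    edcStop("edc_state_error",
            "required consent form(s) are not signed for '%s'", pid)
  }
  if (!is.null(store$state$allocations[[pid]])) {
    edcStop("edc_duplication_error", "participant '%s' is already allocated", pid)
  }
  used <- consumedSequences(store)
  pool <- if (!is.null(table$blocks)) {
    table$blocks[[store$device_code]] %||% integer(0)
  } else {
    seq_len(table$n)
  }
  avail <- setdiff(pool, used)
  if (length(avail) == 0) {
    edcStop("edc_capacity_error", "randomization table exhausted (%d row(s))", table$n)
  }
  row <- table$rows[[min(avail)]]
  arm <- table$color_to_arm[[row$color_group]]
  alloc <- list(participant = pid,
                sequence_no = row$sequence_no,
                color_group = row$color_group,
                arm = arm,
                midline_visit = row$midline_visit,
                allocated_at = formatTs(store$clock()))
  recordChange(store, "allocations", pid, "__init__", alloc,
               username = session$username, meta = list(participant = pid))
  if (idSchemeHasGroupLetter(defn$id_scheme$participant)) {
    eid <- generateParticipantId(defn, p$device_code, p$id_seq,
                                 allocation = alloc)
    recordChange(store, "participants", pid, "enrollment_id", eid,
                 session$username, meta = list(participant = pid))
  }
  if (identical(p$status, "eligible")) {
    setParticipantStatus(store, pid, "enrolled", session$username)
  }
  if (!is.null(alloc$midline_visit) && isTRUE(defn$randomization$midline_sampling)) {
    designateMidlineCrfs(store, defn, session, pid, alloc)
  }
  alloc
}

#' Instantiate midline-designated CRFs at the allocated midline visit
#'
#' Every schedule cell with mode `midline` at the allocation's designated
#' visit gains a CRF instance; no other visit gains any.
#'
#' @inheritParams allocateParticipant
#' @param allocation the participant's allocation (defaults to the stored
#'   one).
#' @return character vector of created instance keys.
#' @export
designateMidlineCrfs <- function(store, defn, session, pid,
                                 allocation = store$state$allocations[[pid]]) {
  if (is.null(allocation) || is.null(allocation$midline_visit)) {
    return(character(0))
  }
  vid <- allocation$midline_visit
  if (!vid %in% unlist(defn$visit_order)) {
    edcStop("edc_definition_error",
            "midline visit '%s' is not a scheduled visit", vid)
  }
  created <- character(0)
  for (cell in defn$schedule) {
    if (identical(cell$mode, "midline") && identical(cell$visit_id, vid)) {
      existing <- Filter(function(i) identical(i$origin$kind, "midline-designated"),
                         crfInstancesFor(store, pid, vid, cell$crf_id))
      if (length(existing) == 0) {
        created <- c(created,
                     createCrfInstance(store, defn, pid, vid, cell$crf_id,
                                       list(kind = "midline-designated"),
                                       session$username))
      }
    }
  }
  created
}

#' Seeded permuted-block sequence generator (testing aid)
#'
#' NOT a production randomization procedure: real studies load a
#' statistician-generated table. This generator exists so fixtures and
#' simulations can build tables with known composition. Blocks are
#' permuted so each block contains every color group `block_size /
#' n_colors` times.
#'
#' @param n number of rows.
#' @param colors character vector of color groups.
#' @param midline_visits optional pool of visit ids to designate for
#'   midline serial sampling (one drawn per row), or `NULL`.
#' @param block_size permuted block size (multiple of `length(colors)`).
#' @param seed RNG seed.
#' @return data frame with columns `sequence_no`, `color_group`,
#'   `midline_visit`.
#' @export
makePermutedBlockTable <- function(n, colors, midline_visits = NULL,
                                   block_size = 2 * length(colors),
                                   seed = 1) {
  if (block_size %% length(colors) != 0) {
    edcStop("edc_definition_error",
            "block_size must be a multiple of the number of colors")
  }
  out <- character(0)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    while (length(out) < n) {
      block <- sample(rep(colors, block_size / length(colors)))
      out <- c(out, block)
    }
    out <- out[seq_len(n)]
    mid <- if (is.null(midline_visits)) {
      rep("", n)
    } else {
      sample(midline_visits, n, replace = TRUE)
    }
    data.frame(sequence_no = seq_len(n), color_group = out,
               midline_visit = mid, stringsAsFactors = FALSE)
  })
}
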