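---
title: "How the edcflow engine enforces a study protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the edcflow engine enforces a study protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcflow)
```

Electronic data capture for field epidemiology has to do two jobs at
once: collect data offline on many devices, and make protocol violations
impossible rather than merely detectable. This vignette explains the
model behind `edcflow` — what is declared, what is enforced, which
conventions and tie-breaks the engine fixes, and what the shipped test
fixtures do and do not demonstrate.

## Protocols as data

A study is a workbook of tabular sheets (CSV canonically; XLSX via
`readxl`): `dictionary`, `forms`, `visits`, `schedule`, `criteria`,
`triggers`, `consent`, `ids`, `validation`, `randomization_config`,
`study`. `loadStudyDefinition()` compiles these into an immutable
definition, cross-checking every reference and reporting *all* dangling
names in a single error, so a study designer can fix a workbook in one
round trip. The published systems this design follows describe their
templates but not their column layouts, so the dialect here is this
package's own, documented in `?loadStudyDefinition` and versioned through
the definition's integer `version` field; data records store the version
they were captured under, which is what makes mid-study schema revisions
auditable.

Two sheets beyond the minimal set deserve a note. CRF-level attributes
(signature slots, consent class, the `pre_consent` marker for
recruitment/screening forms that precede consent) need a home that the
variable-level dictionary cannot provide — that is the `forms` sheet.
Visit ordering and the scheduled/on-demand distinction live in `visits`.

## The expression language

Eligibility criteria, skip rules, trigger sources and cross-field checks
share one side-effect-free grammar: arithmetic and comparison operators,
`&`, `|`, `!`, `%in%`, literals, and two helpers (`is_blank(x)`,
`age_years_asof(dob, date)`). Anything else — function calls, assignment,
control flow — is rejected at compile time. Criteria reference variables
as `crf_id.variable`; the pseudo-CRF `participant` exposes
registry-derived values (`participant.age_years`), which makes age-only
criteria decidable at registration, before any form exists.

Evaluation is three-valued: a variable on an incomplete CRF is unknown
(`NA`), and R's native Kleene semantics propagate it. The practical
consequence is the asymmetry the screening workflow needs: `FALSE`
can be established early (a single failed criterion excludes the
participant immediately), while `TRUE` is only trusted once every
predicate CRF of the criterion is complete. Overall eligibility demands
all criteria passed *and* all predicate CRFs complete; with zero criteria
this holds vacuously at registration. Decisions are terminal: only the
audited data-manager edit path (`editSignedValue()`) forces a full
re-evaluation, and a flipped decision is itself an audit-trail event.

Where several completed instances of one CRF exist, criteria read the
structurally first one (earliest scheduled visit, lowest ordinal) rather
than the most recently completed — the choice that makes evaluation
independent of completion order, a property the test suite checks over
hundreds of random permutations.

## Ages, consent routing, identifiers

Birth-date information in the field comes in three precisions: exact
date, partial date (year, optionally month), and stated age as of a
date. `computeAge()` returns completed years (the anniversary day counts
as completed), days where derivable, and a precision tag. Partial dates
resolve to the **youngest possible** age — computed from the latest
consistent birth date. This is the protective direction for consent: an
ambiguous 17/18-year-old is routed to assent plus parental consent, and
the precision tag is retained for review. Consent bands are half-open
`[min, max)` in completed years, so "15 to 18" adolescents map to
`[15,18)` and adults to `[18, ∞)`.

Identifiers are in-order concatenations of scheme components. With a
device-code component, per-device counters make IDs collision-free with
no coordination; for bare sequential schemes (the 4-digit + color-letter
design used in trial fixtures), `registerDevice()` accepts a starting
counter so sites can pre-assign disjoint ranges — the same
pre-partitioning idea used for randomization rows. Counters survive a
device purge, so no identifier or change id is ever recycled. In
randomized designs the registration ID is provisional (letterless); the
enrollment ID gains the allocation's color letter.

## The event-sourced store and synchronization

Every mutation is a change record — entity, key, field, old value, new
value, username, device, per-device logical timestamp, wall-clock
timestamp, schema version — appended to a log; materialized state is the
fold of that log at all times (`replayLog()` recomputes it from scratch
and the tests require equality after every simulated session). The log
doubles as the audit trail and as the synchronization payload.

Synchronization ships change records between stores, deduplicated by
globally unique change ids (device code + device-local counter) and
tracked by per-device watermarks: idempotent (a second sync transfers
nothing), resumable (each applied record is durable), and convergent —
after both-direction syncs of all devices against one server, all stores
materialize identical state for the shared scope. Pulls can be scoped to
a participant subset, the privacy-minimizing one-direction pattern used
when a station should not hold other stations' data.

Concurrent edits of the same field are expected to be rare by field
protocol (one device per participant per visit) but must still be
defined: the incoming value is appended (history is never dropped), a
conflict record captures both candidates, and the field shows a
deterministic *provisional* value — higher logical timestamp wins, ties
break toward the lexicographically smaller device code — until a holder
of the `resolve-query` privilege resolves it, which is itself audited.
Pre-partitioned per-device randomization blocks
(`assignDeviceBlocks()`) apply the same conflict-avoidance idea to
allocation; reclaiming unconsumed blocks at sync is not implemented and
is listed under limitations.

Two deliberate deviations from a pure fold: `purgeDevice()` erases the
log along with participant data (that is its purpose — end-of-study
removal from devices) while retaining accounts, device identity and
counters; and user sessions are ephemeral, never part of state.

## Data quality: flags, replicates, adaptive protocols

Numeric variables carry two bands: a *soft* (plausibility) range with
inclusive bounds whose violation raises an acknowledgeable `warn` flag,
and a *hard* (possibility) range with exclusive bounds whose violation
raises a `block` flag and refuses storage — zero or negative body weight
is impossible, 1 kg for an adult is merely implausible. Cross-field rules
state a contradiction condition that flags all involved variables;
high-importance variables left blank flag at completion. A CRF cannot
complete while any warn flag is unacknowledged or any block flag stands;
acknowledgments are per-flag, audited, and voided if the value is
re-edited. Interactive entry stores a soft-violating value only
*with* acknowledgment; batch import (`importExternalResults()`) stores it
with the flag left pending, so imported labs surface the same flags but
defer verification to a human — the one asymmetry between the two entry
paths.

Replicate measurements (`<stem>_r1`, `_r2`, ...) unlock strictly in
sequence, forcing a full re-measurement protocol. When the base
replicates disagree beyond the threshold, extra replicate fields appear.
The variation metric is the maximum pairwise absolute difference
(absolute thresholds) or that difference divided by the replicate mean
(relative thresholds); the field literature states thresholds without a
formula, so both are offered and the fixture uses absolute (0.5 cm on
standing height). Adaptive rules render an instruction with the
complement of a determinant substituted — dominant arm *right* yields
"measure the LEFT (nondominant) arm" — and keep the affected variables
locked until the determinant is answered.

## Signing, roles, progression

Signing re-authenticates at the moment of signature; slots on multi-signer
forms must be filled by distinct usernames ("multiple study personnel"
means distinct people). A signed form is locked except through the
audited edit path, which voids signatures — the form must be re-signed —
and this re-signature requirement is this package's choice where the
original systems are silent. A visit is complete when every contained
(non-retired) CRF instance is signed.

`gateProgression()` is the enforcement surface: pre-consent forms and the
routed consent set first; predicate (screening) CRFs once blocking
consent is signed, even while eligibility is pending (they decide it);
everything else only for eligible participants with consent complete;
visits open strictly in order; ineligible participants keep only their
pre-consent forms. Consent forms outside the participant's age band are
never instantiated at all — the wrong form cannot appear, let alone be
filled.

Trigger reconciliation never deletes: lowering a count retires surplus
instances, and a retired instance that already contains data is flagged
for data-manager review. Audit preservation outranks tidiness.

## What the fixtures and simulator emulate — and what they do not

`buildFixture()` constructs four protocol shapes: a clinic cross-sectional
study (three consent age bands, two-signer forms, skip logic, continuous
sync cadence), a household surveillance program (household + participant
ID hierarchy, 15–40 not-pregnant/not-lactating eligibility, pregnancy-count
trigger, replicate and adaptive anthropometry), a two-arm trial (consent
at three successive visits, nine monthly follow-ups, midline serial
sampling, sick-form specimen trigger, 4-digit + letter IDs), and a 2×2
factorial trial (one multi-level consent form, four color groups mapped
two-to-one onto two arms). Their value ranges, label translations and the
simulator's distributions (ages mostly uniform inside the eligible
window with a deliberate out-of-window fraction, yes/no items biased
80 % toward "no", error injection as soft-range violations later
corrected) are **synthetic placeholders** chosen to exercise engine
paths. Passing tests therefore demonstrate protocol *enforcement* —
gating, flags, convergence, composition — not statistical realism of any
real cohort, and no real participant data or study results are
reproduced. The permuted-block table generator exists for testing only;
production studies load a statistician's table.

Problem sizes in the test suite and acceptance script (tens of
participants, up to five devices, a ~1000-record merged log, 200+
eligibility permutations, a 5×100 identifier grid) are the package's
chosen demonstration scale: every property checked is size-independent
by construction, and the simulator scales linearly if larger runs are
wanted.

## Numerical and degenerate-input conventions

* Hard range bounds are exclusive; soft bounds inclusive (see above).
* Completed years: the birthday itself completes the year.
* Stated ages advance by completed years elapsed since their as-of date.
* Empty criteria set ⇒ eligible on the empty predicate set; empty
  randomization table ⇒ valid with zero capacity; zero scheduled visits
  ⇒ empty schedule instantiation.
* A count trigger with a blank or non-numeric source reconciles to zero.
* Exports sort rows by participant, visit order and ordinal, and store
  timestamps in a fixed UTC format, so repeated exports of one store are
  byte-identical; simulations take an injectable deterministic clock, so
  a seed reproduces exports byte-for-byte.
* Conflict tie-break: logical timestamp, then smaller device code —
  arbitrary but total, so every store computes the same provisional
  value.

## Known limitations

* Transport is file/function-level: the sync engine exchanges change
  records between in-memory or saved stores; no network layer, retries
  or encryption-at-rest key management.
* Unconsumed per-device randomization blocks are not reclaimed at sync.
* Audiovisual consent capture is represented as an attachment-reference
  field only; no media handling.
* Deidentification removes identifying-flagged columns and name fields;
  it is a mechanism, not a certified compliance claim, and performs no
  statistical disclosure control.
* Re-screening a previously ineligible person is supported only as a new
  evaluation after an audited data correction; there is no separate
  screening-episode object.
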