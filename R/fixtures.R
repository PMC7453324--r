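## Programmatically built study configurations emulating four field designs:
## a clinic-based cross-sectional study, a household surveillance program,
## a two-arm RCT with midline serial sampling, and a four-color-group 2x2
## RCT. All values (ranges, distributions) are synthetic placeholders that
## exercise the engine's paths; they emulate, not reproduce, any real study.

fxRow <- function(...) {
  vals <- list(...)
  as.data.frame(vals, stringsAsFactors = FALSE)
}

fxVar <- function(crf_id, name, type, label, choices = "", soft_low = "",
                  soft_high = "", hard_low = "", hard_high = "",
                  required = "", high_importance = "", identifying = "",
                  unit = "", skip_if = "") {
  fxRow(crf_id = crf_id, name = name, type = type, label_en = label,
        choices = choices, soft_low = soft_low, soft_high = soft_high,
        hard_low = hard_low, hard_high = hard_high, required = required,
        high_importance = high_importance, identifying = identifying,
        unit = unit, skip_if = skip_if)
}

fxForm <- function(crf_id, title, signature_slots = "1",
                   is_consent_form = "", consent_class = "",
                   pre_consent = "") {
  fxRow(crf_id = crf_id, title_en = title, signature_slots = signature_slots,
        is_consent_form = is_consent_form, consent_class = consent_class,
        pre_consent = pre_consent)
}

## auto-translate labels so every declared language is complete
fxAddLanguage <- function(sheets, lang) {
  d <- sheets$dictionary
  d[[paste0("label_", lang)]] <- sprintf("[%s] %s", lang, d$label_en)
  sheets$dictionary <- d
  f <- sheets$forms
  f[[paste0("title_", lang)]] <- sprintf("[%s] %s", lang, f$title_en)
  sheets$forms <- f
  if (!is.null(sheets$validation) && nrow(sheets$validation) > 0 &&
      "message_en" %in% names(sheets$validation)) {
    sheets$validation[[paste0("message_", lang)]] <-
      ifelse(nzchar(sheets$validation$message_en),
             sprintf("[%s] %s", lang, sheets$validation$message_en), "")
  }
  sheets
}

fxWriteWorkbook <- function(sheets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sheets)) {
    utils::write.csv(sheets[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  dir
}

consentChoice <- "0=No|1=Yes"
yesNo <- "0=No|1=Yes"

fixtureSheetsSurveillance <- function() {
  forms <- rbind(
    fxForm("household_form", "Household characteristics", pre_consent = "1"),
    fxForm("recruitment", "Recruitment and identification", pre_consent = "1"),
    fxForm("screening", "Screening", pre_consent = "1"),
    fxForm("assent_adolescent", "Adolescent assent", is_consent_form = "1",
           consent_class = "adolescent-assent"),
    fxForm("consent_parental", "Parental consent", is_consent_form = "1",
           consent_class = "parental-consent"),
    fxForm("consent_adult", "Adult consent", is_consent_form = "1",
           consent_class = "adult-consent"),
    fxForm("health_questionnaire", "Reproductive and health history"),
    fxForm("pregnancy", "Pregnancy record"),
    fxForm("anthropometry", "Anthropometry")
  )
  dictionary <- rbind(
    fxVar("household_form", "n_members", "integer", "Household members",
          soft_low = "1", soft_high = "15", hard_low = "0", hard_high = "50",
          required = "1"),
    fxVar("household_form", "water_source", "choice", "Water source",
          choices = "1=Piped|2=Well|3=Other", required = "1"),
    fxVar("recruitment", "name_full", "text", "Full name", identifying = "1",
          required = "1"),
    fxVar("recruitment", "phone", "text", "Phone number", identifying = "1"),
    fxVar("screening", "pregnant", "choice", "Currently pregnant",
          choices = yesNo, required = "1", high_importance = "1"),
    fxVar("screening", "lactating", "choice", "Currently lactating",
          choices = yesNo, required = "1", high_importance = "1"),
    fxVar("assent_adolescent", "assent_given", "choice", "Assent given",
          choices = consentChoice, required = "1"),
    fxVar("assent_adolescent", "assent_signature", "signature-ref",
          "Participant signature", required = "1"),
    fxVar("consent_parental", "consent_given", "choice", "Parental consent given",
          choices = consentChoice, required = "1"),
    fxVar("consent_parental", "guardian_signature", "signature-ref",
          "Guardian signature", required = "1"),
    fxVar("consent_adult", "consent_given", "choice", "Consent given",
          choices = consentChoice, required = "1"),
    fxVar("consent_adult", "participant_signature", "signature-ref",
          "Participant signature", required = "1"),
    fxVar("health_questionnaire", "ever_pregnant", "choice", "Ever pregnant",
          choices = yesNo, required = "1", high_importance = "1"),
    fxVar("health_questionnaire", "pregnancies_count", "integer",
          "Number of pregnancies", soft_low = "0", soft_high = "15",
          hard_low = "-1", hard_high = "31", required = "1"),
    fxVar("pregnancy", "outcome", "choice", "Pregnancy outcome",
          choices = "1=Live birth|2=Stillbirth|3=Miscarriage|4=Ongoing",
          required = "1"),
    fxVar("pregnancy", "outcome_year", "integer", "Year of outcome",
          soft_low = "1990", soft_high = "2030", hard_low = "1900",
          hard_high = "2100"),
    fxVar("anthropometry", "weight_kg", "decimal", "Body weight",
          soft_low = "25", soft_high = "200", hard_low = "0",
          hard_high = "400", required = "1", unit = "kg"),
    fxVar("anthropometry", "height_r1", "decimal", "Height, replicate 1",
          soft_low = "120", soft_high = "200", hard_low = "50",
          hard_high = "250", required = "1", unit = "cm"),
    fxVar("anthropometry", "height_r2", "decimal", "Height, replicate 2",
          soft_low = "120", soft_high = "200", hard_low = "50",
          hard_high = "250", required = "1", unit = "cm"),
    fxVar("anthropometry", "height_r3", "decimal", "Height, replicate 3",
          soft_low = "120", soft_high = "200", hard_low = "50",
          hard_high = "250", unit = "cm"),
    fxVar("anthropometry", "dominant_arm", "choice", "Dominant arm",
          choices = "left=Left|right=Right", required = "1"),
    fxVar("anthropometry", "triceps_skinfold", "decimal",
          "Triceps skinfold (nondominant arm)", soft_low = "4",
          soft_high = "40", hard_low = "0", hard_high = "80",
          required = "1", unit = "mm")
  )
  visits <- rbind(
    fxRow(visit_id = "screening_visit", label = "Screening",
          order_index = "1", scheduled = "1"),
    fxRow(visit_id = "health_visit", label = "Health questionnaire",
          order_index = "2", scheduled = "1")
  )
  schedule <- rbind(
    fxRow(visit_id = "screening_visit", crf_id = "household_form", mode = "always"),
    fxRow(visit_id = "screening_visit", crf_id = "recruitment", mode = "always"),
    fxRow(visit_id = "screening_visit", crf_id = "screening", mode = "always"),
    fxRow(visit_id = "screening_visit", crf_id = "assent_adolescent", mode = "always"),
    fxRow(visit_id = "screening_visit", crf_id = "consent_parental", mode = "always"),
    fxRow(visit_id = "screening_visit", crf_id = "consent_adult", mode = "always"),
    fxRow(visit_id = "health_visit", crf_id = "health_questionnaire", mode = "always"),
    fxRow(visit_id = "health_visit", crf_id = "anthropometry", mode = "always"),
    fxRow(visit_id = "health_visit", crf_id = "pregnancy", mode = "trigger")
  )
  criteria <- rbind(
    fxRow(criterion_id = "reproductive_age",
          expression = "participant.age_years >= 15 & participant.age_years <= 40",
          description = "Woman of reproductive age (15-40 completed years)"),
    fxRow(criterion_id = "not_pregnant",
          expression = 'screening.pregnant == "0"',
          description = "Not currently pregnant"),
    fxRow(criterion_id = "not_lactating",
          expression = 'screening.lactating == "0"',
          description = "Not currently lactating")
  )
  triggers <- fxRow(rule_id = "trg_pregnancies", source_crf = "health_questionnaire",
                    expression = "pregnancies_count", mode = "count",
                    target_crf = "pregnancy", target_visit_policy = "same-visit")
  consent <- rbind(
    fxRow(band_id = "adolescent", age_min = "15", age_max = "18",
          consent_crfs = "assent_adolescent;consent_parental",
          blocks_progression = "1"),
    fxRow(band_id = "adult", age_min = "18", age_max = "",
          consent_crfs = "consent_adult", blocks_progression = "1")
  )
  ids <- rbind(
    fxRow(scope = "participant", position = "1", component = "study-code", value = "PS"),
    fxRow(scope = "participant", position = "2", component = "device-code", value = "2"),
    fxRow(scope = "participant", position = "3", component = "sequential", value = "4"),
    fxRow(scope = "household", position = "1", component = "study-code", value = "HH"),
    fxRow(scope = "household", position = "2", component = "device-code", value = "2"),
    fxRow(scope = "household", position = "3", component = "sequential", value = "4")
  )
  validation <- rbind(
    fxRow(rule_id = "cf_pregnancy", kind = "cross-field",
          crf_id = "health_questionnaire",
          expression = 'ever_pregnant == "0" & pregnancies_count > 0',
          variables = "ever_pregnant;pregnancies_count",
          message_en = "Never pregnant but pregnancy count is positive",
          stem = "", n_base = "", threshold = "", threshold_type = "",
          n_extra = "", determinant = "", instruction_en = "", affected = ""),
    fxRow(rule_id = "rep_height", kind = "replicate", crf_id = "anthropometry",
          expression = "", variables = "", message_en = "",
          stem = "height", n_base = "2", threshold = "0.5",
          threshold_type = "absolute", n_extra = "1",
          determinant = "", instruction_en = "", affected = ""),
    fxRow(rule_id = "ad_skinfold", kind = "adaptive", crf_id = "anthropometry",
          expression = "", variables = "", message_en = "",
          stem = "", n_base = "", threshold = "", threshold_type = "",
          n_extra = "", determinant = "dominant_arm",
          instruction_en = "Measure the {side} (nondominant) arm for triceps skinfold",
          affected = "triceps_skinfold")
  )
  study <- fxRow(study_code = "PS", version = "1", default_language = "en",
                 sync_cadence = "daily")
  fxAddLanguage(list(study = study, forms = forms, dictionary = dictionary,
                     visits = visits, schedule = schedule, criteria = criteria,
                     triggers = triggers, consent = consent, ids = ids,
                     validation = validation), "te")
}

fixtureSheetsFeverphone <- function() {
  forms <- rbind(
    fxForm("recruitment", "Recruitment", pre_consent = "1"),
    fxForm("assent_child", "Child assent", is_consent_form = "1",
           consent_class = "adolescent-assent"),
    fxForm("consent_guardian", "Guardian consent", is_consent_form = "1",
           consent_class = "parental-consent"),
    fxForm("consent_adult", "Adult consent", is_consent_form = "1",
           consent_class = "adult-consent"),
    fxForm("clinical_signs", "Clinical signs and symptoms",
           signature_slots = "2"),
    fxForm("specimen_collection", "Specimen collection", signature_slots = "2")
  )
  dictionary <- rbind(
    fxVar("recruitment", "name_full", "text", "Full name", identifying = "1",
          required = "1"),
    fxVar("recruitment", "sex", "choice", "Sex",
          choices = "f=Female|m=Male", required = "1"),
    fxVar("assent_child", "assent_given", "choice", "Assent given",
          choices = consentChoice, required = "1"),
    fxVar("consent_guardian", "consent_given", "choice", "Guardian consent",
          choices = consentChoice, required = "1"),
    fxVar("consent_adult", "consent_given", "choice", "Consent given",
          choices = consentChoice, required = "1"),
    fxVar("clinical_signs", "temperature_c", "decimal", "Axillary temperature",
          soft_low = "35", soft_high = "42", hard_low = "30", hard_high = "45",
          required = "1", high_importance = "1", unit = "C"),
    fxVar("clinical_signs", "fever_days", "integer", "Days of fever",
          soft_low = "0", soft_high = "30", hard_low = "-1", hard_high = "365",
          required = "1", high_importance = "1", unit = "days"),
    fxVar("clinical_signs", "severe", "choice", "Severe presentation",
          choices = yesNo, required = "1"),
    fxVar("clinical_signs", "hospitalized_days", "integer",
          "Days hospitalized", soft_low = "0", soft_high = "60",
          hard_low = "-1", hard_high = "365",
          skip_if = 'severe == "0"', unit = "days"),
    fxVar("specimen_collection", "specimen_type", "choice", "Specimen type",
          choices = "b=Blood|s=Saliva", required = "1"),
    fxVar("specimen_collection", "volume_ml", "decimal", "Volume collected",
          soft_low = "0.5", soft_high = "10", hard_low = "0", hard_high = "50",
          required = "1", unit = "mL")
  )
  visits <- rbind(
    fxRow(visit_id = "enrollment", label = "Enrollment", order_index = "1",
          scheduled = "1"),
    fxRow(visit_id = "specimen_visit", label = "Specimen and laboratory",
          order_index = "2", scheduled = "1")
  )
  schedule <- rbind(
    fxRow(visit_id = "enrollment", crf_id = "recruitment", mode = "always"),
    fxRow(visit_id = "enrollment", crf_id = "assent_child", mode = "always"),
    fxRow(visit_id = "enrollment", crf_id = "consent_guardian", mode = "always"),
    fxRow(visit_id = "enrollment", crf_id = "consent_adult", mode = "always"),
    fxRow(visit_id = "enrollment", crf_id = "clinical_signs", mode = "always"),
    fxRow(visit_id = "specimen_visit", crf_id = "specimen_collection",
          mode = "always")
  )
  criteria <- fxRow(
    criterion_id = "acute_febrile",
    expression = "clinical_signs.temperature_c >= 38 | clinical_signs.fever_days >= 1",
    description = "Acute febrile illness at presentation")
  consent <- rbind(
    fxRow(band_id = "young_child", age_min = "0", age_max = "5",
          consent_crfs = "consent_guardian", blocks_progression = "1"),
    fxRow(band_id = "child", age_min = "5", age_max = "18",
          consent_crfs = "assent_child;consent_guardian",
          blocks_progression = "1"),
    fxRow(band_id = "adult", age_min = "18", age_max = "",
          consent_crfs = "consent_adult", blocks_progression = "1")
  )
  ids <- rbind(
    fxRow(scope = "participant", position = "1", component = "study-code", value = "FP"),
    fxRow(scope = "participant", position = "2", component = "device-code", value = "2"),
    fxRow(scope = "participant", position = "3", component = "sequential", value = "4")
  )
  study <- fxRow(study_code = "FP", version = "1", default_language = "en",
                 sync_cadence = "continuous")
  fxAddLanguage(list(study = study, forms = forms, dictionary = dictionary,
                     visits = visits, schedule = schedule, criteria = criteria,
                     consent = consent, ids = ids), "es")
}

fixtureSheetsMumbai <- function() {
  fu <- sprintf("fu%d", 1:9)
  forms <- rbind(
    fxForm("recruitment", "Recruitment", pre_consent = "1"),
    fxForm("consent_prescreening", "Consent to noninvasive data collection",
           is_consent_form = "1", consent_class = "parental-consent"),
    fxForm("consent_screening", "Consent to biospecimens and growth measurement",
           is_consent_form = "1", consent_class = "parental-consent"),
    fxForm("consent_enrollment", "Consent to trial participation",
           is_consent_form = "1", consent_class = "parental-consent"),
    fxForm("anthro_screen", "Screening anthropometry"),
    fxForm("lab_screen", "Screening laboratory results"),
    fxForm("followup_health", "Monthly health follow-up"),
    fxForm("sick_specimen", "Illness specimen collection"),
    fxForm("serial_sample", "Midline serial sample")
  )
  dictionary <- rbind(
    fxVar("recruitment", "name_child", "text", "Child name", identifying = "1",
          required = "1"),
    fxVar("recruitment", "name_mother", "text", "Mother name", identifying = "1",
          required = "1"),
    fxVar("consent_prescreening", "consent_given", "choice", "Consent given",
          choices = consentChoice, required = "1"),
    fxVar("consent_screening", "consent_given", "choice", "Consent given",
          choices = consentChoice, required = "1"),
    fxVar("consent_enrollment", "consent_given", "choice", "Consent given",
          choices = consentChoice, required = "1"),
    fxVar("anthro_screen", "age_months", "integer", "Age in months",
          soft_low = "10", soft_high = "20", hard_low = "0", hard_high = "60",
          required = "1", high_importance = "1", unit = "months"),
    fxVar("anthro_screen", "weight_kg", "decimal", "Weight",
          soft_low = "5", soft_high = "20", hard_low = "0", hard_high = "40",
          required = "1", unit = "kg"),
    fxVar("lab_screen", "hb_gdl", "decimal", "Hemoglobin",
          soft_low = "7", soft_high = "18", hard_low = "0", hard_high = "25",
          required = "1", high_importance = "1", unit = "g/dL"),
    fxVar("followup_health", "illness_today", "choice", "Any illness today",
          choices = yesNo, required = "1"),
    fxVar("followup_health", "fever", "choice", "Fever since last visit",
          choices = yesNo, required = "1", high_importance = "1"),
    fxVar("sick_specimen", "specimen_type", "choice", "Specimen type",
          choices = "b=Blood|s=Saliva", required = "1"),
    fxVar("serial_sample", "sample_volume_ml", "decimal", "Sample volume",
          soft_low = "0.5", soft_high = "5", hard_low = "0", hard_high = "20",
          required = "1", unit = "mL")
  )
  visits <- rbind(
    fxRow(visit_id = "prescreening", label = "Prescreening",
          order_index = "1", scheduled = "1"),
    fxRow(visit_id = "screening", label = "Screening", order_index = "2",
          scheduled = "1"),
    fxRow(visit_id = "enrollment", label = "Enrollment", order_index = "3",
          scheduled = "1"),
    do.call(rbind, lapply(seq_along(fu), function(i) {
      fxRow(visit_id = fu[[i]], label = sprintf("Monthly follow-up %d", i),
            order_index = as.character(3 + i), scheduled = "1")
    }))
  )
  schedule <- rbind(
    fxRow(visit_id = "prescreening", crf_id = "recruitment", mode = "always"),
    fxRow(visit_id = "prescreening", crf_id = "consent_prescreening", mode = "always"),
    fxRow(visit_id = "screening", crf_id = "consent_screening", mode = "always"),
    fxRow(visit_id = "screening", crf_id = "anthro_screen", mode = "always"),
    fxRow(visit_id = "screening", crf_id = "lab_screen", mode = "always"),
    fxRow(visit_id = "enrollment", crf_id = "consent_enrollment", mode = "always"),
    do.call(rbind, lapply(fu, function(v) {
      rbind(fxRow(visit_id = v, crf_id = "followup_health", mode = "always"),
            fxRow(visit_id = v, crf_id = "sick_specimen", mode = "trigger"),
            fxRow(visit_id = v, crf_id = "serial_sample", mode = "midline"))
    }))
  )
  criteria <- rbind(
    fxRow(criterion_id = "age_window",
          expression = "anthro_screen.age_months >= 12 & anthro_screen.age_months <= 18",
          description = "Child aged 12-18 months at screening"),
    fxRow(criterion_id = "not_severely_anemic",
          expression = "lab_screen.hb_gdl >= 7",
          description = "No severe anemia at screening")
  )
  triggers <- fxRow(rule_id = "trg_sick", source_crf = "followup_health",
                    expression = 'fever == "1"', mode = "predicate",
                    target_crf = "sick_specimen",
                    target_visit_policy = "same-visit")
  ## the three consent forms sit at three successive visits; visit ordering
  ## (each visit completes, consent signed, before the next opens) enforces
  ## the flow, so the band must not block globally
  consent <- fxRow(band_id = "child", age_min = "0", age_max = "18",
                   consent_crfs = "consent_prescreening;consent_screening;consent_enrollment",
                   blocks_progression = "0")
  ids <- rbind(
    fxRow(scope = "participant", position = "1", component = "sequential", value = "4"),
    fxRow(scope = "participant", position = "2", component = "group-letter", value = "")
  )
  randomization_config <- rbind(
    fxRow(color_group = "A", arm = "biofortified", midline_sampling = "1"),
    fxRow(color_group = "B", arm = "conventional", midline_sampling = "1")
  )
  study <- fxRow(study_code = "BPM", version = "1", default_language = "en",
                 sync_cadence = "daily")
  fxAddLanguage(list(study = study, forms = forms, dictionary = dictionary,
                     visits = visits, schedule = schedule, criteria = criteria,
                     triggers = triggers, consent = consent, ids = ids,
                     randomization_config = randomization_config), "hi")
}

fixtureSheetsMbfc <- function() {
  fu <- sprintf("fu%d", 1:9)
  forms <- rbind(
    fxForm("recruitment", "Recruitment", pre_consent = "1"),
    fxForm("consent_multilevel", "Informed consent (multiple levels)",
           is_consent_form = "1", consent_class = "parental-consent"),
    fxForm("screening_mbfc", "Screening"),
    fxForm("followup_mbfc", "Feeding and health follow-up"),
    fxForm("serial_sample_mbfc", "Midline serial sample")
  )
  dictionary <- rbind(
    fxVar("recruitment", "name_child", "text", "Child name", identifying = "1",
          required = "1"),
    fxVar("recruitment", "name_mother", "text", "Mother name", identifying = "1",
          required = "1"),
    fxVar("consent_multilevel", "consent_screening", "choice",
          "Consent to screening and trial participation",
          choices = consentChoice, required = "1"),
    fxVar("consent_multilevel", "consent_storage", "choice",
          "Consent to biological sample storage and analysis",
          choices = consentChoice, required = "1"),
    fxVar("consent_multilevel", "consent_future_genetic", "choice",
          "Consent to future analyses incl. genetic",
          choices = consentChoice, required = "1"),
    fxVar("screening_mbfc", "age_months", "integer", "Age in months",
          soft_low = "4", soft_high = "28", hard_low = "0", hard_high = "60",
          required = "1", high_importance = "1", unit = "months"),
    fxVar("screening_mbfc", "hb_gdl", "decimal", "Hemoglobin",
          soft_low = "7", soft_high = "18", hard_low = "0", hard_high = "25",
          required = "1", high_importance = "1", unit = "g/dL"),
    fxVar("followup_mbfc", "breastfed_today", "choice", "Breastfed today",
          choices = yesNo, required = "1"),
    fxVar("followup_mbfc", "meals_count", "integer", "Meals in past 24h",
          soft_low = "0", soft_high = "10", hard_low = "-1", hard_high = "20",
          required = "1"),
    fxVar("serial_sample_mbfc", "volume_ml", "decimal", "Sample volume",
          soft_low = "0.5", soft_high = "5", hard_low = "0", hard_high = "20",
          required = "1", unit = "mL")
  )
  visits <- rbind(
    fxRow(visit_id = "screening", label = "Screening", order_index = "1",
          scheduled = "1"),
    fxRow(visit_id = "baseline", label = "Baseline", order_index = "2",
          scheduled = "1"),
    do.call(rbind, lapply(seq_along(fu), function(i) {
      fxRow(visit_id = fu[[i]], label = sprintf("Follow-up %d", i),
            order_index = as.character(2 + i), scheduled = "1")
    }))
  )
  schedule <- rbind(
    fxRow(visit_id = "screening", crf_id = "recruitment", mode = "always"),
    fxRow(visit_id = "screening", crf_id = "consent_multilevel", mode = "always"),
    fxRow(visit_id = "screening", crf_id = "screening_mbfc", mode = "always"),
    fxRow(visit_id = "baseline", crf_id = "followup_mbfc", mode = "always"),
    do.call(rbind, lapply(fu, function(v) {
      rbind(fxRow(visit_id = v, crf_id = "followup_mbfc", mode = "always"),
            fxRow(visit_id = v, crf_id = "serial_sample_mbfc", mode = "midline"))
    }))
  )
  criteria <- rbind(
    fxRow(criterion_id = "age_window",
          expression = "screening_mbfc.age_months >= 6 & screening_mbfc.age_months <= 24",
          description = "Infant aged 6-24 months"),
    fxRow(criterion_id = "not_severely_anemic",
          expression = "screening_mbfc.hb_gdl >= 7",
          description = "No severe anemia")
  )
  consent <- fxRow(band_id = "infant", age_min = "0", age_max = "18",
                   consent_crfs = "consent_multilevel",
                   blocks_progression = "1")
  ids <- rbind(
    fxRow(scope = "participant", position = "1", component = "study-code", value = "MB"),
    fxRow(scope = "participant", position = "2", component = "sequential", value = "4"),
    fxRow(scope = "participant", position = "3", component = "group-letter", value = "")
  )
  randomization_config <- rbind(
    fxRow(color_group = "A", arm = "food_basket", midline_sampling = "1"),
    fxRow(color_group = "B", arm = "food_basket", midline_sampling = "1"),
    fxRow(color_group = "C", arm = "control", midline_sampling = "1"),
    fxRow(color_group = "D", arm = "control", midline_sampling = "1")
  )
  study <- fxRow(study_code = "MB", version = "1", default_language = "en",
                 sync_cadence = "daily")
  fxAddLanguage(list(study = study, forms = forms, dictionary = dictionary,
                     visits = visits, schedule = schedule, criteria = criteria,
                     consent = consent, ids = ids,
                     randomization_config = randomization_config), "te")
}

#' Build one of the four reference study configurations
#'
#' Each fixture is written as a CSV workbook in the chosen directory and
#' compiled through the normal loader, so building a fixture also exercises
#' the full schema path. Randomized designs additionally get a
#' seeded permuted-block randomization table (a testing aid, not a
#' production randomization — see [makePermutedBlockTable()]).
#'
#' * `feverphone-like` — clinic-based cross-sectional: age-routed
#'   consent/assent across three bands, two-signer CRFs, skip logic,
#'   continuous-sync cadence.
#' * `surveillance-like` — household surveillance: household + participant
#'   id hierarchy (3-component ids), 15-40 not-pregnant/not-lactating
#'   eligibility, \[15,18) assent + parental / \[18,Inf) adult consent
#'   bands, pregnancy-count trigger, replicate and adaptive anthropometry.
#' * `mumbai-like` — two-arm RCT: consent at three separate visits,
#'   9 monthly follow-ups, midline serial sampling, sick-form specimen
#'   trigger, 4-digit + group-letter ids.
#' * `mbfc-like` — 2x2 factorial RCT: one multi-level consent form, four
#'   color groups mapped two-to-one onto two arms, midline designation.
#'
#' @param name fixture name.
#' @param dir directory for the workbook CSVs (default: a fresh tempdir).
#' @param table_rows rows in the generated randomization table.
#' @return list with `definition`, `workbook_dir`, `rand_table` (an
#'   `edc_rand_table` or `NULL`), `rand_table_path`.
#' @export
buildFixture <- function(name = c("feverphone-like", "surveillance-like",
                                  "mumbai-like", "mbfc-like"),
                         dir = tempfile("workbook-"), table_rows = 24) {
  name <- match.arg(name)
  sheets <- switch(name,
    "feverphone-like" = fixtureSheetsFeverphone(),
    "surveillance-like" = fixtureSheetsSurveillance(),
    "mumbai-like" = fixtureSheetsMumbai(),
    "mbfc-like" = fixtureSheetsMbfc()
  )
  fxWriteWorkbook(sheets, dir)
  defn <- loadStudyDefinition(dir)
  rand_table <- NULL
  rand_path <- NULL
  if (!is.null(defn$randomization)) {
    colors <- names(defn$randomization$color_to_arm)
    mid <- if (isTRUE(defn$randomization$midline_sampling)) {
      sprintf("fu%d", 3:7)
    } else NULL
    tab_df <- makePermutedBlockTable(table_rows, colors, mid,
                                     block_size = 2 * length(colors),
                                     seed = 104729)
    rand_path <- file.path(dir, "randomization_table.csv")
    utils::write.csv(tab_df, rand_path, row.names = FALSE, na = "")
    rand_table <- loadRandomizationTable(rand_path, defn)
  }
  list(definition = defn, workbook_dir = dir, rand_table = rand_table,
       rand_table_path = rand_path)
}
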