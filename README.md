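# edcflow

Schema-driven electronic data capture (EDC) for epidemiological field
studies and randomized controlled trials, written for settings where
internet access is intermittent and protocols are strict: multi-device
offline capture with asynchronous synchronization, real-time eligibility
and consent enforcement, randomization-table allocation, data-quality
flags, electronic signing, and a complete audit trail.

The central idea is that a study protocol is **data, not code**. A
workbook of plain tabular sheets declares the protocol —

* a **data dictionary** (variables per case report form, with types,
  choice lists, plausibility/possibility ranges, skip logic, identifying
  and high-importance flags),
* a **forms schedule** (the visit-by-CRF matrix: which forms are
  instantiated at which scheduled visits, including midline-designated and
  trigger-only cells),
* **eligibility criteria** as boolean formulas over qualified variables
  (`screening.pregnant == "0"`, `participant.age_years >= 15`), evaluated
  under three-valued logic so a single negative criterion excludes a
  participant before the remaining forms even exist,
* **trigger rules** (a pregnancy count spawns that many pregnancy forms; a
  positive sick form spawns a specimen form),
* **consent routing** by half-open age bands in completed years
  (`[15,18)` assent + parental consent, `[18,∞)` adult consent),
* an **identifier scheme** (study code + device code + zero-padded
  sequential counter + optional randomization color letter) that generates
  collision-free IDs offline, and
* **validation rules** (cross-field contradictions, replicate measurements
  with a variation threshold, adaptive instructions such as "measure the
  nondominant arm").

The engine compiles the workbook into an immutable study definition and
enforces it at entry time; no per-study code is written. Every store
(one per capture device, plus a server) is event-sourced: the change log —
who changed what, when, from which device, old value to new value — is at
once the audit trail and the synchronization payload, shipped between
stores by per-device watermarks so synchronization is idempotent,
resumable, and convergent.

## Worked example

Four reference configurations ship with the package (a clinic
cross-sectional study, a household surveillance program, and two
randomized trials); `buildFixture()` writes the CSV workbook and compiles
it through the normal loader:

```r
library(edcflow)
fx <- buildFixture("surveillance-like", dir = "workbook")
defn <- fx$definition
defn
#> <edc_study_definition> PS (v1)
#>   CRFs: 9 | scheduled visits: 2 | criteria: 3 | triggers: 1
#>   consent bands: 2 | languages: en, te

store <- createStore(defn, device_code = "01")
addUser(store, "dm", "dm-pw", "data-manager")
dm <- authenticate(store, "dm", "dm-pw")
addUser(store, "asha", "field-pw", "research-assistant", session = dm)
ra <- authenticate(store, "asha", "field-pw")

hh  <- registerHousehold(store, defn, ra)
pid <- registerParticipant(store, defn, ra,
                           dobPartial(as.integer(format(Sys.Date(), "%Y")) - 18),
                           household_id = hh)
c(hh, pid)
#> [1] "HH010001" "PS010002"
```

The participant's birth year is known but not the day, so the engine uses
the *youngest possible* age (here 17): the ambiguous 17/18-year-old is
routed to assent plus parental consent, never prematurely to the adult
form, and the progression gate offers only the pre-consent forms and that
routed consent set:

```r
requiredConsentForms(store, defn, pid)
#> [1] "assent_adolescent" "consent_parental"
instantiateSchedule(store, defn, ra, pid)
gateProgression(store, defn, pid)
#> [1] "assent_adolescent" "consent_parental"  "household_form"
#> [4] "recruitment"       "screening"
```

Completing the screening form evaluates eligibility immediately:

```r
key <- paste(pid, "screening_visit", "screening", 1, sep = "|")
enterValue(store, defn, ra, key, "pregnant", "0")
enterValue(store, defn, ra, key, "lactating", "0")
completeCrf(store, defn, ra, key)
eligibilityReport(store, defn, pid)
#>       criterion_id status                                       description ...
#> 1 reproductive_age   pass Woman of reproductive age (15-40 completed years)
#> 2     not_pregnant   pass                            Not currently pregnant
#> 3    not_lactating   pass                           Not currently lactating
```

An implausible (but possible) value raises an acknowledgeable warning;
an impossible one blocks storage outright:

```r
checkValue(defn$crfs$anthropometry$variables$weight_kg, 1)[[1]]$message
#> [1] "weight_kg = 1 is outside the anticipated range [25, 200]"
```

`simulateSessions()` drives whole multi-device field days against any
fixture — registration, gated entry with injected errors, signing,
allocation from per-device randomization-table blocks, end-of-day sync —
fully reproducible from a seed.

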