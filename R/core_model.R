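#' @title Core domain types
#' @description Constructors for the records the engine evaluates: patients,
#'   pregnancy episodes, Child-Pugh inputs, laboratory results and
#'   prescriptions. Constructors do light coercion only; full invariant
#'   checking is the job of [validate_record()], which returns findings
#'   instead of raising, so a batch of records can be triaged in one pass.
#' @name core_model
NULL

# Canonical reporting unit per analyte. Unknown analytes are allowed (the KB
# can grow); they simply have no canonical unit to check against.
.canonical_units <- c(
  Cr = "mg/dl", AST = "U/L", ALT = "U/L", Bili_total = "mg/dl",
  Na = "mEq/L", K = "mEq/L", Mg = "mg/dl", Cl = "mEq/L",
  UricAcid = "mg/dl", VitB12 = "pg/mL", bHCG = "mIU/mL"
)

#' Canonical unit for an analyte
#'
#' ALT is reported in U/L throughout; the occasional "U/mL" spelling seen in
#' drug references is treated as a typographical variant of U/L and
#' normalised on input.
#'
#' @param analyte analyte code, e.g. `"Cr"`, `"ALT"`.
#' @return the canonical unit string, or `NA` for analytes the engine does
#'   not know.
#' @export
canonical_unit <- function(analyte) {
  u <- .canonical_units[analyte]
  unname(u)
}

normalize_unit <- function(unit) {
  u <- trimws(unit)
  u[tolower(u) %in% c("u/ml", "u/l")] <- "U/L"
  u
}

#' Construct a patient record
#'
#' @param patient_id opaque identifier string.
#' @param sex `"male"` or `"female"`.
#' @param birth_date calendar date of birth (Date or ISO string).
#' @param weight body weight in kg (positive).
#' @param height height in cm, or `NULL` if unknown.
#' @param pregnancy optional [pregnancy_record()]; only legal for females.
#' @param cirrhosis_history logical: documented cirrhotic liver disease.
#' @param child_pugh_inputs optional [child_pugh_inputs()].
#' @return an object of class `dli_patient`.
#' @examples
#' patient_record("p1", "female", "1980-05-01", weight = 65, height = 162)
#' @export
patient_record <- function(patient_id, sex, birth_date, weight,
                           height = NULL, pregnancy = NULL,
                           cirrhosis_history = FALSE,
                           child_pugh_inputs = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  structure(list(
    patient_id = as.character(patient_id),
    sex = sex,
    birth_date = as_date(birth_date),
    weight = as.numeric(weight),
    height = if (!is.null(height)) as.numeric(height),
    pregnancy = pregnancy,
    cirrhosis_history = isTRUE(cirrhosis_history),
    child_pugh_inputs = child_pugh_inputs
  ), class = "dli_patient")
}

#' Construct a pregnancy episode record
#'
#' Marks the date positive pregnancy evidence was recorded and, optionally,
#' the recorded termination date. Alert activity derived from this record is
#' governed by [pregnancy_alert_active()].
#'
#' @param detected_date date of positive pregnancy evidence.
#' @param termination_date optional recorded termination date (must not
#'   precede `detected_date`).
#' @return an object of class `dli_pregnancy`.
#' @export
pregnancy_record <- function(detected_date, termination_date = NULL) {
  structure(list(
    detected_date = as_date(detected_date),
    termination_date = if (!is.null(termination_date)) as_date(termination_date)
  ), class = "dli_pregnancy")
}

#' Construct Child-Pugh scoring inputs
#'
#' The five standard parameters of hepatic disease severity.
#'
#' @param bilirubin_total total bilirubin, mg/dl.
#' @param albumin serum albumin, g/dl.
#' @param inr international normalised ratio.
#' @param ascites `"none"`, `"mild"`, or `"moderate_severe"`.
#' @param encephalopathy `"none"`, `"grade1_2"`, or `"grade3_4"`.
#' @return an object of class `dli_child_pugh_inputs`.
#' @export
child_pugh_inputs <- function(bilirubin_total, albumin, inr,
                              ascites = c("none", "mild", "moderate_severe"),
                              encephalopathy = c("none", "grade1_2", "grade3_4")) {
  structure(list(
    bilirubin_total = as.numeric(bilirubin_total),
    albumin = as.numeric(albumin),
    inr = as.numeric(inr),
    ascites = match.arg(ascites),
    encephalopathy = match.arg(encephalopathy)
  ), class = "dli_child_pugh_inputs")
}

#' Construct a laboratory result
#'
#' @param analyte analyte code (`"Cr"`, `"AST"`, `"ALT"`, `"Bili_total"`,
#'   `"Na"`, `"K"`, `"Mg"`, `"Cl"`, `"UricAcid"`, `"VitB12"`, `"bHCG"`, or
#'   any extension the knowledge base declares).
#' @param value measured value in the canonical unit (non-negative).
#' @param unit unit string; checked against the analyte's canonical unit
#'   after normalisation ("U/mL" is accepted as U/L).
#' @param observed_at observation date.
#' @param positive optional logical flag for qualitative results (used for
#'   pregnancy tests); `NA` when not applicable.
#' @return an object of class `dli_lab`.
#' @export
lab_result <- function(analyte, value, unit = canonical_unit(analyte),
                       observed_at, positive = NA) {
  if (is.na(unit) || is.null(unit)) unit <- NA_character_
  structure(list(
    analyte = as.character(analyte),
    value = as.numeric(value),
    unit = normalize_unit(as.character(unit)),
    observed_at = as_date(observed_at),
    positive = as.logical(positive)
  ), class = "dli_lab")
}

#' Construct a prescription event
#'
#' @param medication_id medication name as listed in the knowledge base's
#'   catalog (unknown medications are legal but generate no alerts).
#' @param start_date date of the prescription event.
#' @param event_kind `"new"`, `"refill"`, or `"revision"` — every kind
#'   triggers re-evaluation.
#' @param dose optional free-text dose (amount + unit).
#' @param frequency optional free-text per-day schedule.
#' @return an object of class `dli_prescription`.
#' @export
prescription <- function(medication_id, start_date,
                         event_kind = c("new", "refill", "revision"),
                         dose = NULL, frequency = NULL) {
  structure(list(
    medication_id = as.character(medication_id),
    start_date = as_date(start_date),
    event_kind = match.arg(event_kind),
    dose = dose,
    frequency = frequency
  ), class = "dli_prescription")
}

finding <- function(record, invariant, severity = c("error", "warning")) {
  severity <- match.arg(severity)
  list(record = record, invariant = invariant, severity = severity)
}

#' Validate a patient bundle against the domain invariants
#'
#' Pure and idempotent: the same input always yields the same findings, and
#' nothing is raised — malformed records come back as a list of findings,
#' each naming the record, the violated invariant and a severity. A bundle
#' with no `error`-severity findings is guaranteed processable by
#' [evaluate()]. Unknown analytes and medications yield warnings, not
#' errors, so the knowledge base can grow without breaking ingestion.
#'
#' @param patient a [patient_record()].
#' @param labs list of [lab_result()]s.
#' @param prescriptions list of [prescription()]s.
#' @param as_of evaluation date the age invariant is checked against.
#' @param kb optional [knowledge_base]; when given, prescriptions for
#'   medications outside its catalog produce warnings.
#' @return list of findings (empty when everything holds); each finding has
#'   `$record`, `$invariant`, `$severity`.
#' @examples
#' p <- patient_record("p1", "female", "1980-05-01", weight = 65)
#' validate_record(p, list(), list(), as_of = "2020-06-01")  # list()
#' @export
validate_record <- function(patient, labs = list(), prescriptions = list(),
                            as_of, kb = NULL) {
  as_of <- as_date(as_of)
  out <- list()
  add <- function(f) out[[length(out) + 1L]] <<- f

  if (!inherits(patient, "dli_patient"))
    return(list(finding("patient", "not a dli_patient object", "error")))

  pid <- patient$patient_id
  if (!is.finite(patient$weight) || patient$weight <= 0)
    add(finding(pid, "weight must be > 0 kg", "error"))
  if (!is.null(patient$height) &&
      (!is.finite(patient$height) || patient$height < 100 || patient$height > 250))
    add(finding(pid, "height must lie in [100, 250] cm", "error"))
  age <- age_at(patient$birth_date, as_of)
  if (age < 18)
    add(finding(pid, sprintf("age %d at %s is below the adult outpatient scope (>= 18)",
                             age, format(as_of)), "error"))
  if (!is.null(patient$pregnancy)) {
    if (patient$sex != "female")
      add(finding(pid, "pregnancy record present on a non-female patient", "error"))
    pr <- patient$pregnancy
    if (!is.null(pr$termination_date) && pr$termination_date < pr$detected_date)
      add(finding(pid, "pregnancy termination_date precedes detected_date", "error"))
  }
  if (!is.null(patient$child_pugh_inputs)) {
    cp <- patient$child_pugh_inputs
    num <- c(cp$bilirubin_total, cp$albumin, cp$inr)
    if (any(!is.finite(num) | num <= 0))
      add(finding(pid, "Child-Pugh numeric inputs must be positive", "error"))
  }

  for (i in seq_along(labs)) {
    lab <- labs[[i]]
    tag <- sprintf("lab[%d] %s@%s", i, lab$analyte, format(lab$observed_at))
    if (!is.finite(lab$value) || lab$value < 0)
      add(finding(tag, "lab value must be >= 0", "error"))
    cu <- canonical_unit(lab$analyte)
    if (is.na(cu)) {
      add(finding(tag, sprintf("unknown analyte '%s'", lab$analyte), "warning"))
    } else if (!is.na(lab$unit) && lab$unit != cu) {
      add(finding(tag, sprintf("unit '%s' does not match canonical '%s'",
                               lab$unit, cu), "error"))
    }
  }

  known_meds <- if (!is.null(kb)) kb$medication_catalog$name else NULL
  for (i in seq_along(prescriptions)) {
    rx <- prescriptions[[i]]
    tag <- sprintf("prescription[%d] %s", i, rx$medication_id)
    if (!is.null(known_meds) && !(rx$medication_id %in% known_meds))
      add(finding(tag, "medication not in knowledge-base catalog (no alerts will fire)",
                  "warning"))
  }
  out
}

#' @export
print.dli_patient <- function(x, ...) {
  cat(sprintf("<patient %s: %s, born %s, %.1f kg%s%s%s>\n",
              x$patient_id, x$sex, format(x$birth_date), x$weight,
              if (!is.null(x$height)) sprintf(", %.0f cm", x$height) else "",
              if (!is.null(x$pregnancy)) ", pregnant" else "",
              if (x$cirrhosis_history) ", cirrhosis" else ""))
  invisible(x)
}

#' @export
print.dli_lab <- function(x, ...) {
  cat(sprintf("<lab %s = %g %s on %s>\n", x$analyte, x$value,
              ifelse(is.na(x$unit), "", x$unit), format(x$observed_at)))
  invisible(x)
}
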