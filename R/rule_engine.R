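#' @title Alert evaluation engine
#' @description Matches a patient's derived state (renal, hepatic,
#'   pregnancy, raw labs) and active prescriptions against a knowledge
#'   base as of a given instant and emits fully rendered, severity-graded,
#'   display-classified alerts. Evaluation is deterministic: identical
#'   inputs and configuration produce identical alert lists.
#' @name rule_engine
NULL

#' Engine configuration
#'
#' @param lab_window_months lookback for historical lab values (calendar
#'   months, default 6).
#' @param pregnancy_expiry_months pregnancy alerts expire this many months
#'   after detection (default 9).
#' @param bsa_normalize normalise CrCl to 1.73 m^2 body surface area
#'   (default off: raw Cockcroft-Gault output is compared to thresholds).
#' @param crcl_weight `"actual"` (default) or `"lbm"`: which weight feeds
#'   Cockcroft-Gault.
#' @param default_monitor_interval_months repeat interval for monitoring
#'   rules that specify none (default 6).
#' @param bhcg_positive_threshold quantitative bHCG (mIU/mL) above which a
#'   pregnancy test without a qualitative flag counts as positive.
#' @param cirrhosis_implies_severe,child_pugh_c_implies_severe hepatic-tier
#'   triangulation toggles (see [hepatic_state()]).
#' @param kb_path,log_path optional file paths used by the CLI.
#' @return object of class `dli_config`.
#' @export
engine_config <- function(lab_window_months = 6, pregnancy_expiry_months = 9,
                          bsa_normalize = FALSE,
                          crcl_weight = c("actual", "lbm"),
                          default_monitor_interval_months = 6,
                          bhcg_positive_threshold = 5,
                          cirrhosis_implies_severe = TRUE,
                          child_pugh_c_implies_severe = TRUE,
                          kb_path = NULL, log_path = NULL) {
  crcl_weight <- match.arg(crcl_weight)
  months <- c(lab_window_months, pregnancy_expiry_months,
              default_monitor_interval_months)
  if (any(!is.finite(months) | months <= 0))
    stop("all month-valued configuration fields must be positive", call. = FALSE)
  structure(list(
    lab_window_months = lab_window_months,
    pregnancy_expiry_months = pregnancy_expiry_months,
    bsa_normalize = bsa_normalize, crcl_weight = crcl_weight,
    default_monitor_interval_months = default_monitor_interval_months,
    bhcg_positive_threshold = bhcg_positive_threshold,
    cirrhosis_implies_severe = cirrhosis_implies_severe,
    child_pugh_c_implies_severe = child_pugh_c_implies_severe,
    kb_path = kb_path, log_path = log_path
  ), class = "dli_config")
}

#' Most recent in-window laboratory result for an analyte
#'
#' The lookback window is half-open: `(as_of - window, as_of]`. A result
#' exactly `window_months` calendar months old is excluded.
#'
#' @param labs list of [lab_result()]s.
#' @param analyte analyte code.
#' @param as_of evaluation date.
#' @param window_months window width in calendar months (default 6).
#' @return the most recent matching `dli_lab`, or `NULL` if none.
#' @export
latest_lab <- function(labs, analyte, as_of, window_months = 6) {
  as_of <- as_date(as_of)
  hits <- Filter(function(l) l$analyte == analyte &&
                   within_window(l$observed_at, as_of, window_months), labs)
  if (!length(hits)) return(NULL)
  dates <- vapply(hits, function(l) as.numeric(l$observed_at), numeric(1))
  hits[[which.max(dates)]]
}

#' @describeIn latest_lab is the patient pregnant as of `as_of`? True when
#'   an unexpired pregnancy episode is on record (see
#'   [pregnancy_alert_active()]) or the latest in-window bHCG result is
#'   positive (qualitative flag, or value above the configured threshold).
#' @param patient a [patient_record()].
#' @param config an [engine_config()].
#' @export
is_pregnant <- function(patient, labs, as_of, config = engine_config()) {
  if (patient$sex != "female") return(FALSE)
  if (!is.null(patient$pregnancy) &&
      pregnancy_alert_active(patient$pregnancy, as_of,
                             expiry_months = config$pregnancy_expiry_months))
    return(TRUE)
  hcg <- latest_lab(labs, "bHCG", as_of, config$lab_window_months)
  if (is.null(hcg)) return(FALSE)
  if (!is.na(hcg$positive)) return(isTRUE(hcg$positive))
  hcg$value > config$bhcg_positive_threshold
}

# Derived state snapshot the predicates are evaluated against.
derive_state <- function(patient, labs, as_of, config) {
  as_of <- as_date(as_of)
  renal <- NULL
  cr <- latest_lab(labs, "Cr", as_of, config$lab_window_months)
  if (!is.null(cr) && cr$value > 0) {
    w <- patient$weight
    if (config$crcl_weight == "lbm" && !is.null(patient$height))
      w <- lean_body_mass(patient$sex, patient$weight, patient$height)$lbm
    renal <- creatinine_clearance(
      age = age_at(patient$birth_date, as_of), weight = w, sex = patient$sex,
      serum_cr = cr$value, cr_observed_at = cr$observed_at,
      bsa_normalize = config$bsa_normalize, height = patient$height)
  }
  hepatic <- hepatic_state(
    labs, cirrhosis_history = patient$cirrhosis_history,
    cp = patient$child_pugh_inputs, as_of = as_of,
    window_months = config$lab_window_months,
    cirrhosis_implies_severe = config$cirrhosis_implies_severe,
    child_pugh_c_implies_severe = config$child_pugh_c_implies_severe)
  list(renal = renal, hepatic = hepatic,
       pregnant = is_pregnant(patient, labs, as_of, config),
       cr_lab = cr, as_of = as_of)
}

.tier_rank <- c(normal = 0L, impaired = 1L, severe = 2L)

eval_predicate <- function(pred, state, patient, labs, config, rule_id = "?") {
  ev <- function(node) {
    switch(node$type,
      always = TRUE,
      crcl_in = {
        if (is.null(state$renal)) return(FALSE)  # no in-window Cr: renal rules do not fire
        x <- state$renal$crcl
        lo_ok <- if (isTRUE(node$lo_inclusive)) x >= node$lo else x > node$lo
        hi_ok <- if (isTRUE(node$hi_inclusive)) x <= node$hi else x < node$hi
        lo_ok && hi_ok
      },
      hepatic_tier_at_least =
        .tier_rank[[state$hepatic$tier]] >= .tier_rank[[node$tier]],
      pregnant = state$pregnant,
      sex_is = patient$sex == node$sex,
      lab_cmp = {
        lab <- latest_lab(labs, node$analyte, state$as_of, config$lab_window_months)
        if (is.null(lab)) return(FALSE)
        do.call(node$op, list(lab$value, node$threshold))
      },
      lab_missing = is.null(latest_lab(labs, node$analyte, state$as_of,
                                       node$within_months %||% config$lab_window_months)),
      and = all(vapply(node$args, ev, logical(1))),
      or = any(vapply(node$args, ev, logical(1))),
      not = !ev(node$args[[1]]),
      stop(sprintf("rule '%s': predicate atom '%s' cannot be derived by this engine",
                   rule_id, node$type), call. = FALSE)
    )
  }
  ev(pred)
}

#' Interruptive or informational?
#'
#' Alerts interrupt the prescribing workflow (pop-up requiring a reaction)
#' only at severity level 1 — when a medication must be stopped or its
#' dose adjusted. Levels 2 and 3 are informational visual clues.
#'
#' @param severity integer 1, 2 or 3.
#' @return `"interruptive"` for 1, `"informational"` for 2 and 3.
#' @export
classify_display <- function(severity) {
  if (!(length(severity) == 1L && severity %in% 1:3))
    stop("severity must be 1, 2 or 3", call. = FALSE)
  if (severity == 1L) "interruptive" else "informational"
}

.severity_color <- c("red", "orange", "yellow")

#' Render an alert message from a rule's template
#'
#' The rendered text always carries the medication name and the
#' recommendation; for lab-triggered rules it also embeds the triggering
#' analyte's name, value with unit, and ISO date. Rendering is strict: a
#' placeholder left without a bound value is an error — the engine never
#' emits a literal `{lab_value}`.
#'
#' @param rule a [rule()].
#' @param patient a [patient_record()] (available to templates as context).
#' @param triggering_lab the `dli_lab` justifying the alert, or `NULL` for
#'   rules without one (e.g. monitoring with no result yet).
#' @param extra named character vector of additional bindings (e.g. a
#'   derived CrCl annotation appended to the lab value).
#' @return rendered message text.
#' @export
render_alert_message <- function(rule, patient, triggering_lab = NULL,
                                 extra = character()) {
  bindings <- c(medication = rule$medication,
                recommendation = rule$action$text, extra)
  if (!is.null(triggering_lab)) {
    unit <- if (is.na(triggering_lab$unit)) "" else paste0(" ", triggering_lab$unit)
    bindings <- c(bindings,
      lab_name = triggering_lab$analyte,
      lab_value = sprintf("%g%s", triggering_lab$value, unit),
      lab_date = format(triggering_lab$observed_at, "%Y-%m-%d"))
  }
  out <- rule$message_template
  for (nm in names(bindings))
    out <- gsub(paste0("{", nm, "}"), bindings[[nm]], out, fixed = TRUE)
  leftover <- regmatches(out, gregexpr("\\{[a-z_]+\\}", out))[[1]]
  if (length(leftover))
    stop(sprintf("rule '%s': unbound placeholder(s) %s in message template",
                 rule$rule_id, paste(leftover, collapse = ", ")), call. = FALSE)
  out
}

make_alert <- function(rule, patient, state, triggering_lab, reason, message) {
  severity <- rule$severity
  structure(list(
    alert_id = sprintf("%s|%s|%s", patient$patient_id, rule$rule_id,
                       format(state$as_of, "%Y-%m-%d")),
    rule_id = rule$rule_id,
    patient_id = patient$patient_id,
    medication = rule$medication,
    category = rule$category,
    severity_level = severity,
    color = .severity_color[severity],
    display_mode = classify_display(severity),
    recommendation = rule$action$text,
    reason = reason,
    message = message,
    lab = if (!is.null(triggering_lab)) list(
      analyte = triggering_lab$analyte, value = triggering_lab$value,
      unit = triggering_lab$unit,
      observed_at = format(triggering_lab$observed_at, "%Y-%m-%d")),
    evaluated_at = format(state$as_of, "%Y-%m-%d")
  ), class = "dli_alert")
}

# Which lab justifies a firing rule? Renal rules cite the serum creatinine
# behind the CrCl; hepatic rules the strongest in-window liver evidence;
# pregnancy rules the bHCG result when one triggered; monitoring rules the
# latest result of their first monitored analyte, if any.
triggering_lab_for <- function(rule, state, labs, config) {
  switch(rule$category,
    renal = state$cr_lab,
    hepatic = {
      ev <- Filter(function(e) e$source %in% c("ALT", "AST", "Bili_total"),
                   state$hepatic$evidence)
      if (length(ev)) latest_lab(labs, ev[[1]]$source, state$as_of,
                                 config$lab_window_months)
      else NULL
    },
    pregnancy = latest_lab(labs, "bHCG", state$as_of, config$lab_window_months),
    monitoring = {
      hits <- lapply(rule$action$analytes, latest_lab, labs = labs,
                     as_of = state$as_of, window_months = config$lab_window_months)
      hits <- Filter(Negate(is.null), hits)
      if (length(hits)) hits[[1]] else NULL
    }
  )
}

reason_for <- function(rule, state, triggering_lab) {
  switch(rule$category,
    renal = {
      lab <- triggering_lab
      sprintf("CrCl %.1f ml/min (Cr %g mg/dl on %s)", state$renal$crcl,
              lab$value, format(lab$observed_at, "%Y-%m-%d"))
    },
    hepatic = {
      if (length(state$hepatic$evidence))
        paste(vapply(state$hepatic$evidence, function(e)
          sprintf("%s (%s)", e$criterion,
                  if (is.logical(e$value)) "history" else format(e$value)), ""),
          collapse = "; ")
      else "hepatic impairment"
    },
    pregnancy = if (!is.null(triggering_lab))
      sprintf("positive pregnancy test (bHCG on %s)",
              format(triggering_lab$observed_at, "%Y-%m-%d"))
    else "active pregnancy on record",
    monitoring = if (!is.null(triggering_lab))
      sprintf("latest %s = %g on %s", triggering_lab$analyte,
              triggering_lab$value, format(triggering_lab$observed_at, "%Y-%m-%d"))
    else "no recent result on file (baseline needed)"
  )
}

#' Evaluate a patient against the knowledge base
#'
#' For each active prescription resolvable in the KB catalog, every rule
#' for that medication whose trigger holds against the derived state (CrCl
#' from the latest in-window creatinine, hepatic tier, pregnancy status,
#' latest in-window analyte values) yields exactly one alert. Renal rules
#' do not fire when no in-window serum creatinine exists. Alerts are
#' deterministic and ordered by (medication, severity ascending, rule_id);
#' multiple alerts for one medication are thereby grouped together, ready
#' for single-screen display.
#'
#' @param patient a [patient_record()].
#' @param labs list of [lab_result()]s.
#' @param prescriptions list of [prescription()]s.
#' @param kb a [knowledge_base()].
#' @param as_of evaluation date.
#' @param config an [engine_config()].
#' @return object of class `dli_alerts`: list of `dli_alert`s.
#' @examples
#' kb <- seeded_kb()
#' p <- patient_record("p1", "male", "1980-01-15", weight = 72)
#' labs <- list(lab_result("Cr", 4.8, observed_at = "2020-05-20"))
#' rx <- list(prescription("Allopurinol", "2020-06-01"))
#' evaluate(p, labs, rx, kb, as_of = "2020-06-01")
#' @export
evaluate <- function(patient, labs, prescriptions, kb, as_of,
                     config = engine_config()) {
  as_of <- as_date(as_of)
  findings <- validate_record(patient, labs, prescriptions, as_of, kb)
  errs <- Filter(function(f) f$severity == "error", findings)
  if (length(errs))
    stop("record fails validation: ",
         paste(vapply(errs, function(f) sprintf("%s: %s", f$record, f$invariant), ""),
               collapse = "; "), call. = FALSE)

  state <- derive_state(patient, labs, as_of, config)
  meds <- unique(vapply(prescriptions, `[[`, "", "medication_id"))
  meds <- intersect(meds, kb$medication_catalog$name)

  alerts <- list()
  for (r in kb$rules) {
    if (!(r$medication %in% meds)) next
    if (!eval_predicate(r$trigger, state, patient, labs, config, r$rule_id)) next
    lab <- triggering_lab_for(r, state, labs, config)
    # lab-bearing templates fall back to the plain template when no lab exists
    rule_r <- r
    if (is.null(lab) && grepl("{lab_value}", r$message_template, fixed = TRUE))
      rule_r$message_template <- .nolab_template
    msg <- render_alert_message(rule_r, patient, lab)
    reason <- reason_for(r, state, lab)
    alerts[[length(alerts) + 1L]] <- make_alert(r, patient, state, lab, reason, msg)
  }

  ord <- order(vapply(alerts, `[[`, "", "medication"),
               vapply(alerts, `[[`, 1L, "severity_level"),
               vapply(alerts, `[[`, "", "rule_id"))
  structure(alerts[ord], class = "dli_alerts")
}

#' Level-3 reminders for missing or overdue monitored labs
#'
#' For each monitor-action rule of each active prescription, checks every
#' monitored analyte against the rule's schedule: an analyte with no
#' in-window result is requested as a baseline/initial test once its due
#' date (prescription start plus offset, or the start itself when the
#' schedule asks for a baseline) has passed; an analyte whose latest
#' result is older than the repeat interval is requested as overdue. One
#' level-3 informational alert is emitted per rule with outstanding
#' analytes.
#'
#' @inheritParams evaluate
#' @return a `dli_alerts` list (possibly empty).
#' @export
missing_baseline_alerts <- function(patient, labs, prescriptions, kb, as_of,
                                    config = engine_config()) {
  as_of <- as_date(as_of)
  state <- list(as_of = as_of)
  meds <- vapply(prescriptions, `[[`, "", "medication_id")
  alerts <- list()

  for (r in kb$rules) {
    if (r$action$kind != "monitor") next
    idx <- which(meds == r$medication)
    if (!length(idx)) next
    start <- min(do.call(c, lapply(prescriptions[idx], `[[`, "start_date")))
    sch <- r$action$schedule %||% list()
    due <- character()
    for (a in r$action$analytes) {
      lab <- latest_lab(labs, a, as_of, config$lab_window_months)
      if (is.null(lab)) {
        # never measured in-window: due at start (baseline) or start + offset
        due_date <- if (isTRUE(sch$baseline)) start
                    else if (!is.null(sch$offset_days)) start + sch$offset_days
                    else add_months(start, sch$repeat_months %||%
                                      config$default_monitor_interval_months)
        if (as_of >= due_date)
          due <- c(due, sprintf("%s (baseline/initial test due %s)", a, format(due_date)))
      } else {
        next_due <- if (!is.null(sch$repeat_months)) add_months(lab$observed_at, sch$repeat_months)
                    else if (!is.null(sch$repeat_days)) lab$observed_at + sch$repeat_days
                    else NULL
        if (!is.null(next_due) && as_of > next_due)
          due <- c(due, sprintf("%s (last %s, repeat was due %s)", a,
                                format(lab$observed_at), format(next_due)))
      }
    }
    if (!length(due)) next
    reason <- paste("outstanding monitored lab test(s):", paste(due, collapse = "; "))
    msg <- sprintf("%s: request %s. %s", r$medication,
                   paste(vapply(strsplit(due, " "), `[[`, "", 1L), collapse = ", "),
                   r$action$text)
    al <- make_alert(r, patient, state, NULL, reason, msg)
    al$alert_id <- paste0(al$alert_id, "|due")
    alerts[[length(alerts) + 1L]] <- al
  }
  ord <- order(vapply(alerts, `[[`, "", "medication"),
               vapply(alerts, `[[`, "", "rule_id"))
  structure(alerts[ord], class = "dli_alerts")
}

#' @export
print.dli_alert <- function(x, ...) {
  cat(sprintf("[%s|L%d|%s] %s\n    %s\n", toupper(x$color), x$severity_level,
              x$display_mode, x$message, x$reason))
  invisible(x)
}

#' @export
print.dli_alerts <- function(x, ...) {
  if (!length(x)) {
    cat("<no alerts>\n")
    return(invisible(x))
  }
  cat(sprintf("%d alert(s):\n", length(x)))
  for (a in x) print(a)
  invisible(x)
}

#' @export
format.dli_alerts <- function(x, ...) {
  vapply(x, `[[`, "", "message")
}

#' @export
as.data.frame.dli_alerts <- function(x, ...) {
  if (!length(x))
    return(data.frame(alert_id = character(), rule_id = character(),
                      patient_id = character(), medication = character(),
                      category = character(), severity_level = integer(),
                      color = character(), display_mode = character(),
                      message = character(), evaluated_at = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(x, function(a)
    data.frame(alert_id = a$alert_id, rule_id = a$rule_id,
               patient_id = a$patient_id, medication = a$medication,
               category = a$category, severity_level = a$severity_level,
               color = a$color, display_mode = a$display_mode,
               message = a$message, evaluated_at = a$evaluated_at,
               stringsAsFactors = FALSE)))
}
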