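#' @title Declarative rule knowledge base
#' @description The knowledge-base atom is a `Rule`: one medication, one
#'   trigger predicate over derived patient state, one recommended action,
#'   a clinical severity level (1 fatal/life-threatening, 2 serious,
#'   3 monitoring) and a message template. Rules live in a YAML (canonical)
#'   or JSON file; [seeded_kb()] builds the shipped eight-medication set in
#'   code. Predicates and actions are plain nested lists so a KB
#'   round-trips through its file format without loss.
#' @name knowledgebase
NULL

## ---- predicate atoms -------------------------------------------------------

#' Predicate atoms and combinators
#'
#' Triggers are boolean expression trees over a small atom vocabulary:
#' creatinine-clearance bands, hepatic tier, pregnancy, raw lab
#' comparisons, sex, and lab absence; combined with `p_and()`, `p_or()`,
#' `p_not()`. `p_always()` is the trigger of monitoring rules that fire
#' with every prescription of their medication.
#'
#' @param lo,hi band bounds, ml/min; `lo < hi` required.
#' @param lo_inclusive,hi_inclusive include the boundary? Comparisons are
#'   otherwise strict, matching how guideline thresholds are written.
#' @param tier minimum hepatic tier: `"impaired"` or `"severe"`.
#' @param analyte analyte code.
#' @param op one of `<`, `<=`, `>`, `>=`.
#' @param threshold positive numeric threshold in `unit`.
#' @param unit canonical unit string.
#' @param sex `"male"` or `"female"`.
#' @param within_months lookback for `lab_missing`.
#' @param ... sub-predicates.
#' @param x a predicate to negate.
#' @return a predicate node (plain list with a `type` field).
#' @export
crcl_in <- function(lo, hi, lo_inclusive = TRUE, hi_inclusive = FALSE) {
  stopifnot(lo < hi)
  list(type = "crcl_in", lo = lo, hi = hi,
       lo_inclusive = lo_inclusive, hi_inclusive = hi_inclusive)
}

#' @rdname crcl_in
#' @export
hepatic_tier_at_least <- function(tier = c("impaired", "severe"))
  list(type = "hepatic_tier_at_least", tier = match.arg(tier))

#' @rdname crcl_in
#' @export
pregnant <- function() list(type = "pregnant")

#' @rdname crcl_in
#' @export
lab_cmp <- function(analyte, op, threshold, unit = canonical_unit(analyte)) {
  stopifnot(op %in% c("<", "<=", ">", ">="), threshold > 0)
  list(type = "lab_cmp", analyte = analyte, op = op,
       threshold = threshold, unit = unit)
}

#' @rdname crcl_in
#' @export
sex_is <- function(sex) list(type = "sex_is", sex = match.arg(sex, c("male", "female")))

#' @rdname crcl_in
#' @export
lab_missing <- function(analyte, within_months = 6)
  list(type = "lab_missing", analyte = analyte, within_months = within_months)

#' @rdname crcl_in
#' @export
p_always <- function() list(type = "always")

#' @rdname crcl_in
#' @export
p_and <- function(...) list(type = "and", args = list(...))

#' @rdname crcl_in
#' @export
p_or <- function(...) list(type = "or", args = list(...))

#' @rdname crcl_in
#' @export
p_not <- function(x) list(type = "not", args = list(x))

## ---- actions ---------------------------------------------------------------

.action_kinds <- c("adjust_exact", "adjust_percent", "adjust_interval",
                   "adjust_cap", "initiate_dose", "avoid", "discontinue",
                   "caution", "monitor", "supplement", "adjust_exact_table")

# Action kinds for which interruptive severity-1 is permitted: stopping a
# medication or adjusting its dose.
.severity1_kinds <- c("discontinue", "avoid", "adjust_exact", "adjust_percent",
                      "adjust_interval", "adjust_cap", "adjust_exact_table")

#' Construct a rule action
#'
#' `kind` fixes the action taxonomy: exact dose, percent reduction,
#' interval extension, maximum-dose cap, starting dose, avoid, discontinue,
#' free-text caution, lab monitoring with a schedule, or supplementary
#' medication. `text` is the clinician-facing recommendation rendered into
#' the alert, stored verbatim (numerals exactly as in the source guidance).
#'
#' @param kind one of the action kinds above.
#' @param text verbatim recommendation text.
#' @param percent for `adjust_percent`: reduction in (0, 100).
#' @param dose,frequency for dose-bearing kinds: positive amount +
#'   free-text unit, e.g. `"200 mg/day"`.
#' @param analytes for `monitor`: character vector of analyte codes.
#' @param schedule for `monitor`: list with `baseline` (logical),
#'   `offset_days` (first check this many days after the start, optional),
#'   `repeat_months` or `repeat_days` (ongoing interval, optional),
#'   `note` (free text). At least one of baseline/offset/repeat required.
#' @param supplement_medication for `supplement`: medication name.
#' @return an action (plain list).
#' @export
rule_action <- function(kind, text, percent = NULL, dose = NULL,
                        frequency = NULL, analytes = NULL, schedule = NULL,
                        supplement_medication = NULL) {
  kind <- match.arg(kind, .action_kinds)
  if (kind == "adjust_percent") {
    stopifnot(!is.null(percent), percent > 0, percent < 100)
  }
  if (kind == "monitor") {
    stopifnot(!is.null(analytes), length(analytes) >= 1)
    if (is.null(schedule)) schedule <- list()
    has_any <- isTRUE(schedule$baseline) || !is.null(schedule$offset_days) ||
      !is.null(schedule$repeat_months) || !is.null(schedule$repeat_days)
    if (!has_any)
      stop("monitor schedule needs at least one of baseline/offset/repeat",
           call. = FALSE)
  }
  out <- list(kind = kind, text = text)
  for (nm in c("percent", "dose", "frequency", "analytes", "schedule",
               "supplement_medication")) {
    v <- get(nm)
    if (!is.null(v)) out[[nm]] <- v
  }
  out
}

## ---- rules and KB ----------------------------------------------------------

.default_template <-
  "{medication}: {recommendation} Reason: {lab_name} = {lab_value} on {lab_date}."
.nolab_template <- "{medication}: {recommendation}"

#' Construct a single IF/THEN rule
#'
#' @param rule_id unique opaque identifier.
#' @param medication medication name (must appear in the KB catalog).
#' @param atc WHO ATC category code.
#' @param category `"renal"`, `"hepatic"`, `"pregnancy"`, or `"monitoring"`.
#' @param severity integer 1..3; level 1 (interruptive) is only legal for
#'   stop/adjust action kinds.
#' @param trigger a predicate tree (see [crcl_in()]).
#' @param action a [rule_action()].
#' @param message_template alert template with placeholders
#'   `{medication}`, `{recommendation}`, `{lab_name}`, `{lab_value}`,
#'   `{lab_date}`. Defaults to a lab-bearing template for lab-triggered
#'   categories and a plain one for monitoring rules.
#' @return a rule (plain list).
#' @export
rule <- function(rule_id, medication, atc,
                 category = c("renal", "hepatic", "pregnancy", "monitoring"),
                 severity, trigger, action, message_template = NULL) {
  category <- match.arg(category)
  if (is.null(message_template))
    message_template <- if (category == "monitoring") .nolab_template else .default_template
  list(rule_id = rule_id, medication = medication, atc = atc,
       category = category, severity = as.integer(severity),
       trigger = trigger, action = action,
       message_template = message_template)
}

#' Construct a knowledge base
#'
#' @param rules list of [rule()]s.
#' @param medication_catalog data.frame with columns `atc`, `name`.
#' @param kb_version version string.
#' @return object of class `dli_kb`.
#' @seealso [seeded_kb()], [load_kb()], [validate_kb()]
#' @export
knowledge_base <- function(rules, medication_catalog, kb_version = "0") {
  structure(list(kb_version = as.character(kb_version), rules = rules,
                 medication_catalog = medication_catalog),
            class = "dli_kb")
}

#' @export
print.dli_kb <- function(x, ...) {
  cats <- table(vapply(x$rules, `[[`, "", "category"))
  cat(sprintf("<knowledge base v%s: %d medications, %d rules (%s)>\n",
              x$kb_version, nrow(x$medication_catalog), length(x$rules),
              paste(sprintf("%s %d", names(cats), cats), collapse = ", ")))
  invisible(x)
}

#' Validate an in-memory knowledge base
#'
#' Re-checks every KB invariant: unique rule ids, catalog-resolvable
#' medications, severity bounds, the severity-1/action-kind contract,
#' predicate well-formedness (bands with `lo < hi`, positive thresholds,
#' known atom types), action parameter bounds, monitor-schedule presence,
#' and pairwise-disjoint renal CrCl bands per medication.
#'
#' @param kb a [knowledge_base()].
#' @return list of findings (empty iff valid), each with `$rule_id`,
#'   `$field`, `$message`.
#' @export
validate_kb <- function(kb) {
  out <- list()
  add <- function(rule_id, field, message)
    out[[length(out) + 1L]] <<- list(rule_id = rule_id, field = field,
                                     message = message)
  ids <- vapply(kb$rules, `[[`, "", "rule_id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add(d, "rule_id", "duplicate rule_id")

  for (r in kb$rules) {
    if (!(r$medication %in% kb$medication_catalog$name))
      add(r$rule_id, "medication", sprintf("'%s' not in medication catalog", r$medication))
    if (!(r$severity %in% 1:3))
      add(r$rule_id, "severity", "severity must be 1, 2 or 3")
    if (r$severity == 1L && !(r$action$kind %in% .severity1_kinds))
      add(r$rule_id, "severity",
          sprintf("severity 1 not permitted for action kind '%s'", r$action$kind))
    for (msg in check_predicate(r$trigger)) add(r$rule_id, "trigger", msg)
    for (msg in check_action(r$action)) add(r$rule_id, "action", msg)
  }

  # renal CrCl bands must be pairwise disjoint per medication
  renal <- Filter(function(r) r$category == "renal", kb$rules)
  by_med <- split(renal, vapply(renal, `[[`, "", "medication"))
  for (med in names(by_med)) {
    bands <- lapply(by_med[[med]], function(r) {
      b <- collect_atoms(r$trigger, "crcl_in")
      if (length(b)) c(b[[1]], list(rule_id = r$rule_id))
    })
    bands <- Filter(Negate(is.null), bands)
    if (length(bands) > 1) {
      for (i in seq_len(length(bands) - 1)) for (j in seq((i + 1), length(bands))) {
        if (bands_overlap(bands[[i]], bands[[j]]))
          add(bands[[i]]$rule_id, "trigger",
              sprintf("renal CrCl band overlaps with rule '%s' for %s",
                      bands[[j]]$rule_id, med))
      }
    }
  }
  out
}

check_predicate <- function(p) {
  msgs <- character()
  walk <- function(node) {
    switch(node$type,
      crcl_in = {
        if (!(node$lo < node$hi)) msgs <<- c(msgs, "crcl_in band must have lo < hi")
      },
      lab_cmp = {
        if (!is.finite(node$threshold) || node$threshold <= 0)
          msgs <<- c(msgs, "lab_cmp threshold must be positive")
        if (!(node$op %in% c("<", "<=", ">", ">=")))
          msgs <<- c(msgs, sprintf("unknown comparison operator '%s'", node$op))
      },
      hepatic_tier_at_least = {
        if (!(node$tier %in% c("impaired", "severe")))
          msgs <<- c(msgs, sprintf("unknown hepatic tier '%s'", node$tier))
      },
      pregnant = NULL, sex_is = NULL, lab_missing = NULL, always = NULL,
      and = , or = , not = lapply(node$args, walk),
      msgs <<- c(msgs, sprintf("unknown predicate atom '%s'", node$type))
    )
  }
  walk(p)
  msgs
}

check_action <- function(a) {
  msgs <- character()
  if (!(a$kind %in% .action_kinds))
    return(sprintf("unknown action kind '%s'", a$kind))
  if (a$kind == "adjust_percent" &&
      (is.null(a$percent) || a$percent <= 0 || a$percent >= 100))
    msgs <- c(msgs, "adjust_percent requires percent in (0, 100)")
  if (a$kind == "monitor") {
    s <- a$schedule
    has_any <- isTRUE(s$baseline) || !is.null(s$offset_days) ||
      !is.null(s$repeat_months) || !is.null(s$repeat_days)
    if (!has_any) msgs <- c(msgs, "monitor schedule needs baseline/offset/repeat")
  }
  msgs
}

collect_atoms <- function(p, type) {
  found <- list()
  walk <- function(node) {
    if (identical(node$type, type)) found[[length(found) + 1L]] <<- node
    if (node$type %in% c("and", "or", "not")) lapply(node$args, walk)
  }
  walk(p)
  found
}

bands_overlap <- function(a, b) {
  # half-open-aware interval intersection
  lo <- max(a$lo, b$lo); hi <- min(a$hi, b$hi)
  if (lo < hi) return(TRUE)
  if (lo > hi) return(FALSE)
  # they touch at one point; overlap only if that point is inside both
  in_a <- (lo > a$lo || a$lo_inclusive) && (lo < a$hi || a$hi_inclusive)
  in_b <- (lo > b$lo || b$lo_inclusive) && (lo < b$hi || b$hi_inclusive)
  in_a && in_b
}

## ---- file I/O --------------------------------------------------------------

#' Load a knowledge base from YAML or JSON
#'
#' Loading is total: any invariant violation is collected by
#' [validate_kb()] and reported in a single error naming each offending
#' rule and field — never silently dropped.
#'
#' @param path file path; `.yaml`/`.yml` parsed with the YAML reader,
#'   anything else as JSON.
#' @return a validated `dli_kb`.
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stop("knowledge-base file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  kb_from_list(raw)
}

kb_from_list <- function(raw) {
  if (is.null(raw$rules)) raw$rules <- list()
  catalog <- do.call(rbind, lapply(raw$medication_catalog, function(m)
    data.frame(atc = m$atc, name = m$name, stringsAsFactors = FALSE)))
  if (is.null(catalog)) catalog <- data.frame(atc = character(), name = character())
  rules <- lapply(raw$rules, function(r) {
    r$severity <- as.integer(r$severity)
    r
  })
  kb <- knowledge_base(rules, catalog, kb_version = raw$kb_version %||% "0")
  findings <- validate_kb(kb)
  if (length(findings)) {
    msg <- vapply(findings, function(f)
      sprintf("[%s] %s: %s", f$rule_id, f$field, f$message), "")
    stop("invalid knowledge base:\n  ", paste(msg, collapse = "\n  "), call. = FALSE)
  }
  kb
}

#' Serialise a knowledge base to YAML or JSON
#'
#' Numerals are stored as given (no unit conversion at rest); a written KB
#' re-read with [load_kb()] is semantically identical.
#'
#' @param kb a `dli_kb`.
#' @param path destination; extension chooses the dialect as in [load_kb()].
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  raw <- list(
    kb_version = kb$kb_version,
    medication_catalog = lapply(seq_len(nrow(kb$medication_catalog)), function(i)
      list(atc = kb$medication_catalog$atc[i], name = kb$medication_catalog$name[i])),
    rules = kb$rules
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(raw, path)
  else
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- the seeded knowledge base ---------------------------------------------

#' The shipped eight-medication knowledge base
#'
#' Renal, hepatic, pregnancy and lab-monitoring rules for eight high-volume
#' kidney-transplant outpatient medications (Allopurinol, Azathioprine,
#' Captopril, Cyclosporine, Hydrochlorothiazide, Losartan, Mycophenolate,
#' Omeprazole), with recommendation text and thresholds carried verbatim
#' from the compiled prescribing guidance. Severity follows the display
#' contract: stop/adjust actions are level 1 (interruptive), starting-dose
#' and caution advice level 2, monitoring level 3. Curation choices
#' (documented in the package vignette): the qualitative Azathioprine
#' renal caution triggers below CrCl 60 ml/min; "monitor periodically"
#' defaults to every `default_monitor_interval_months`; "1-2 weeks after
#' the start" is scheduled at 14 days.
#'
#' @param default_monitor_interval_months repeat interval used where the
#'   guidance says only "periodically" (default 6).
#' @return a validated `dli_kb` with 8 medications and 25 rules.
#' @examples
#' kb <- seeded_kb()
#' print(kb)
#' @export
seeded_kb <- function(default_monitor_interval_months = 6) {
  catalog <- data.frame(
    atc = c("M04", "L04", "C09", "L04", "C03", "C09", "L04", "A02"),
    name = c("Allopurinol", "Azathioprine", "Captopril", "Cyclosporine",
             "Hydrochlorothiazide", "Losartan", "Mycophenolate", "Omeprazole"),
    stringsAsFactors = FALSE
  )
  hep_impaired <- hepatic_tier_at_least("impaired")
  hep_severe <- hepatic_tier_at_least("severe")
  dm <- default_monitor_interval_months

  rules <- list(
    ## Allopurinol (M04 antigout)
    rule("allopurinol-renal-10-20", "Allopurinol", "M04", "renal", 1,
         crcl_in(10, 20),
         rule_action("adjust_exact", "prescribe 200 mg/day per oral",
                     dose = "200 mg/day", frequency = "once daily")),
    rule("allopurinol-renal-3-10", "Allopurinol", "M04", "renal", 1,
         crcl_in(3, 10),
         rule_action("adjust_exact", "prescribe 100 mg/day per oral",
                     dose = "100 mg/day", frequency = "once daily")),
    rule("allopurinol-renal-lt3", "Allopurinol", "M04", "renal", 1,
         crcl_in(0, 3, lo_inclusive = FALSE),
         rule_action("adjust_interval",
                     paste("prescribe 100 mg per oral every 24 h or longer;",
                           "or 100 mg per oral every third day"),
                     dose = "100 mg", frequency = "every 24 h or longer")),
    rule("allopurinol-hepatic-caution", "Allopurinol", "M04", "hepatic", 2,
         hep_impaired,
         rule_action("caution",
                     "dosage adjustment may be necessary; no specific recommendations available")),
    rule("allopurinol-monitor-uricacid", "Allopurinol", "M04", "monitoring", 3,
         p_always(),
         rule_action("monitor",
                     paste("Monitor Uric acid level: if normal, check it every 6 months;",
                           "if abnormal, change Allopurinol dose accordingly"),
                     analytes = "UricAcid",
                     schedule = list(baseline = FALSE, repeat_months = 6))),

    ## Azathioprine (L04 immunosuppressant)
    rule("azathioprine-renal-caution", "Azathioprine", "L04", "renal", 2,
         crcl_in(0, 60, lo_inclusive = FALSE),
         rule_action("caution",
                     paste("renal impairment or oliguria: modify dosage depending on",
                           "clinical response and degree of renal impairment;",
                           "no quantitative recommendations are available"))),
    rule("azathioprine-pregnancy-discontinue", "Azathioprine", "L04", "pregnancy", 1,
         pregnant(), rule_action("discontinue", "Discontinue")),

    ## Captopril (C09 renin-angiotensin)
    rule("captopril-renal-10-50", "Captopril", "C09", "renal", 1,
         crcl_in(10, 50),
         rule_action("adjust_percent", "reduce the recommended dose by 25%",
                     percent = 25)),
    rule("captopril-renal-lt10", "Captopril", "C09", "renal", 1,
         crcl_in(0, 10, lo_inclusive = FALSE),
         rule_action("adjust_percent", "reduce the recommended dose by 50%",
                     percent = 50)),
    rule("captopril-pregnancy-discontinue", "Captopril", "C09", "pregnancy", 1,
         pregnant(), rule_action("discontinue", "Discontinue")),
    rule("captopril-monitor-na-k", "Captopril", "C09", "monitoring", 3,
         p_always(),
         rule_action("monitor",
                     "Monitor Na and K at the baseline and 1-2 weeks after the start",
                     analytes = c("Na", "K"),
                     schedule = list(baseline = TRUE, offset_days = 14))),

    ## Cyclosporine (L04 immunosuppressant)
    rule("cyclosporine-hepatic-monitor-level", "Cyclosporine", "L04", "hepatic", 2,
         hep_impaired,
         rule_action("caution",
                     paste("monitor Cyclosporine blood concentration level;",
                           "may require dose reduction based on concentration"))),
    rule("cyclosporine-monitor-uricacid-k-mg", "Cyclosporine", "L04", "monitoring", 3,
         p_always(),
         rule_action("monitor",
                     paste("Monitor Uric acid, K, and Mg levels every 2 weeks",
                           "in the first 3 months then monthly"),
                     analytes = c("UricAcid", "K", "Mg"),
                     schedule = list(baseline = FALSE, offset_days = 14,
                                     repeat_days = 14,
                                     note = "every 2 weeks in the first 3 months then monthly"))),

    ## Hydrochlorothiazide (C03 diuretic)
    rule("hydrochlorothiazide-renal-lt30", "Hydrochlorothiazide", "C03", "renal", 1,
         crcl_in(0, 30, lo_inclusive = FALSE),
         rule_action("avoid", "do not use")),
    rule("hydrochlorothiazide-hepatic-caution", "Hydrochlorothiazide", "C03", "hepatic", 2,
         hep_impaired,
         rule_action("caution",
                     paste("use with caution, since minor alteration of fluid and",
                           "electrolyte balance may precipitate hepatic coma"))),
    rule("hydrochlorothiazide-monitor-k-na-cl", "Hydrochlorothiazide", "C03",
         "monitoring", 3, p_always(),
         rule_action("monitor", "Monitor K, Na and Cl",
                     analytes = c("K", "Na", "Cl"),
                     schedule = list(baseline = TRUE, repeat_months = dm))),

    ## Losartan (C09 renin-angiotensin)
    rule("losartan-renal-lt30-volume", "Losartan", "C09", "renal", 2,
         crcl_in(0, 30, lo_inclusive = FALSE),
         rule_action("caution",
                     paste("if the patient is also volume-depleted,",
                           "dose adjustment will be needed"))),
    rule("losartan-hepatic-initiate-25", "Losartan", "C09", "hepatic", 2,
         hep_impaired,
         rule_action("initiate_dose", "initiate with 25 mg per oral once daily",
                     dose = "25 mg", frequency = "once daily")),
    rule("losartan-pregnancy-discontinue", "Losartan", "C09", "pregnancy", 1,
         pregnant(), rule_action("discontinue", "Discontinue")),
    rule("losartan-monitor-na-k", "Losartan", "C09", "monitoring", 3,
         p_always(),
         rule_action("monitor",
                     "Monitor Na and K at the baseline and 1-2 weeks after the start",
                     analytes = c("Na", "K"),
                     schedule = list(baseline = TRUE, offset_days = 14))),

    ## Mycophenolate (L04 immunosuppressant)
    rule("mycophenolate-renal-lt25", "Mycophenolate", "L04", "renal", 1,
         crcl_in(0, 25, lo_inclusive = FALSE),
         rule_action("adjust_cap", "do not exceed 1 g per oral twice daily",
                     dose = "1 g", frequency = "twice daily")),
    rule("mycophenolate-pregnancy-discontinue", "Mycophenolate", "L04", "pregnancy", 1,
         pregnant(), rule_action("discontinue", "Discontinue")),
    rule("mycophenolate-monitor-bhcg", "Mycophenolate", "L04", "monitoring", 3,
         p_always(),
         rule_action("monitor",
                     paste("Monitor pregnancy test (bHCG) 8 to 10 days after the",
                           "initiation and then every 3 months afterward"),
                     analytes = "bHCG",
                     schedule = list(baseline = FALSE, offset_days = 10,
                                     repeat_months = 3))),

    ## Omeprazole (A02 acid-related disorders)
    rule("omeprazole-hepatic-severe-10mg", "Omeprazole", "A02", "hepatic", 1,
         hep_severe,
         rule_action("adjust_exact",
                     "reduce Omeprazole dose to 10 mg once daily receiving for long-term therapy",
                     dose = "10 mg", frequency = "once daily")),
    rule("omeprazole-monitor-mg-b12", "Omeprazole", "A02", "monitoring", 3,
         p_always(),
         rule_action("monitor", "Monitor Mg and Vit B12 levels periodically",
                     analytes = c("Mg", "VitB12"),
                     schedule = list(baseline = FALSE, repeat_months = dm)))
  )

  kb <- knowledge_base(rules, catalog, kb_version = "1.0")
  findings <- validate_kb(kb)
  stopifnot(length(findings) == 0)
  kb
}
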