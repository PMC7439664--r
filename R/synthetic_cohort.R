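#' @title Synthetic patients: boundary fixtures and random cohorts
#' @description Two generators make the whole pipeline testable without
#'   real patient data. [fixture_patients()] enumerates deterministic
#'   "fictitious patients" crossing every rule threshold at `t - eps`, `t`
#'   and `t + eps`, with the expected alert set computed by an independent
#'   hand-coded oracle — never by the engine under test. [sample_cohort()]
#'   draws seeded random cohorts matching a transplant-clinic profile
#'   (sex mix, age/weight ranges, medication prevalences, lab
#'   distributions).
#' @name synthetic_cohort
NULL

## ---- independent rule oracle ----------------------------------------------

# Each shipped rule's trigger, re-written as a standalone boolean over a
# flat context — deliberately independent of the predicate-tree evaluator.
# ctx: crcl (NA when no creatinine), alt/ast/bili (NA when unmeasured),
# cirrhosis, pregnant.
.or_na <- function(x) !is.na(x) & x

.hep_impaired_ctx <- function(ctx)
  .or_na(ctx$alt > 40) || .or_na(ctx$ast > 40) || .or_na(ctx$bili > 1.5) ||
    isTRUE(ctx$cirrhosis)

.hep_severe_ctx <- function(ctx)
  .or_na(ctx$alt > 120) || .or_na(ctx$ast > 120) || .or_na(ctx$bili > 3) ||
    isTRUE(ctx$cirrhosis)

.seeded_oracle <- list(
  "allopurinol-renal-10-20" = function(ctx) .or_na(ctx$crcl >= 10 & ctx$crcl < 20),
  "allopurinol-renal-3-10" = function(ctx) .or_na(ctx$crcl >= 3 & ctx$crcl < 10),
  "allopurinol-renal-lt3" = function(ctx) .or_na(ctx$crcl > 0 & ctx$crcl < 3),
  "allopurinol-hepatic-caution" = .hep_impaired_ctx,
  "allopurinol-monitor-uricacid" = function(ctx) TRUE,
  "azathioprine-renal-caution" = function(ctx) .or_na(ctx$crcl > 0 & ctx$crcl < 60),
  "azathioprine-pregnancy-discontinue" = function(ctx) isTRUE(ctx$pregnant),
  "captopril-renal-10-50" = function(ctx) .or_na(ctx$crcl >= 10 & ctx$crcl < 50),
  "captopril-renal-lt10" = function(ctx) .or_na(ctx$crcl > 0 & ctx$crcl < 10),
  "captopril-pregnancy-discontinue" = function(ctx) isTRUE(ctx$pregnant),
  "captopril-monitor-na-k" = function(ctx) TRUE,
  "cyclosporine-hepatic-monitor-level" = .hep_impaired_ctx,
  "cyclosporine-monitor-uricacid-k-mg" = function(ctx) TRUE,
  "hydrochlorothiazide-renal-lt30" = function(ctx) .or_na(ctx$crcl > 0 & ctx$crcl < 30),
  "hydrochlorothiazide-hepatic-caution" = .hep_impaired_ctx,
  "hydrochlorothiazide-monitor-k-na-cl" = function(ctx) TRUE,
  "losartan-renal-lt30-volume" = function(ctx) .or_na(ctx$crcl > 0 & ctx$crcl < 30),
  "losartan-hepatic-initiate-25" = .hep_impaired_ctx,
  "losartan-pregnancy-discontinue" = function(ctx) isTRUE(ctx$pregnant),
  "losartan-monitor-na-k" = function(ctx) TRUE,
  "mycophenolate-renal-lt25" = function(ctx) .or_na(ctx$crcl > 0 & ctx$crcl < 25),
  "mycophenolate-pregnancy-discontinue" = function(ctx) isTRUE(ctx$pregnant),
  "mycophenolate-monitor-bhcg" = function(ctx) TRUE,
  "omeprazole-hepatic-severe-10mg" = .hep_severe_ctx,
  "omeprazole-monitor-mg-b12" = function(ctx) TRUE
)

#' Brute-force oracle for the shipped rules
#'
#' Evaluates one shipped rule's trigger as a standalone boolean function
#' over a flat context, independently of the engine's predicate
#' evaluator. Used to compute fixture expectations and to cross-check
#' [evaluate()] in the test suite, mirroring iterative verification
#' against manual rule review until full sensitivity and specificity.
#'
#' @param rule_id a shipped rule id (see [seeded_kb()]).
#' @param ctx list with `crcl`, `alt`, `ast`, `bili` (numeric, `NA` when
#'   unmeasured), `cirrhosis`, `pregnant` (logical).
#' @return logical: does the rule fire for a patient in this state who is
#'   prescribed the rule's medication?
#' @export
oracle_fires <- function(rule_id, ctx) {
  f <- .seeded_oracle[[rule_id]]
  if (is.null(f)) stop("no oracle for rule '", rule_id, "'", call. = FALSE)
  defaults <- list(crcl = NA_real_, alt = NA_real_, ast = NA_real_,
                   bili = NA_real_, cirrhosis = FALSE, pregnant = FALSE)
  defaults[names(ctx)] <- ctx
  isTRUE(f(defaults))
}

oracle_expected <- function(kb, medication, ctx) {
  rids <- vapply(kb$rules, `[[`, "", "rule_id")
  meds <- vapply(kb$rules, `[[`, "", "medication")
  keep <- rids[meds == medication & vapply(rids, function(r)
    !is.null(.seeded_oracle[[r]]) && oracle_fires(r, ctx), logical(1))]
  sort(unname(keep))
}

#' Serum creatinine that lands a patient at a target CrCl
#'
#' Inverts Cockcroft-Gault: `Cr = (140 - age) x weight x k / (72 x
#' target)` with `k = 0.85` for females. The inversion is checked against
#' forward evaluation in the test suite.
#'
#' @param target_crcl desired creatinine clearance, ml/min.
#' @param age,weight,sex patient covariates.
#' @return serum creatinine in mg/dl.
#' @export
cr_for_crcl <- function(target_crcl, age, weight, sex) {
  sex <- match.arg(sex, c("male", "female"))
  k <- if (sex == "female") 0.85 else 1
  (140 - age) * weight * k / (72 * target_crcl)
}

## ---- boundary fixtures ------------------------------------------------------

fixture_demographics <- function(sex, as_of) {
  patient_record(paste0("fx-", sex), sex,
                 birth_date = add_months(as_of, -480),  # exactly 40 years
                 weight = 72, height = 170)
}

normal_liver_labs <- function(obs) list(
  lab_result("ALT", 20, observed_at = obs),
  lab_result("AST", 20, observed_at = obs),
  lab_result("Bili_total", 1.0, observed_at = obs)
)

#' Deterministic boundary-crossing fixture patients
#'
#' For every numeric threshold `t` in the knowledge base's rule triggers,
#' emits fictitious patients whose derived value sits at `t - eps`, `t`
#' and `t + eps`: CrCl targets are reached by back-solving serum
#' creatinine through Cockcroft-Gault (per sex; age 40, weight 72 kg),
#' liver-analyte targets by direct lab values. Cirrhosis-history and
#' pregnancy-status fixtures (active, absent, expired) cover the non-lab
#' triggers, plus a zero-prescription fixture. Expected alert sets come
#' from [oracle_fires()] evaluated on the *realised* derived values (the
#' forward Cockcroft-Gault result, not the nominal target), never from
#' the engine under test.
#'
#' @param kb the knowledge base (must be the shipped rule set — the
#'   oracle is defined per shipped rule).
#' @param as_of evaluation date for all fixtures.
#' @param eps boundary offset in the threshold's own unit (default 1e-6).
#' @return list of fixtures; each has `id`, `patient`, `labs`,
#'   `prescriptions`, `expected` (sorted rule-id character vector), and
#'   `ctx` (the realised context the oracle saw).
#' @export
fixture_patients <- function(kb = seeded_kb(), as_of = "2020-06-01", eps = 1e-6) {
  as_of <- as_date(as_of)
  obs <- as_of - 30
  fixtures <- list()
  add <- function(id, patient, labs, rx_med, ctx) {
    patient$patient_id <- id
    prescriptions <- if (is.null(rx_med)) list()
                     else list(prescription(rx_med, as_of))
    expected <- if (is.null(rx_med)) character()
                else oracle_expected(kb, rx_med, ctx)
    fixtures[[length(fixtures) + 1L]] <<- list(
      id = id, patient = patient, labs = labs,
      prescriptions = prescriptions, expected = expected, ctx = ctx)
  }

  rids <- vapply(kb$rules, `[[`, "", "rule_id")

  # CrCl band boundaries per medication
  for (r in kb$rules) {
    bands <- collect_atoms(r$trigger, "crcl_in")
    if (!length(bands)) next
    thresholds <- unique(unlist(lapply(bands, function(b)
      setdiff(c(b$lo, b$hi), c(0, Inf)))))
    for (t in thresholds) for (v in c(t - eps, t, t + eps)) for (sx in c("male", "female")) {
      p <- fixture_demographics(sx, as_of)
      cr <- cr_for_crcl(v, age = 40, weight = 72, sex = sx)
      labs <- c(list(lab_result("Cr", cr, observed_at = obs)), normal_liver_labs(obs))
      realised <- creatinine_clearance(40, 72, sx, cr)$crcl
      ctx <- list(crcl = realised, alt = 20, ast = 20, bili = 1.0)
      add(sprintf("%s-crcl%.8g-%s", r$rule_id, v, sx), p, labs, r$medication, ctx)
    }
  }

  # liver-analyte thresholds for medications with hepatic rules
  hep_meds <- unique(vapply(Filter(function(r) r$category == "hepatic", kb$rules),
                            `[[`, "", "medication"))
  liver_grid <- list(ALT = c(40, 120), AST = c(40, 120), Bili_total = c(1.5, 3))
  for (med in hep_meds) {
    for (a in names(liver_grid)) for (t in liver_grid[[a]]) for (v in c(t - eps, t, t + eps)) {
      p <- fixture_demographics("male", as_of)
      base <- list(ALT = 20, AST = 20, Bili_total = 1.0)
      base[[a]] <- v
      labs <- lapply(names(base), function(an)
        lab_result(an, base[[an]], observed_at = obs))
      ctx <- list(alt = base$ALT, ast = base$AST, bili = base$Bili_total)
      add(sprintf("%s-%s%.8g", tolower(med), a, v), p, labs, med, ctx)
    }
    # cirrhosis history alone
    p <- fixture_demographics("male", as_of)
    p$cirrhosis_history <- TRUE
    add(sprintf("%s-cirrhosis", tolower(med)), p, normal_liver_labs(obs), med,
        list(alt = 20, ast = 20, bili = 1.0, cirrhosis = TRUE))
  }

  # pregnancy status for medications with pregnancy rules
  preg_meds <- unique(vapply(Filter(function(r) r$category == "pregnancy", kb$rules),
                             `[[`, "", "medication"))
  preg_cases <- list(
    active = pregnancy_record(add_months(as_of, -2)),
    absent = NULL,
    expired = pregnancy_record(add_months(as_of, -10)),
    terminated = pregnancy_record(add_months(as_of, -2),
                                  termination_date = as_of - 7)
  )
  for (med in preg_meds) for (case in names(preg_cases)) {
    p <- fixture_demographics("female", as_of)
    p$pregnancy <- preg_cases[[case]]
    # direct re-derivation of activity, independent of the engine helper
    active <- !is.null(p$pregnancy) &&
      as_of < add_months(p$pregnancy$detected_date, 9) &&
      (is.null(p$pregnancy$termination_date) || as_of < p$pregnancy$termination_date)
    add(sprintf("%s-pregnancy-%s", tolower(med), case), p,
        normal_liver_labs(obs), med,
        list(alt = 20, ast = 20, bili = 1.0, pregnant = active))
  }

  # no prescriptions: no alerts, however deranged the labs
  p <- fixture_demographics("male", as_of)
  labs <- c(list(lab_result("Cr", 8, observed_at = obs)),
            list(lab_result("ALT", 300, observed_at = obs)))
  add("no-prescriptions", p, labs, NULL, list(alt = 300))

  fixtures
}

## ---- random cohorts ---------------------------------------------------------

#' Cohort sampling profile
#'
#' Distributional spec for [sample_cohort()]. Ages and weights are drawn
#' from truncated normals whose sd is chosen so the stated range spans
#' roughly the mean plus/minus 2.5 sd (`sd = (max - min) / 5`); labs from
#' normals truncated at zero; each medication is assigned independently
#' with its prevalence. Correlations between labs and medications are not
#' modelled.
#'
#' @param male_fraction probability of male sex.
#' @param age,weight lists with `mean`, `sd`, `min`, `max`.
#' @param medication_prevalences named probabilities.
#' @param lab_distributions named lists with `mean`, `sd` (truncated at 0).
#' @param pregnancy_rate probability that a sampled female has an active
#'   pregnancy episode on record.
#' @return object of class `dli_cohort_profile`.
#' @export
cohort_profile <- function(male_fraction, age, weight, medication_prevalences,
                           lab_distributions, pregnancy_rate = 0) {
  probs <- c(male_fraction, medication_prevalences, pregnancy_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  sds <- c(age$sd, weight$sd, vapply(lab_distributions, `[[`, 1, "sd"))
  if (any(!is.finite(sds) | sds <= 0))
    stop("all sd values must be positive", call. = FALSE)
  structure(list(male_fraction = male_fraction, age = age, weight = weight,
                 medication_prevalences = medication_prevalences,
                 lab_distributions = lab_distributions,
                 pregnancy_rate = pregnancy_rate),
            class = "dli_cohort_profile")
}

#' The default transplant-clinic cohort profile
#'
#' Matches the observed 100-patient validation cohort of the outpatient
#' kidney-transplant clinic the shipped rules were curated for: 56% male;
#' age mean 47.44 years, range 20-73; weight mean 72.07 kg, range 45-135;
#' medication prevalences Mycophenolate 0.74, Cyclosporine 0.71,
#' Sirolimus 0.23, Diltiazem 0.51, Calcium 0.50, Omeprazole 0.39,
#' Losartan 0.34, Atorvastatin 0.27 (medications outside the shipped rule
#' set are kept so the prescription mix is realistic; they generate no
#' alerts); labs Cr 1.57 +/- 0.66 mg/dl, AST 19.64 +/- 8.16 U/L, ALT
#' 21.14 +/- 13.24 U/L. The pregnancy rate (0.05 of females) is a
#' modelling choice, not an observed figure.
#'
#' @return a [cohort_profile()].
#' @export
default_cohort_profile <- function() {
  cohort_profile(
    male_fraction = 0.56,
    age = list(mean = 47.44, sd = (73 - 20) / 5, min = 20, max = 73),
    weight = list(mean = 72.07, sd = (135 - 45) / 5, min = 45, max = 135),
    medication_prevalences = c(
      Mycophenolate = 0.74, Cyclosporine = 0.71, Sirolimus = 0.23,
      Diltiazem = 0.51, Calcium = 0.50, Omeprazole = 0.39,
      Losartan = 0.34, Atorvastatin = 0.27),
    lab_distributions = list(
      Cr = list(mean = 1.57, sd = 0.66),
      AST = list(mean = 19.64, sd = 8.16),
      ALT = list(mean = 21.14, sd = 13.24)),
    pregnancy_rate = 0.05
  )
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] < lo | out[todo] > hi]
  }
  out
}

#' Sample a random patient cohort
#'
#' Deterministic given `seed`. Each bundle carries a patient (with height
#' drawn from sex-specific normals — a modelling addition, no height is
#' part of the profile), a creatinine/AST/ALT panel observed within the
#' 6-month window, and independently assigned prescriptions.
#'
#' @param profile a [cohort_profile()].
#' @param n number of patients (> 0).
#' @param seed integer RNG seed (required: sampling is never implicitly
#'   seeded).
#' @param as_of reference date; ages and lab dates are anchored to it.
#' @return list of `n` bundles, each `list(patient, labs, prescriptions)`.
#' @examples
#' cohort <- sample_cohort(default_cohort_profile(), n = 5, seed = 42)
#' cohort[[1]]$patient
#' @export
sample_cohort <- function(profile, n, seed, as_of = "2020-06-01") {
  if (!inherits(profile, "dli_cohort_profile"))
    stop("profile must be built with cohort_profile()", call. = FALSE)
  stopifnot(n > 0, length(seed) == 1L, is.finite(seed))
  as_of <- as_date(as_of)
  set.seed(as.integer(seed))

  lapply(seq_len(n), function(i) {
    sex <- if (stats::runif(1) < profile$male_fraction) "male" else "female"
    age <- rtrunc_norm(1, profile$age$mean, profile$age$sd,
                       profile$age$min, profile$age$max)
    weight <- rtrunc_norm(1, profile$weight$mean, profile$weight$sd,
                          profile$weight$min, profile$weight$max)
    height <- if (sex == "male") rtrunc_norm(1, 175, 7, 150, 205)
              else rtrunc_norm(1, 162, 7, 140, 195)
    birth <- as_of - round(age * 365.2425)
    preg <- NULL
    if (sex == "female" && stats::runif(1) < profile$pregnancy_rate)
      preg <- pregnancy_record(as_of - sample.int(180, 1))
    patient <- patient_record(sprintf("sim-%05d", i), sex, birth,
                              weight = weight, height = height,
                              pregnancy = preg)
    labs <- lapply(names(profile$lab_distributions), function(a) {
      d <- profile$lab_distributions[[a]]
      lab_result(a, rtrunc_norm(1, d$mean, d$sd, lo = 0),
                 observed_at = as_of - sample.int(150, 1))
    })
    meds <- names(profile$medication_prevalences)
    assigned <- meds[stats::runif(length(meds)) < profile$medication_prevalences]
    prescriptions <- lapply(assigned, function(m)
      prescription(m, as_of - sample.int(120, 1) + 1L))
    list(patient = patient, labs = labs, prescriptions = prescriptions)
  })
}

#' Summary moments of a sampled cohort
#'
#' @param cohort output of [sample_cohort()].
#' @param as_of the reference date the cohort was sampled against.
#' @return list with `n`, `male_fraction`, `mean_age` (continuous years),
#'   `mean_weight`, `lab_means` (named), `medication_prevalence` (named).
#' @export
cohort_summary <- function(cohort, as_of = "2020-06-01") {
  as_of <- as_date(as_of)
  sexes <- vapply(cohort, function(b) b$patient$sex, "")
  ages <- vapply(cohort, function(b)
    as.numeric(as_of - b$patient$birth_date) / 365.2425, numeric(1))
  weights <- vapply(cohort, function(b) b$patient$weight, numeric(1))
  analytes <- unique(unlist(lapply(cohort, function(b)
    vapply(b$labs, `[[`, "", "analyte"))))
  lab_means <- vapply(analytes, function(a) {
    vals <- unlist(lapply(cohort, function(b) {
      hits <- Filter(function(l) l$analyte == a, b$labs)
      vapply(hits, `[[`, 1, "value")
    }))
    mean(vals)
  }, numeric(1))
  meds <- unique(unlist(lapply(cohort, function(b)
    vapply(b$prescriptions, `[[`, "", "medication_id"))))
  prev <- vapply(meds, function(m) mean(vapply(cohort, function(b)
    m %in% vapply(b$prescriptions, `[[`, "", "medication_id"), logical(1))),
    numeric(1))
  list(n = length(cohort), male_fraction = mean(sexes == "male"),
       mean_age = mean(ages), mean_weight = mean(weights),
       lab_means = lab_means, medication_prevalence = prev)
}
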