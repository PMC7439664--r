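#' @title Derived physiologic state
#' @description Pure functions (no I/O) turning raw demographics and labs
#'   into the derived quantities rules trigger on: creatinine clearance,
#'   lean body mass, Child-Pugh score and the two-tier hepatic impairment
#'   classification.
#' @name physiology
NULL

#' Creatinine clearance by Cockcroft-Gault
#'
#' CrCl = (140 - age) x weight / (72 x serum Cr), times 0.85 for females;
#' age in years, weight in kg, serum creatinine in mg/dl, result in ml/min.
#' The raw (non-BSA-normalised) value is what renal rules compare against
#' their thresholds by default; an optional body-surface-area normalisation
#' to 1.73 m^2 (Du Bois) is available when height is known.
#'
#' @param age years, in [18, 140).
#' @param weight kg, positive. Actual body weight by default; callers may
#'   pass lean body mass instead (see [engine_config()] `crcl_weight`).
#' @param sex `"male"` or `"female"`.
#' @param serum_cr serum creatinine, mg/dl, positive.
#' @param cr_observed_at date the creatinine was observed (carried into the
#'   returned state for alert rendering).
#' @param bsa_normalize normalise to 1.73 m^2 body surface area (requires
#'   `height`); default off.
#' @param height cm, only used when `bsa_normalize = TRUE`.
#' @return a `dli_renal_state`: list with `crcl` (ml/min), `serum_cr_used`,
#'   `cr_observed_at`.
#' @examples
#' creatinine_clearance(40, 72, "male", 1.0)$crcl    # 100
#' creatinine_clearance(40, 72, "female", 1.0)$crcl  # 85
#' @export
creatinine_clearance <- function(age, weight, sex, serum_cr,
                                 cr_observed_at = NULL,
                                 bsa_normalize = FALSE, height = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(serum_cr) || serum_cr <= 0)
    stop("serum creatinine must be positive (got ", serum_cr, ")", call. = FALSE)
  if (!is.finite(weight) || weight <= 0)
    stop("weight must be positive (got ", weight, ")", call. = FALSE)
  if (!is.finite(age) || age < 18)
    stop("age must be >= 18 (adult outpatient scope), got ", age, call. = FALSE)
  if (age >= 140)
    stop("age >= 140 makes the Cockcroft-Gault term (140 - age) vanish; ",
         "input considered unusable", call. = FALSE)
  crcl <- (140 - age) * weight / (72 * serum_cr)
  if (sex == "female") crcl <- 0.85 * crcl
  if (isTRUE(bsa_normalize)) {
    if (is.null(height)) stop("bsa_normalize requires height", call. = FALSE)
    bsa <- 0.007184 * weight^0.425 * height^0.725  # Du Bois
    crcl <- crcl * 1.73 / bsa
  }
  structure(list(crcl = crcl, serum_cr_used = serum_cr,
                 cr_observed_at = if (!is.null(cr_observed_at)) as_date(cr_observed_at)),
            class = "dli_renal_state")
}

#' Lean body mass by the Hume equation
#'
#' male: 0.32810 W + 0.33929 H - 29.5336; female: 0.29569 W + 0.41813 H -
#' 43.2933 (W in kg, H in cm). Used for weight-based dosing of drugs such
#' as digoxin. An LBM exceeding actual weight (possible at extreme inputs)
#' is returned with a warning, not an error.
#'
#' @param sex `"male"` or `"female"`.
#' @param weight kg, positive.
#' @param height cm; when missing (`NULL`), LBM is unavailable and rules
#'   needing it must degrade to a monitoring alert.
#' @return a `dli_body_composition`: list with `lbm` (kg).
#' @examples
#' lean_body_mass("male", 72, 170)$lbm    # 51.77
#' lean_body_mass("female", 72, 170)$lbm  # 49.37
#' @export
lean_body_mass <- function(sex, weight, height) {
  sex <- match.arg(sex, c("male", "female"))
  if (is.null(height) || !is.finite(height))
    stop("height required to compute lean body mass", call. = FALSE)
  if (!is.finite(weight) || weight <= 0)
    stop("weight must be positive", call. = FALSE)
  lbm <- if (sex == "male") 0.32810 * weight + 0.33929 * height - 29.5336
         else               0.29569 * weight + 0.41813 * height - 43.2933
  if (lbm <= 0 || lbm > weight)
    warning(sprintf("lean body mass %.2f kg outside (0, weight]; extreme inputs", lbm))
  structure(list(lbm = lbm), class = "dli_body_composition")
}

# Per-parameter Child-Pugh points over the standard published bands.
.cp_points <- function(inputs) {
  bili <- inputs$bilirubin_total; alb <- inputs$albumin; inr <- inputs$inr
  c(
    bilirubin = if (bili < 2) 1L else if (bili <= 3) 2L else 3L,
    albumin = if (alb > 3.5) 1L else if (alb >= 2.8) 2L else 3L,
    inr = if (inr < 1.7) 1L else if (inr <= 2.3) 2L else 3L,
    ascites = switch(inputs$ascites, none = 1L, mild = 2L, moderate_severe = 3L),
    encephalopathy = switch(inputs$encephalopathy,
                            none = 1L, grade1_2 = 2L, grade3_4 = 3L)
  )
}

#' Child-Pugh score and class
#'
#' Standard 5-parameter scheme, 1-3 points each: total bilirubin (< 2 /
#' 2-3 / > 3 mg/dl), albumin (> 3.5 / 2.8-3.5 / < 2.8 g/dl), INR (< 1.7 /
#' 1.7-2.3 / > 2.3), ascites (none / mild / moderate-severe),
#' encephalopathy (none / grade 1-2 / grade 3-4). Class A = 5-6, B = 7-9,
#' C = 10-15.
#'
#' @param inputs a [child_pugh_inputs()]; all five parameters must be
#'   present — a missing parameter makes the score unavailable (error),
#'   never silently zero.
#' @return list with integer `score` (5..15) and `class` (`"A"|"B"|"C"`).
#' @examples
#' child_pugh(child_pugh_inputs(2.5, 3.0, 1.9, "mild", "none"))  # score 9, B
#' @export
child_pugh <- function(inputs) {
  if (!inherits(inputs, "dli_child_pugh_inputs"))
    stop("inputs must be built with child_pugh_inputs()", call. = FALSE)
  num <- c(inputs$bilirubin_total, inputs$albumin, inputs$inr)
  if (any(is.na(num)) || is.na(inputs$ascites) || is.na(inputs$encephalopathy))
    stop("Child-Pugh score unavailable: all five parameters are required",
         call. = FALSE)
  score <- sum(.cp_points(inputs))
  cls <- if (score <= 6) "A" else if (score <= 9) "B" else "C"
  list(score = as.integer(score), class = cls)
}

# Liver-analyte thresholds for the two tiers (canonical units).
.hepatic_thresholds <- list(
  impaired = c(ALT = 40, AST = 40, Bili_total = 1.5),
  severe = c(ALT = 120, AST = 120, Bili_total = 3)
)

#' Two-tier hepatic impairment classification
#'
#' Liver dysfunction is triangulated from three sources: the latest
#' in-window liver labs, a documented cirrhosis history, and (optionally)
#' the Child-Pugh class. Tier `severe` when AST > 120 U/L or ALT > 120 U/L
#' or total bilirubin > 3 mg/dl, or cirrhosis history, or Child-Pugh class
#' C; tier `impaired` when ALT > 40 or AST > 40 or bilirubin > 1.5 and not
#' severe; otherwise `normal`. All comparisons are strict, exactly as the
#' guideline thresholds are written: a value sitting exactly on a threshold
#' does not trigger. Only the latest result per analyte inside the lookback
#' window is consulted.
#'
#' @param labs list of [lab_result()]s (canonical units).
#' @param cirrhosis_history logical.
#' @param cp optional [child_pugh_inputs()].
#' @param as_of evaluation date.
#' @param window_months lookback window (calendar months, default 6).
#' @param cirrhosis_implies_severe,child_pugh_c_implies_severe toggles for
#'   the two non-lab contributions (both default on).
#' @return a `dli_hepatic_state`: `tier` (`"normal"|"impaired"|"severe"`),
#'   `evidence` (list of satisfied criteria, each `(source, value,
#'   criterion)`), and `no_data` (TRUE when no liver evidence at all was
#'   available — distinguishing "no data" from "data normal").
#' @examples
#' labs <- list(lab_result("ALT", 41, observed_at = "2020-05-01"))
#' hepatic_state(labs, FALSE, as_of = "2020-06-01")$tier  # "impaired"
#' @export
hepatic_state <- function(labs, cirrhosis_history = FALSE, cp = NULL,
                          as_of, window_months = 6,
                          cirrhosis_implies_severe = TRUE,
                          child_pugh_c_implies_severe = TRUE) {
  as_of <- as_date(as_of)
  vals <- vapply(c("ALT", "AST", "Bili_total"), function(a) {
    lab <- latest_lab(labs, a, as_of, window_months)
    if (is.null(lab)) NA_real_ else lab$value
  }, numeric(1))

  evidence <- list()
  note <- function(source, value, criterion)
    evidence[[length(evidence) + 1L]] <<- list(source = source, value = value,
                                               criterion = criterion)
  unit_of <- c(ALT = "U/L", AST = "U/L", Bili_total = "mg/dl")
  sev_lab <- FALSE; imp_lab <- FALSE
  for (a in names(vals)) {
    v <- vals[[a]]
    if (is.na(v)) next
    if (v > .hepatic_thresholds$severe[[a]]) {
      sev_lab <- TRUE
      note(a, v, sprintf("%s > %g %s", a, .hepatic_thresholds$severe[[a]], unit_of[[a]]))
    } else if (v > .hepatic_thresholds$impaired[[a]]) {
      imp_lab <- TRUE
      note(a, v, sprintf("%s > %g %s", a, .hepatic_thresholds$impaired[[a]], unit_of[[a]]))
    }
  }
  # imp_lab is implied by sev_lab: a severe lab also exceeds the lower bound
  if (sev_lab) imp_lab <- TRUE

  severe <- sev_lab
  if (isTRUE(cirrhosis_history) && cirrhosis_implies_severe) {
    severe <- TRUE
    note("cirrhosis_history", TRUE, "documented cirrhotic liver disease")
  }
  cp_class <- NULL
  if (!is.null(cp)) {
    cp_res <- child_pugh(cp)
    cp_class <- cp_res$class
    if (cp_res$class == "C" && child_pugh_c_implies_severe) {
      severe <- TRUE
      note("child_pugh", cp_res$score, "Child-Pugh class C")
    }
  }

  tier <- if (severe) "severe" else if (imp_lab) "impaired" else "normal"
  no_data <- all(is.na(vals)) && !isTRUE(cirrhosis_history) && is.null(cp)
  structure(list(tier = tier, evidence = evidence, no_data = no_data,
                 lab_values = vals, child_pugh_class = cp_class),
            class = "dli_hepatic_state")
}

#' @export
print.dli_renal_state <- function(x, ...) {
  cat(sprintf("<renal state: CrCl %.1f ml/min (Cr %.2f mg/dl%s)>\n",
              x$crcl, x$serum_cr_used,
              if (!is.null(x$cr_observed_at)) paste0(" on ", format(x$cr_observed_at)) else ""))
  invisible(x)
}

#' @export
print.dli_hepatic_state <- function(x, ...) {
  cat(sprintf("<hepatic state: %s%s; %d evidence item(s)>\n", x$tier,
              if (x$no_data) " (no liver data)" else "", length(x$evidence)))
  invisible(x)
}
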