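test_that("Cockcroft-Gault reproduces hand-computed clearances", {
  expect_equal(creatinine_clearance(40, 72, "male", 1.0)$crcl, 100.0)
  expect_equal(creatinine_clearance(40, 72, "female", 1.0)$crcl, 85.0)
  # female result is exactly 0.85 x male at identical covariates
  for (cr in c(0.6, 1.3, 4.2)) {
    m <- creatinine_clearance(55, 80, "male", cr)$crcl
    f <- creatinine_clearance(55, 80, "female", cr)$crcl
    expect_equal(f, 0.85 * m)
  }
})

test_that("Cockcroft-Gault is monotone in its covariates", {
  base <- creatinine_clearance(40, 72, "male", 1.0)$crcl
  expect_lt(creatinine_clearance(41, 72, "male", 1.0)$crcl, base)
  expect_lt(creatinine_clearance(40, 72, "male", 1.1)$crcl, base)
  expect_gt(creatinine_clearance(40, 80, "male", 1.0)$crcl, base)
})

test_that("unusable Cockcroft-Gault inputs are domain errors", {
  expect_error(creatinine_clearance(140, 72, "male", 1.0), "140")
  expect_error(creatinine_clearance(40, 72, "male", 0), "creatinine")
  expect_error(creatinine_clearance(40, -5, "male", 1.0), "weight")
  expect_error(creatinine_clearance(17, 72, "male", 1.0), "18")
})

test_that("Hume lean body mass matches the published coefficients", {
  expect_equal(lean_body_mass("male", 72, 170)$lbm,
               0.32810 * 72 + 0.33929 * 170 - 29.5336, tolerance = 1e-12)
  expect_equal(lean_body_mass("male", 72, 170)$lbm, 51.77, tolerance = 0.01)
  expect_equal(lean_body_mass("female", 72, 170)$lbm,
               0.29569 * 72 + 0.41813 * 170 - 43.2933, tolerance = 1e-12)
  # one kg of weight adds exactly the weight coefficient
  expect_equal(lean_body_mass("male", 73, 170)$lbm -
                 lean_body_mass("male", 72, 170)$lbm, 0.32810)
  expect_error(lean_body_mass("male", 72, NULL), "height")
})

test_that("Child-Pugh bands span 5..15 and classes partition the range", {
  best <- child_pugh(child_pugh_inputs(1.0, 4.0, 1.0, "none", "none"))
  expect_equal(best$score, 5L); expect_equal(best$class, "A")
  worst <- child_pugh(child_pugh_inputs(5.0, 2.0, 3.0, "moderate_severe", "grade3_4"))
  expect_equal(worst$score, 15L); expect_equal(worst$class, "C")
  # frozen hand-tallied case: bili 2.5 -> 2, alb 3.0 -> 2, INR 1.9 -> 2,
  # mild ascites -> 2, no encephalopathy -> 1; total 9, class B
  mid <- child_pugh(child_pugh_inputs(2.5, 3.0, 1.9, "mild", "none"))
  expect_equal(mid$score, 9L); expect_equal(mid$class, "B")
})

test_that("Child-Pugh class follows score bands over an exhaustive sweep", {
  bili <- c(1, 2.5, 4); alb <- c(4, 3, 2.5); inr <- c(1.2, 2, 3)
  asc <- c("none", "mild", "moderate_severe")
  enc <- c("none", "grade1_2", "grade3_4")
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    res <- child_pugh(child_pugh_inputs(bili[i], alb[j], inr[k], asc[i], enc[j]))
    expect_true(res$score >= 5 && res$score <= 15)
    expect_equal(res$class,
                 if (res$score <= 6) "A" else if (res$score <= 9) "B" else "C")
  }
})

test_that("hepatic tiers follow the threshold formulas with strict comparisons", {
  st <- hepatic_state(liver_labs(alt = 41), FALSE, as_of = AS_OF)
  expect_equal(st$tier, "impaired")
  expect_equal(st$evidence[[1]]$source, "ALT")
  expect_match(st$evidence[[1]]$criterion, "> 40")

  expect_equal(hepatic_state(liver_labs(), FALSE, as_of = AS_OF)$tier, "normal")
  expect_equal(hepatic_state(liver_labs(alt = 40), FALSE, as_of = AS_OF)$tier,
               "normal")  # exactly at a strict threshold does not trigger
  expect_equal(hepatic_state(liver_labs(alt = 130), FALSE, as_of = AS_OF)$tier,
               "severe")
  expect_equal(hepatic_state(liver_labs(bili = 3.1), FALSE, as_of = AS_OF)$tier,
               "severe")
})

test_that("cirrhosis history and Child-Pugh class C raise the tier to severe", {
  st <- hepatic_state(liver_labs(), TRUE, as_of = AS_OF)
  expect_equal(st$tier, "severe")
  expect_false(st$no_data)
  cp <- child_pugh_inputs(5.0, 2.0, 3.0, "moderate_severe", "grade3_4")
  expect_equal(hepatic_state(liver_labs(), FALSE, cp = cp, as_of = AS_OF)$tier,
               "severe")
  # both contributions are configurable
  expect_equal(hepatic_state(liver_labs(), TRUE, as_of = AS_OF,
                             cirrhosis_implies_severe = FALSE)$tier, "normal")
})

test_that("no liver data is distinguished from normal liver data", {
  st <- hepatic_state(list(), FALSE, as_of = AS_OF)
  expect_equal(st$tier, "normal")
  expect_true(st$no_data)
  expect_length(st$evidence, 0)
  st2 <- hepatic_state(liver_labs(), FALSE, as_of = AS_OF)
  expect_false(st2$no_data)
})

test_that("tier assignment agrees with brute-force re-evaluation around every threshold", {
  eps <- 1e-6
  grid_alt <- c(20, 40 - eps, 40, 40 + eps, 120 - eps, 120, 120 + eps)
  grid_bili <- c(1.0, 1.5 - eps, 1.5, 1.5 + eps, 3, 3 + eps)
  for (alt in grid_alt) for (bili in grid_bili) for (cirr in c(FALSE, TRUE)) {
    st <- hepatic_state(liver_labs(alt = alt, bili = bili), cirr, as_of = AS_OF)
    severe <- (alt > 120) || (20 > 120) || (bili > 3) || cirr
    impaired <- (alt > 40) || (20 > 40) || (bili > 1.5)
    want <- if (severe) "severe" else if (impaired) "impaired" else "normal"
    expect_equal(st$tier, want,
                 label = sprintf("tier at ALT=%.7g bili=%.7g cirr=%s", alt, bili, cirr))
    if (want != "normal") expect_gt(length(st$evidence), 0)
  }
})

test_that("raising a single liver analyte never lowers the tier", {
  rank <- c(normal = 0, impaired = 1, severe = 2)
  vals <- c(10, 39, 41, 119, 121, 200)
  for (i in seq_len(length(vals) - 1)) {
    lo <- hepatic_state(liver_labs(ast = vals[i]), FALSE, as_of = AS_OF)$tier
    hi <- hepatic_state(liver_labs(ast = vals[i + 1]), FALSE, as_of = AS_OF)$tier
    expect_gte(rank[[hi]], rank[[lo]])
  }
})

test_that("only in-window labs feed the hepatic tier", {
  old <- liver_labs(alt = 200, observed_at = add_months(AS_OF, -7))
  expect_equal(hepatic_state(old, FALSE, as_of = AS_OF)$tier, "normal")
  expect_true(hepatic_state(old, FALSE, as_of = AS_OF)$no_data)
})
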