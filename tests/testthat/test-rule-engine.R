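KB <- seeded_kb()

test_that("latest_lab honours the half-open 6-month window and recency", {
  mk <- function(d) lab_result("K", 4.2, observed_at = d)
  expect_equal(latest_lab(list(mk(add_months(AS_OF, -5))), "K", AS_OF)$observed_at,
               add_months(AS_OF, -5))
  expect_null(latest_lab(list(mk(add_months(AS_OF, -7))), "K", AS_OF))
  expect_null(latest_lab(list(mk(add_months(AS_OF, -6))), "K", AS_OF))
  two <- list(mk(add_months(AS_OF, -3)), mk(add_months(AS_OF, -1)))
  expect_equal(latest_lab(two, "K", AS_OF)$observed_at, add_months(AS_OF, -1))
})

test_that("a low-clearance Allopurinol patient gets the interruptive band alert", {
  labs <- list(cr_lab(cr_for_crcl(15, 40, 72, "male")))
  al <- evaluate(std_patient(), labs, list(rx("Allopurinol")), KB, as_of = AS_OF)
  expect_equal(fired_ids(al),
               c("allopurinol-monitor-uricacid", "allopurinol-renal-10-20"))
  renal <- al[[which(vapply(al, `[[`, "", "category") == "renal")]]
  expect_equal(renal$severity_level, 1L)
  expect_equal(renal$display_mode, "interruptive")
  expect_equal(renal$color, "red")
  expect_match(renal$message, "200 mg/day per oral")
})

test_that("normal labs on Cyclosporine yield only the level-3 monitoring alert", {
  labs <- c(list(cr_lab(1.0)), liver_labs())
  al <- evaluate(std_patient(), labs, list(rx("Cyclosporine")), KB, as_of = AS_OF)
  expect_equal(fired_ids(al), "cyclosporine-monitor-uricacid-k-mg")
  expect_equal(al[[1]]$severity_level, 3L)
  expect_equal(al[[1]]$display_mode, "informational")
})

test_that("a pregnant patient on Mycophenolate gets discontinue + pregnancy-test alerts", {
  p <- std_patient("female")
  p$pregnancy <- pregnancy_record(add_months(AS_OF, -2))
  al <- evaluate(p, list(), list(rx("Mycophenolate")), KB, as_of = AS_OF)
  expect_equal(fired_ids(al),
               c("mycophenolate-monitor-bhcg", "mycophenolate-pregnancy-discontinue"))
  disc <- al[[1]]  # severity ascending: discontinue first
  expect_equal(disc$rule_id, "mycophenolate-pregnancy-discontinue")
  expect_equal(disc$severity_level, 1L)
  expect_match(disc$message, "Discontinue")
})

test_that("an empty prescription list produces no alerts", {
  al <- evaluate(std_patient(), list(cr_lab(8)), list(), KB, as_of = AS_OF)
  expect_length(al, 0)
})

test_that("renal rules stay silent without an in-window creatinine", {
  old_cr <- list(cr_lab(8, observed_at = add_months(AS_OF, -7)))
  al <- evaluate(std_patient(), old_cr, list(rx("Captopril")), KB, as_of = AS_OF)
  cats <- vapply(al, `[[`, "", "category")
  expect_false("renal" %in% cats)
  expect_true("monitoring" %in% cats)  # monitoring still fires
})

test_that("rendered messages embed medication, recommendation, lab value and date", {
  cr <- cr_for_crcl(8, 40, 72, "male")
  labs <- list(lab_result("Cr", cr, observed_at = as.Date("2020-01-10")))
  al <- evaluate(std_patient(), labs, list(rx("Captopril")), KB,
                 as_of = as.Date("2020-02-01"))
  msg <- al[[1]]$message
  expect_match(msg, "Captopril")
  expect_match(msg, "50%")
  expect_match(msg, "2020-01-10")
  expect_match(msg, "Cr = ")
  expect_false(grepl("{", msg, fixed = TRUE))  # no unbound placeholders ever
})

test_that("templates with unbindable placeholders are a rendering error", {
  r <- rule("x", "Captopril", "C09", "renal", 1, crcl_in(10, 50),
            rule_action("adjust_percent", "reduce", percent = 25),
            message_template = "{medication}: {nonexistent}")
  expect_error(render_alert_message(r, std_patient(), NULL), "unbound placeholder")
})

test_that("monitoring alerts without a lab use baseline phrasing, no value or date", {
  al <- evaluate(std_patient(), list(), list(rx("Captopril")), KB, as_of = AS_OF)
  mon <- al[[which(fired_ids(al) == "captopril-monitor-na-k")]]
  expect_match(mon$message, "baseline")
  expect_match(mon$reason, "baseline needed")
  expect_null(mon$lab)
})

test_that("display classification is exactly severity 1 = interruptive", {
  expect_equal(classify_display(1), "interruptive")
  expect_equal(classify_display(2), "informational")
  expect_equal(classify_display(3), "informational")
  expect_error(classify_display(0), "severity")
  expect_error(classify_display(4), "severity")
})

test_that("alerts are ordered by medication, then severity, then rule id", {
  p <- std_patient("female")
  p$pregnancy <- pregnancy_record(add_months(AS_OF, -1))
  labs <- c(list(cr_lab(cr_for_crcl(20, 40, 72, "female"))), liver_labs(alt = 50))
  scripts <- list(rx("Mycophenolate"), rx("Losartan"))
  al <- evaluate(p, labs, scripts, KB, as_of = AS_OF)
  meds <- vapply(al, `[[`, "", "medication")
  expect_equal(meds, sort(meds))
  for (m in unique(meds)) {
    sev <- vapply(al[meds == m], `[[`, 1L, "severity_level")
    expect_equal(sev, sort(sev))
  }
})

test_that("evaluation is deterministic: identical inputs give identical alerts", {
  p <- std_patient("female")
  labs <- c(list(cr_lab(2.5)), liver_labs(ast = 60))
  scripts <- list(rx("Cyclosporine"), rx("Hydrochlorothiazide"))
  a1 <- evaluate(p, labs, scripts, KB, as_of = AS_OF)
  a2 <- evaluate(p, labs, scripts, KB, as_of = AS_OF)
  expect_identical(a1, a2)
})

test_that("a KB trigger the engine cannot derive errors at evaluate time, naming the rule", {
  weird <- rule("weird-rule", "Captopril", "C09", "renal", 2,
                list(type = "phase_of_moon"), rule_action("caution", "x"))
  kb <- knowledge_base(list(weird), data.frame(atc = "C09", name = "Captopril"))
  expect_error(
    evaluate(std_patient(), list(cr_lab(1)), list(rx("Captopril")), kb, as_of = AS_OF),
    "weird-rule")
})

test_that("a positive bHCG lab triggers pregnancy rules like a pregnancy record", {
  p <- std_patient("female")
  labs <- list(lab_result("bHCG", 1200, observed_at = OBS))
  al <- evaluate(p, labs, list(rx("Losartan")), KB, as_of = AS_OF)
  expect_true("losartan-pregnancy-discontinue" %in% fired_ids(al))
  # qualitative negative flag wins over the numeric threshold
  labs2 <- list(lab_result("bHCG", 1200, observed_at = OBS, positive = FALSE))
  al2 <- evaluate(p, labs2, list(rx("Losartan")), KB, as_of = AS_OF)
  expect_false("losartan-pregnancy-discontinue" %in% fired_ids(al2))
})

test_that("new Captopril with no Na/K on file prompts a baseline request", {
  al <- missing_baseline_alerts(std_patient(), list(), list(rx("Captopril")),
                                KB, as_of = AS_OF)
  expect_equal(fired_ids(al), "captopril-monitor-na-k")
  expect_equal(al[[1]]$severity_level, 3L)
  expect_match(al[[1]]$message, "baseline")
  expect_match(al[[1]]$reason, "Na")
  expect_match(al[[1]]$reason, "K")
})

test_that("overdue repeat monitoring is flagged by schedule arithmetic", {
  start <- add_months(AS_OF, -4)
  hcg <- list(lab_result("bHCG", 1, observed_at = AS_OF - 106))  # ~3.5 months ago
  al <- missing_baseline_alerts(std_patient("female"), hcg,
                                list(rx("Mycophenolate", start = start)),
                                KB, as_of = AS_OF)
  expect_equal(fired_ids(al), "mycophenolate-monitor-bhcg")
  expect_match(al[[1]]$reason, "repeat was due")
})

test_that("fresh monitored analytes produce no baseline alerts", {
  labs <- list(lab_result("Na", 140, observed_at = OBS),
               lab_result("K", 4.1, observed_at = OBS))
  al <- missing_baseline_alerts(std_patient(), labs, list(rx("Captopril")),
                                KB, as_of = AS_OF)
  expect_length(al, 0)
})

test_that("alerts convert to a well-formed data frame", {
  labs <- list(cr_lab(cr_for_crcl(15, 40, 72, "male")))
  al <- evaluate(std_patient(), labs, list(rx("Allopurinol")), KB, as_of = AS_OF)
  df <- as.data.frame(al)
  expect_equal(nrow(df), 2)
  expect_true(all(c("rule_id", "severity_level", "color", "display_mode",
                    "message") %in% names(df)))
})
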