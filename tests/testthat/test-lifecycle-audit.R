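KB <- seeded_kb()

fire_one <- function() {
  labs <- list(cr_lab(cr_for_crcl(15, 40, 72, "male")))
  al <- evaluate(std_patient(), labs, list(rx("Allopurinol")), KB, as_of = AS_OF)
  log <- log_firing(audit_log(), al, at = AS_OF)
  list(log = log, alerts = al)
}

test_that("reactions append entries without touching prior ones", {
  st <- fire_one()
  lvl1 <- st$alerts[[which(vapply(st$alerts, `[[`, 1L, "severity_level") == 1L)]]
  before <- st$log$entries
  log2 <- record_reaction(st$log, lvl1, "override", actor = "dr-a", at = AS_OF)
  expect_length(log2$entries, length(before) + 1)
  expect_identical(log2$entries[seq_along(before)], before)  # append-only
  new <- log2$entries[[length(log2$entries)]]
  expect_equal(new$reaction, "override")
  expect_equal(new$alert_id, lvl1$alert_id)
})

test_that("reactions on unknown alerts or before the firing are errors", {
  st <- fire_one()
  expect_error(record_reaction(st$log, "nope|x|2020-06-01", "override", "dr", AS_OF),
               "no fired alert")
  expect_error(record_reaction(st$log, st$alerts[[1]], "override", "dr", AS_OF - 1),
               "precedes")
})

test_that("only level-1 alerts block prescription completion", {
  st <- fire_one()
  expect_false(can_complete(st$log, "t1"))  # fired level 1, no reaction yet
  lvl1 <- st$alerts[[which(vapply(st$alerts, `[[`, 1L, "severity_level") == 1L)]]
  log2 <- record_reaction(st$log, lvl1, "override", "dr-a", AS_OF)
  expect_true(can_complete(log2, "t1"))

  # a patient with only level-2/3 alerts completes without any reaction
  labs <- c(list(cr_lab(1.0)), liver_labs())
  al <- evaluate(std_patient(id = "t2"), labs, list(rx("Cyclosporine")), KB,
                 as_of = AS_OF)
  log3 <- log_firing(audit_log(), al, at = AS_OF)
  expect_true(can_complete(log3, "t2"))
})

test_that("an overridden alert reappears at refill while its trigger holds", {
  st <- fire_one()
  lvl1_id <- "allopurinol-renal-10-20"
  log2 <- record_reaction(st$log, st$alerts[[1]], "override", "dr-a", AS_OF)
  labs <- list(cr_lab(cr_for_crcl(15, 40, 72, "male"), observed_at = AS_OF + 10))
  refill <- rx("Allopurinol", start = add_months(AS_OF, 1), kind = "refill")
  expect_true(should_reappear(log2, lvl1_id, std_patient(), labs, refill, KB))

  # condition resolved: clearance recovered above the band
  labs_ok <- list(cr_lab(cr_for_crcl(90, 40, 72, "male"), observed_at = AS_OF + 10))
  expect_false(should_reappear(log2, lvl1_id, std_patient(), labs_ok, refill, KB))

  # first-ever prescription: reappearance is just the trigger holding
  expect_true(should_reappear(audit_log(), lvl1_id, std_patient(), labs,
                              rx("Allopurinol", start = add_months(AS_OF, 1)), KB))
})

test_that("pregnancy alerts expire after nine months or at recorded termination", {
  det <- as.Date("2020-01-10")
  pr <- pregnancy_record(det)
  expect_true(pregnancy_alert_active(pr, add_months(det, 8)))
  expect_false(pregnancy_alert_active(pr, add_months(det, 10)))
  expect_false(pregnancy_alert_active(pr, add_months(det, 9)))  # boundary exclusive
  expect_true(pregnancy_alert_active(pr, add_months(det, 9) - 1))

  term <- pregnancy_record(det, termination_date = det + 60)
  expect_true(pregnancy_alert_active(term, det + 59))
  expect_false(pregnancy_alert_active(term, det + 60))
  expect_false(pregnancy_alert_active(term, det + 61))
})

test_that("the JSONL mirror round-trips and summarises per rule", {
  path <- file.path(tempdir(), "audit.jsonl")
  on.exit(unlink(path))
  labs <- list(cr_lab(cr_for_crcl(15, 40, 72, "male")))
  al <- evaluate(std_patient(), labs, list(rx("Allopurinol")), KB, as_of = AS_OF)
  log <- log_firing(audit_log(path), al, at = AS_OF)
  log <- record_reaction(log, al[[1]], "override", "dr-a", AS_OF)
  log <- record_reaction(log, al[[1]], "stop_medication", "dr-b", AS_OF + 1)

  back <- read_audit_log(path)
  expect_length(back$entries, length(log$entries))

  s <- audit_summary(back)
  row <- s[s$rule_id == "allopurinol-renal-10-20", ]
  expect_equal(row$firings, 1)
  expect_equal(row$reactions, 2)
  expect_equal(row$overrides, 1)
  expect_equal(row$stops, 1)
  expect_equal(row$override_rate, 0.5)
})
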