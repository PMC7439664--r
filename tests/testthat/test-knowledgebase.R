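test_that("the shipped KB has the expected shape and passes validation", {
  kb <- seeded_kb()
  expect_identical(validate_kb(kb), list())
  expect_equal(nrow(kb$medication_catalog), 8)
  expect_gte(length(kb$rules), 20)
  renal_allo <- Filter(function(r)
    r$medication == "Allopurinol" && r$category == "renal", kb$rules)
  expect_length(renal_allo, 3)
  # every severity-1 rule recommends stopping or adjusting
  for (r in Filter(function(r) r$severity == 1L, kb$rules))
    expect_true(r$action$kind %in%
                  c("avoid", "discontinue", "adjust_exact", "adjust_percent",
                    "adjust_interval", "adjust_cap"))
})

test_that("shipped rule constants carry the guideline numerals verbatim", {
  kb <- seeded_kb()
  get <- function(id) Filter(function(r) r$rule_id == id, kb$rules)[[1]]
  expect_equal(get("allopurinol-renal-10-20")$action$text,
               "prescribe 200 mg/day per oral")
  expect_equal(get("captopril-renal-10-50")$action$percent, 25)
  expect_equal(get("captopril-renal-lt10")$action$percent, 50)
  expect_match(get("mycophenolate-renal-lt25")$action$text,
               "do not exceed 1 g per oral twice daily")
  expect_match(get("omeprazole-hepatic-severe-10mg")$action$text,
               "10 mg once daily")
  b <- get("allopurinol-renal-10-20")$trigger
  expect_equal(c(b$lo, b$hi), c(10, 20))
  expect_true(b$lo_inclusive); expect_false(b$hi_inclusive)
})

test_that("a KB round-trips through YAML and JSON semantically unchanged", {
  kb <- seeded_kb()
  for (ext in c("yaml", "json")) {
    f <- file.path(tempdir(), paste0("kb.", ext))
    write_kb(kb, f)
    back <- load_kb(f)
    expect_equal(back$kb_version, kb$kb_version)
    expect_equal(back$medication_catalog, kb$medication_catalog)
    expect_equal(length(back$rules), length(kb$rules))
    expect_equal(vapply(back$rules, `[[`, "", "rule_id"),
                 vapply(kb$rules, `[[`, "", "rule_id"))
    # triggers and actions survive serialisation
    expect_equal(back$rules[[1]]$trigger, kb$rules[[1]]$trigger)
    expect_equal(back$rules[[1]]$action$text, kb$rules[[1]]$action$text)
    unlink(f)
  }
})

test_that("overlapping renal bands are a load error naming both rules", {
  catalog <- data.frame(atc = "M04", name = "Allopurinol")
  r1 <- rule("a", "Allopurinol", "M04", "renal", 1, crcl_in(10, 20),
             rule_action("adjust_exact", "x"))
  r2 <- rule("b", "Allopurinol", "M04", "renal", 1, crcl_in(15, 25),
             rule_action("adjust_exact", "y"))
  kb <- knowledge_base(list(r1, r2), catalog)
  f <- validate_kb(kb)
  expect_length(f, 1)
  expect_match(f[[1]]$message, "overlap")
  expect_match(f[[1]]$message, "'b'")

  path <- file.path(tempdir(), "overlap.yaml")
  write_kb(kb, path)
  expect_error(load_kb(path), "overlap")
  unlink(path)
})

test_that("touching half-open bands are accepted as disjoint", {
  catalog <- data.frame(atc = "M04", name = "Allopurinol")
  r1 <- rule("a", "Allopurinol", "M04", "renal", 1, crcl_in(3, 10),
             rule_action("adjust_exact", "x"))
  r2 <- rule("b", "Allopurinol", "M04", "renal", 1, crcl_in(10, 20),
             rule_action("adjust_exact", "y"))
  expect_identical(validate_kb(knowledge_base(list(r1, r2), catalog)), list())
})

test_that("invariant violations surface as findings for in-memory KBs", {
  catalog <- data.frame(atc = "C09", name = "Captopril")
  ok <- rule("r1", "Captopril", "C09", "renal", 1, crcl_in(10, 50),
             rule_action("adjust_percent", "reduce by 25%", percent = 25))
  kb <- knowledge_base(list(ok, ok), catalog)   # duplicate id
  expect_true(any(grepl("duplicate",
                        vapply(validate_kb(kb), `[[`, "", "message"))))

  bad_pct <- ok
  bad_pct$rule_id <- "r2"
  bad_pct$trigger <- crcl_in(0, 10, lo_inclusive = FALSE)
  bad_pct$action$percent <- 150
  f <- validate_kb(knowledge_base(list(bad_pct), catalog))
  expect_true(any(grepl("percent", vapply(f, `[[`, "", "message"))))

  sev1_monitor <- rule("r3", "Captopril", "C09", "monitoring", 1, p_always(),
                       rule_action("monitor", "m", analytes = "Na",
                                   schedule = list(baseline = TRUE)))
  f <- validate_kb(knowledge_base(list(sev1_monitor), catalog))
  expect_true(any(grepl("severity 1", vapply(f, `[[`, "", "message"))))
})

test_that("an empty KB is valid and produces no alerts", {
  kb <- knowledge_base(list(), data.frame(atc = character(), name = character()))
  expect_identical(validate_kb(kb), list())
  p <- std_patient()
  al <- evaluate(p, list(cr_lab(5)), list(rx("Allopurinol")), kb, as_of = AS_OF)
  expect_length(al, 0)
})

test_that("renal band coverage: bands plus the no-action region tile (0, Inf)", {
  kb <- seeded_kb()
  renal <- Filter(function(r) r$category == "renal", kb$rules)
  by_med <- split(renal, vapply(renal, `[[`, "", "medication"))
  for (med in names(by_med)) {
    bands <- lapply(by_med[[med]], function(r) collect_bands(r$trigger))
    bands <- do.call(rbind, bands)
    # probe a fine grid; each point must be claimed by at most one band
    for (x in c(0.5, 1, 2.9, 3, 9.99, 10, 15, 19.99, 20, 24, 25, 29, 30,
                45, 49.99, 50, 59, 60, 80, 120)) {
      claims <- sum(x >= bands$lo & x < bands$hi |
                      (x == bands$lo & bands$lo_inc) |
                      (x == bands$hi & bands$hi_inc))
      expect_lte(claims, 1)
    }
  }
})
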