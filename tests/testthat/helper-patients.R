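# Shared fixtures built in code. AS_OF anchors every evaluation; the
# standard test patient is 40 years old (exactly, in calendar months),
# 72 kg, 170 cm.
AS_OF <- as.Date("2020-06-01")
OBS <- AS_OF - 30

std_patient <- function(sex = "male", id = "t1", ...) {
  patient_record(id, sex, birth_date = add_months(AS_OF, -480),
                 weight = 72, height = 170, ...)
}

cr_lab <- function(value, observed_at = OBS) {
  lab_result("Cr", value, observed_at = observed_at)
}

liver_labs <- function(alt = 20, ast = 20, bili = 1.0, observed_at = OBS) {
  list(lab_result("ALT", alt, observed_at = observed_at),
       lab_result("AST", ast, observed_at = observed_at),
       lab_result("Bili_total", bili, observed_at = observed_at))
}

rx <- function(med, start = AS_OF, kind = "new") {
  prescription(med, start, event_kind = kind)
}

fired_ids <- function(alerts) sort(vapply(alerts, `[[`, "", "rule_id"))

# flatten a trigger's CrCl atoms into a band table
collect_bands <- function(trigger) {
  atoms <- dlicdss:::collect_atoms(trigger, "crcl_in")
  do.call(rbind, lapply(atoms, function(a)
    data.frame(lo = a$lo, hi = a$hi, lo_inc = isTRUE(a$lo_inclusive),
               hi_inc = isTRUE(a$hi_inclusive))))
}
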