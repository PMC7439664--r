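---
title: "Methods: a drug-laboratory interaction rule engine for transplant prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a drug-laboratory interaction rule engine for transplant prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlicdss)
```

## The decision model

`dlicdss` evaluates a declarative knowledge base of IF/THEN medication
safety rules against a patient's derived physiologic state at an explicit
instant. A rule is the atom: one medication, one trigger predicate, one
recommended action, a clinical severity level, and a message template.
Four rule categories cover the classic drug–laboratory interaction
failure modes in transplant outpatients: **renal** (dose bands over
creatinine clearance), **hepatic** (recommendations conditioned on a
liver-impairment tier), **pregnancy** (contraindications active while a
pregnancy episode is), and **monitoring** (baseline and follow-up lab
reminders that accompany every prescription of their medication).

The core assumption is that prescribing safety can be decided from (a)
demographics, (b) the *latest* value of each relevant analyte within a
bounded lookback window, and (c) a small set of recorded clinical facts
(cirrhosis history, pregnancy episodes). The engine deliberately has no
memory between evaluations: every prescription event — new, refill or
revision — re-derives state and re-fires whatever still holds. That is
what makes overrides safe to allow: an override is a reaction recorded in
the audit log, never a suppression of the rule.

## Derived physiologic state

**Creatinine clearance** uses Cockcroft–Gault,
$\mathrm{CrCl} = (140 - \text{age}) \cdot W / (72 \cdot S_{Cr})$,
times 0.85 for women, with age in years, weight in kg and serum
creatinine in mg/dl. Two deliberate choices:

* *Weight* is actual body weight by default (`crcl_weight = "actual"`);
  lean body mass (Hume) is a config toggle. LBM is computed but only
  feeds dosing rules that ask for it.
* *Units*: guideline thresholds for renal bands are conventionally
  printed per 1.73 m² body surface area while Cockcroft–Gault yields raw
  ml/min. The engine compares the raw value to the printed thresholds —
  the practice the shipped rules were curated under — and exposes
  `bsa_normalize` (Du Bois BSA, default off) for sites that prefer the
  normalised convention.

Age ≥ 140 makes the Cockcroft–Gault numerator vanish and is treated as a
domain error (unusable input), never as a zero or negative clearance.

**Hepatic impairment** is triangulated from three sources into two
tiers. Labs: impaired when ALT > 40 U/L or AST > 40 U/L or total
bilirubin > 1.5 mg/dl; severe when ALT > 120 or AST > 120 or bilirubin
> 3. (ALT thresholds are occasionally printed as "U/mL" in drug
references; that spelling is treated as a typographical variant of U/L —
clinical ALT is universally reported in U/L — and the numerals are used
unchanged.) History: a documented cirrhosis flag raises the tier to
severe. Scores: Child-Pugh class C raises the tier to severe. The two
non-lab contributions are best-effort reconstructions of clinical
"triangulation" and both are configurable
(`cirrhosis_implies_severe`, `child_pugh_c_implies_severe`). The state
distinguishes "no liver data in window" from "liver data normal" via a
`no_data` marker, and carries an evidence list naming every satisfied
criterion so alerts can cite their justification.

**Child-Pugh** is the standard five-parameter, 1–3-points-each scheme
(bilirubin < 2 / 2–3 / > 3 mg/dl; albumin > 3.5 / 2.8–3.5 / < 2.8 g/dl;
INR < 1.7 / 1.7–2.3 / > 2.3; ascites; encephalopathy), classes A = 5–6,
B = 7–9, C = 10–15. A missing parameter makes the score unavailable —
never silently zero.

## Numerical and temporal semantics

* **Strict comparisons.** Every threshold is compared exactly as
  written: `CrCl < 30` does not trigger at 30.0; `ALT > 40` does not
  trigger at 40.0. Band edges therefore behave predictably:
  `10 ≤ CrCl < 20` contains 10 and excludes 20.
* **Calendar months, half-open windows.** All durations ("within 6
  months", "expire after 9 months") are calendar months through a single
  shared utility (`add_months()`, day-clamped so Jan 31 + 1 month is
  Feb 28/29). The lab lookback window is `(as_of − 6 months, as_of]`: a
  result exactly six months old is excluded — a conservative freshness
  choice. Pregnancy expiry is boundary-exclusive the same way: the alert
  dies at the instant the ninth month completes, and immediately at a
  recorded termination date.
* **No in-window creatinine** means renal rules simply do not fire; the
  engine does not emit "order a creatinine" prompts, because creatinine
  is part of routine transplant follow-up and such reminders would be
  redundant noise.
* **Reproducibility.** Age is computed against the explicit `as_of`
  date, never the wall clock; evaluation is a pure function of (patient,
  labs, prescriptions, KB, date, config), and alert ordering is total:
  medication, severity ascending, rule id.

## Severity, colour and display

Severity is stored per rule but follows a fixed editorial mapping:
stop-or-adjust actions (avoid, discontinue, exact dose, percent
reduction, interval extension, dose cap) are level 1; starting-dose and
caution advice level 2; monitoring and supplementation level 3. The
display contract is a pair of engine-enforced laws: colour red/orange/
yellow if and only if severity 1/2/3, and interruptive display if and
only if severity 1. This is the alert-fatigue design: only
"stop it or change the dose" interrupts the prescriber; everything else
is a visual clue. The knowledge-base validator rejects any rule claiming
severity 1 with a non-stop/adjust action.

## The shipped knowledge base

`seeded_kb()` carries 25 rules for eight medications (Allopurinol,
Azathioprine, Captopril, Cyclosporine, Hydrochlorothiazide, Losartan,
Mycophenolate, Omeprazole), with recommendation text and numerals stored
verbatim. Curation choices where the source guidance is qualitative:

* *Azathioprine renal caution* — the guidance says "if renal impairment
  or oliguria exists" without a number; encoded as CrCl < 60 ml/min, the
  conventional renal-impairment boundary. It is a level-2 caution (it
  informs; it cannot prescribe a number).
* *Losartan CrCl < 30 + volume depletion* — no structured volume-status
  field exists; the rule triggers on the CrCl atom alone and states the
  volume-depletion condition in its message, at level 2.
* *"Monitor … periodically"* (Omeprazole) — no printed interval;
  defaults to every 6 months (`default_monitor_interval_months`),
  explicitly a KB curation default.
* *"1–2 weeks after the start"* (Captopril, Losartan Na/K) — scheduled
  at 14 days.
* *Cyclosporine monitoring* ("every 2 weeks in the first 3 months then
  monthly") — the machine-readable schedule stores the first-phase
  2-week repeat with the phase change in a free-text note; a two-phase
  schedule type was judged disproportionate for one rule.
* *Pregnancy positivity* — a qualitative `positive` flag on a bHCG
  result wins; without a flag, value > 5 mIU/mL
  (`bhcg_positive_threshold`) counts as positive.

Renal bands per medication must be pairwise disjoint (touching half-open
bands are fine); the loader reports every violation by rule id and never
drops a rule silently.

## Synthetic patients: what they do and do not show

**Boundary fixtures** (`fixture_patients()`) probe every numeric
threshold t in the KB at t − ε, t and t + ε with ε = 10⁻⁶ of the
threshold's unit. CrCl targets are reached by back-solving serum
creatinine through the inverted Cockcroft–Gault formula (per sex, at age
40 / 72 kg); because floating-point inversion can land a hair off the
nominal target, the expected alert set is computed on the *realised*
forward-evaluated clearance — by an independent, hand-coded per-rule
oracle, never by the engine under test. Cirrhosis, pregnancy
(active/absent/expired/terminated) and zero-prescription fixtures cover
the non-numeric triggers. The oracle-equivalence suite is the package's
analogue of iterating a pilot against manual review until sensitivity
and specificity are both 100%.

**Random cohorts** (`sample_cohort()`) emulate a transplant-clinic
outpatient population: 56% male; age mean 47.44 y in [20, 73]; weight
mean 72.07 kg in [45, 135]; Cr 1.57 ± 0.66 mg/dl, AST 19.64 ± 8.16 U/L,
ALT 21.14 ± 13.24 U/L (normals truncated at zero); eight medication
prevalences assigned independently. Modelling choices, since only means
and ranges are stated: ages and weights are truncated normals with
sd = range/5 (range ≈ mean ± 2.5 sd); heights (not profiled) are drawn
from sex-specific normals; the pregnancy rate among women (0.05) is a
modelling choice; correlations between labs, and between labs and
medications, are **not** modelled. Consequently the cohorts validate
engine throughput, determinism and the qualitative alert mix — a
monitoring-dominated spectrum with rare renal alerts, echoing what a
closely-monitored chronic cohort produces — but they cannot validate
calibration against real comorbidity structure, and passing tests on
them says nothing about real-world alert volumes.

Four of the profiled medications (Sirolimus, Diltiazem, Calcium,
Atorvastatin) have no shipped rules; they are kept in the profile so the
prescription mix is realistic, and they silently generate no alerts —
unknown medications are legal throughout.

## Problem sizes

The test suite evaluates the full fixture grid (about 184 fixtures, 650
rule decisions) plus cohorts of 25–60 patients for the property suites,
and one 10,000-patient cohort for moment recovery (male fraction within
±0.02, mean age within ±0.5 y, mean creatinine within ±0.05 mg/dl —
3-σ-scale binomial/normal sampling bounds). The acceptance script reruns
the grid, the 10,000-patient moments, and a 100-patient cohort for the
alert-mix summary; all of it completes in well under a minute.

## Known limitations

* The knowledge base ships eight medications; the schema (including a
  reserved `adjust_exact_table` action kind for CrCl-and-LBM-indexed
  dose nomograms such as digoxin's) extends to a full formulary, but no
  further content is included.
* Drug–drug interactions and drug interference with laboratory test
  interpretation are out of scope by design.
* Cockcroft–Gault from a single serum creatinine is an estimate, not a
  measured glomerular filtration rate; the engine inherits that
  imprecision.
* The engine is headless: `display_mode` is a machine-readable hint for
  a host prescribing system, not a UI.

```{r example}
kb <- seeded_kb()
p <- patient_record("ex", "male", "1980-06-01", weight = 72, height = 170)
labs <- list(lab_result("Cr", 6.67, observed_at = "2020-05-20"))
evaluate(p, labs, list(prescription("Allopurinol", "2020-06-01")),
         kb, as_of = "2020-06-01")
```
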