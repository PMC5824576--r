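# pcitriage

Predicting suboptimal cytoreductive surgery in advanced ovarian cancer
from the peritoneal carcinomatosis index (PCI).

## The problem

Most advanced epithelial ovarian cancers present with intraperitoneal
spread. Primary debulking surgery (PDS) improves survival only when it
leaves no residual tumor (complete cytoreduction, CCS) or residual
disease under 1 cm (optimal, OCS); a **suboptimal cytoreduction (SCS,
residual > 1 cm)** exposes the patient to major surgery without the
survival benefit. Units therefore need a preoperative rule for deciding
who goes to PDS and who to neoadjuvant chemotherapy with interval
debulking (NACT/IDS).

The tumor burden is quantified by Sugarbaker's PCI: thirteen
abdominopelvic regions are each scored 0–3 by largest implant size, and
the sum (0–39) is banded 1–10 / 11–20 / > 20. The PCI can be measured by
CT, by diagnostic laparoscopy, and at laparotomy; `pcitriage` implements
the rule **predict SCS iff PCI > 20** for each modality, the combined
criterion (positive only when *both* CT and laparoscopy exceed 20), and
the surrounding machinery:

- an unresectability screen (lung metastasis, hepatic metastasis in ≥ 3
  segments, severe hepatic pedicle involvement, progression after NACT,
  diffuse serous small-bowel disease) and a triage routine (screen →
  combined PCI rule → PDS);
- diagnostic accuracy: SEN = tp/(tp+fn), SPC = tn/(tn+fp), exact
  Clopper–Pearson 95% intervals, raw predictive values from counts, and
  **prevalence-standardized** predictive values via Bayes' theorem,

      PPV(p) = SEN·p / (SEN·p + (1−SPC)(1−p))
      NPV(p) = SPC·(1−p) / (SPC·(1−p) + (1−SEN)·p),

  which make predictive values comparable across units with different
  SCS rates;
- Youden-index cut-off selection (scan all 40 thresholds, maximize
  J = SEN + SPC − 1, ties toward the more specific rule);
- a CUSUM curve of observed-minus-expected major complications
  (Clavien–Dindo ≥ II) ordered by visceral-resection count, and Spearman
  correlation of resections with the intraoperative PCI;
- a seeded synthetic cohort generator emulating a PDS cohort (SCS
  prevalence 13.8%, intraoperative PCI median 12, 56% major-complication
  rate, ≥ 3 visceral resections whenever PCI > 20), so the whole pipeline
  is testable without patient data.

## Worked example

```r
library(pcitriage)

# predictive values of the combined rule (SEN 38%, SPC 98%) across
# hypothetical SCS prevalences
tab <- predictive_value_table(sen = 0.38, spc = 0.98,
                              prevalences = seq(0.1, 0.5, 0.1))
as_pct(tab$ppv)   #> 68 83 89 93 95
as_pct(tab$npv)   #> 93 86 79 70 61

# the laparotomy rule at its published operating point, standardized to
# an SCS prevalence of 13.8%
t <- confusion(predicted = c(rep(TRUE, 8), rep(FALSE, 3), rep(TRUE, 13), rep(FALSE, 56)),
               truth     = c(rep(TRUE, 11), rep(FALSE, 69)))
diagnostic_summary(t, prevalence = 0.138)
#> n=80  SEN 73% (39-94)  SPC 81% (70-90)  PPV 38% (18-62)  NPV 95% (86-99) (at prevalence 13.8%)

# a fully synthetic cohort end to end
g <- generate_cohort(generator_config(n_patients = 80, seed = 1))
print(make_report(g$cohort, cutoff = 20, reference_prevalence = 0.138, p0 = 0.56))
#> Cohort: n=80, intraoperative PCI median 12 (range 0-37)
#>   PCI bands: 1-10=34, 11-20=35, >20=11
#>   outcomes: CCS=67, OCS=3, SCS=10 (SCS prevalence 13%)
#>   ...
```

The first block reads: if a unit's true SCS rate is 10%, a combined
CT-and-laparoscopy positive is right 68% of the time and a negative is
right 93% of the time; at a 50% SCS rate those flip to 95% and 61%. The
second block shows the intraoperative rule: high sensitivity (73%) but,
at a 13.8% prevalence, a standardized PPV of only 38% — most flagged
patients would still achieve an adequate cytoreduction.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full
pipeline on a simulated cohort and write their tables under `results/`:

1. `01_simulate_cohort.R` — draw the 80-patient cohort (+ ground truth);
2. `02_diagnostic_accuracy.R` — per-rule accuracy report;
3. `03_prevalence_projection.R` — predictive values across prevalences;
4. `04_cutoff_selection.R` — Youden scan recovering the PCI > 20 cutoff;
5. `05_complication_risk.R` — CUSUM curve and Spearman correlation.

Run them in order from the repository root with `Rscript`.

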