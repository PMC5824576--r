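#!/usr/bin/env Rscript
# Step 2: diagnostic accuracy of the PCI > 20 rule per modality.
#
# For each rule (CT, laparoscopy, laparotomy, combined CT-and-laparoscopy)
# computes sensitivity and specificity with exact Clopper-Pearson
# intervals and predictive values standardized to the 13.8% reference SCS
# prevalence, over the patients holding the assessments each rule needs.

suppressPackageStartupMessages(library(pcitriage))

cohort <- read_cohort("results/cohort.csv")
report <- make_report(cohort, cutoff = 20, reference_prevalence = 0.138,
                      p0 = 0.56)
write_report(report, "results/report")
print(report)
cat("wrote results/report/{summary.json,diagnostics.csv,projection.csv,cusum.csv}\n")
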