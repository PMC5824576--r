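#!/usr/bin/env Rscript
# Step 3: predictive values as a function of SCS prevalence.
#
# Projects the combined CT-and-laparoscopy rule's published operating
# point (sensitivity 38%, specificity 98%) onto populations with SCS
# prevalence 10-50% via Bayes' theorem. PPV climbs and NPV falls with
# prevalence: a unit achieving few suboptimal surgeries cannot expect a
# high PPV from any preoperative rule.

suppressPackageStartupMessages(library(pcitriage))

dir.create("results", showWarnings = FALSE)
tab <- predictive_value_table(sen = 0.38, spc = 0.98,
                              prevalences = seq(0.1, 0.5, 0.1), ci_n = 80)
tab$ppv_pct <- as_pct(tab$ppv)
tab$npv_pct <- as_pct(tab$npv)
write.csv(tab, "results/prevalence_projection.csv", row.names = FALSE)

for (i in seq_len(nrow(tab))) {
  cat(sprintf("prevalence %2.0f%%: PPV %2d%% (%d-%d)  NPV %2d%% (%d-%d)\n",
              100 * tab$prevalence[i],
              tab$ppv_pct[i], as_pct(tab$ppv_lo[i]), as_pct(tab$ppv_hi[i]),
              tab$npv_pct[i], as_pct(tab$npv_lo[i]), as_pct(tab$npv_hi[i])))
}
cat("wrote results/prevalence_projection.csv\n")
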