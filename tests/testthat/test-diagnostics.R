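test_that("confusion counts partition the sample", {
  t <- confusion(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unclass(t)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  t2 <- confusion(rep(FALSE, 10), c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(t2$fn, 4L)
  expect_equal(t2$tp, 0L)
  g <- generate_cohort(generator_config(n_patients = 80, seed = 2))
  rp <- rule_predictions(g$cohort, "laparotomy")
  t3 <- confusion(rp$predicted, rp$truth)
  expect_equal(t3$tp + t3$fp + t3$fn + t3$tn, 80L)
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "same length")
  expect_error(confusion(NA, TRUE), "missing")
})

test_that("sensitivity and specificity match their count definitions", {
  t <- structure(list(tp = 8L, fp = 13L, fn = 3L, tn = 56L),
                 class = "two_by_two")
  acc <- sen_spc(t)
  expect_equal(acc$sen, 8 / 11)
  expect_equal(acc$spc, 56 / 69)
  # exact interval for 8/11 successes (frozen from the binomial oracle)
  expect_equal(unname(acc$sen_ci), c(0.390257, 0.939782), tolerance = 1e-5)
  t0 <- structure(list(tp = 5L, fp = 0L, fn = 0L, tn = 5L),
                  class = "two_by_two")
  acc0 <- sen_spc(t0)
  expect_equal(acc0$sen, 1)
  expect_equal(unname(acc0$sen_ci[2]), 1)
  tna <- structure(list(tp = 0L, fp = 2L, fn = 0L, tn = 3L),
                   class = "two_by_two")
  expect_error(sen_spc(tna), "sensitivity undefined")
})

test_that("Clopper-Pearson equals the brute-force binomial tail search", {
  # exhaustive over all k <= n <= 10, plus the frozen 3/8 example
  for (n in 1:10) for (k in 0:n) {
    expect_equal(unname(clopper_pearson(k, n)),
                 unname(cp_bruteforce(k, n)), tolerance = 1e-6,
                 label = sprintf("CP(%d, %d)", k, n))
  }
  expect_equal(unname(clopper_pearson(3, 8)), c(0.085233, 0.755137),
               tolerance = 1e-5)
})

test_that("raw predictive values come straight from the counts", {
  t <- structure(list(tp = 3L, fp = 1L, fn = 3L, tn = 56L),
                 class = "two_by_two")
  rv <- raw_predictive_values(t)
  expect_equal(rv$ppv_raw, 0.75)
  expect_equal(rv$npv_raw, 56 / 59)
  t0 <- structure(list(tp = 0L, fp = 4L, fn = 1L, tn = 5L),
                  class = "two_by_two")
  expect_equal(raw_predictive_values(t0)$ppv_raw, 0)
  tbad <- structure(list(tp = 0L, fp = 0L, fn = 1L, tn = 5L),
                    class = "two_by_two")
  expect_error(raw_predictive_values(tbad), "PPV undefined")
})

test_that("standardized predictive values implement Bayes' theorem", {
  expect_equal(standardized_ppv(0.38, 0.98, 0.10), 0.038 / 0.056)
  expect_equal(standardized_npv(0.38, 0.98, 0.10), 0.882 / 0.944)
  expect_equal(standardized_ppv(0.5, 1, 0.3), 1)   # no false positives
  expect_equal(standardized_npv(1, 0.5, 0.3), 1)   # no false negatives
  expect_error(standardized_ppv(1.2, 0.9, 0.1), "proportion")
  expect_error(standardized_ppv(0, 1, 0.5), "undefined")
})

test_that("standardized values at the empirical prevalence equal raw values", {
  set.seed(17)
  for (i in 1:20) {
    t <- structure(as.list(c(tp = sample(1:10, 1), fp = sample(1:10, 1),
                             fn = sample(1:10, 1), tn = sample(1:10, 1))),
                   class = "two_by_two")
    n <- t$tp + t$fp + t$fn + t$tn
    prev <- (t$tp + t$fn) / n
    acc <- sen_spc(t)
    rv <- raw_predictive_values(t)
    expect_equal(standardized_ppv(acc$sen, acc$spc, prev), rv$ppv_raw)
    expect_equal(standardized_npv(acc$sen, acc$spc, prev), rv$npv_raw)
  }
})

test_that("ppv rises and npv falls with prevalence", {
  p <- seq(0.01, 0.99, 0.01)
  ppv <- standardized_ppv(0.73, 0.81, p)
  npv <- standardized_npv(0.73, 0.81, p)
  expect_true(all(diff(ppv) > 0))
  expect_true(all(diff(npv) < 0))
})

test_that("predictive_value_table projects a rule across prevalences", {
  tab <- predictive_value_table(0.38, 0.98, seq(0.1, 0.5, 0.1))
  expect_equal(as_pct(tab$ppv), c(68, 83, 89, 93, 95))
  expect_equal(as_pct(tab$npv), c(93, 86, 79, 70, 61))
  # an uninformative rule returns the prevalence itself
  tab2 <- predictive_value_table(0.5, 0.5, c(0.2, 0.4))
  expect_equal(tab2$ppv, c(0.2, 0.4))
  expect_equal(tab2$npv, 1 - c(0.2, 0.4))
  expect_error(predictive_value_table(0.5, 0.5, c(0.4, 0.2)), "increasing")
  expect_error(predictive_value_table(0.5, 0.5, c(0, 0.5)), "inside")
  tab3 <- predictive_value_table(0.38, 0.98, 0.1, ci_n = 49)
  expect_true(all(tab3$ppv_lo <= tab3$ppv & tab3$ppv <= tab3$ppv_hi))
})

test_that("diagnostic_summary combines counts, intervals and standardization", {
  t <- structure(list(tp = 8L, fp = 13L, fn = 3L, tn = 56L),
                 class = "two_by_two")
  d <- diagnostic_summary(t, prevalence = 0.138)
  expect_equal(d$n, 80L)
  expect_equal(as_pct(d$sen), 73)
  expect_equal(as_pct(d$spc), 81)
  expect_equal(as_pct(d$ppv_std), 38)
  expect_equal(as_pct(d$npv_std), 95)
  expect_true(d$sen_ci[["lo"]] <= d$sen && d$sen <= d$sen_ci[["hi"]])
  expect_true(d$ppv_std_ci[["lo"]] <= d$ppv_std &&
                d$ppv_std <= d$ppv_std_ci[["hi"]])
})

test_that("the Youden scan matches an exhaustive independent search", {
  # perfectly separated data forces the boundary threshold
  pci <- c(rep(10L, 6), rep(25L, 4))
  truth <- c(rep(FALSE, 6), rep(TRUE, 4))
  sc <- roc_best_cutoff(pci, truth)
  expect_equal(sc$best_threshold, youden_bruteforce(pci, truth)$best_threshold)
  expect_equal(max(sc$scan$youden_j), 1)
  # separation boundary: any threshold in 10..24 attains J = 1, the scan
  # resolves the tie toward the largest
  expect_equal(sc$best_threshold, 24)

  set.seed(23)
  for (i in 1:10) {
    pci <- sample(0:39, 150, replace = TRUE)
    truth <- runif(150) < plogis(-4 + 0.2 * pci)
    if (!any(truth) || all(truth)) next
    sc <- roc_best_cutoff(pci, truth)
    bf <- youden_bruteforce(pci, truth)
    expect_equal(sc$best_threshold, bf$best_threshold)
    expect_equal(max(sc$scan$youden_j), bf$j)
    # input order is irrelevant
    perm <- sample(length(pci))
    expect_equal(roc_best_cutoff(pci[perm], truth[perm])$best_threshold,
                 sc$best_threshold)
  }
  expect_error(roc_best_cutoff(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("labels independent of the PCI give a near-zero Youden maximum", {
  set.seed(29)
  pci <- sample(0:39, 4000, replace = TRUE)
  truth <- runif(4000) < 0.3
  sc <- roc_best_cutoff(pci, truth)
  expect_lt(max(sc$scan$youden_j), 0.1)
})

test_that("rule predictions restrict to patients with the needed assessments", {
  df <- tiny_cohort_df()
  co <- as_cohort(df)
  # laparoscopy present only for patient B
  rp <- rule_predictions(co, "laparoscopy")
  expect_equal(rp$patient_id, "B")
  expect_true(rp$predicted)
  rp2 <- rule_predictions(co, "combined")
  expect_equal(rp2$patient_id, "B")
  rp3 <- rule_predictions(co, "ct")
  expect_equal(rp3$patient_id, c("A", "B", "C"))
  expect_equal(rp3$truth, c(FALSE, TRUE, FALSE))
})

test_that("cohort_diagnostics degrades gracefully without laparoscopy", {
  df <- tiny_cohort_df()
  df$lap_pci_total <- NA_integer_
  df[paste0("lap_r", 0:12)] <- NA_integer_
  co <- as_cohort(df)
  d <- suppressWarnings(cohort_diagnostics(co))
  expect_false("combined" %in% names(d))
  expect_false("laparoscopy" %in% names(d))
  expect_true(all(c("ct", "laparotomy") %in% names(d)))
})
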