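test_that("cusum accumulates observed minus expected in resection order", {
  df <- tiny_cohort_df()
  co <- as_cohort(df)
  cs <- cusum_curve(co, p0 = 0.56)
  # sorted ascending by resections: A (1), C (2), B (5)
  expect_equal(cs$points$patient_id, c("A", "C", "B"))
  expect_equal(cs$points$observed_major, c(0L, 0L, 1L))
  expect_equal(cs$points$cumulative, cumsum(c(0, 0, 1) - 0.56))

  # single-patient curves
  one <- as_cohort(df[2, ])
  expect_equal(cusum_curve(one, 0.56)$points$cumulative, 0.44)

  # default p0 is the empirical major-complication rate
  cs2 <- cusum_curve(co)
  expect_equal(cs2$p0, 1 / 3)
  expect_equal(cs2$points$cumulative[3], 0, tolerance = 1e-12)

  expect_error(cusum_curve(co, p0 = 1.2), "inside")
  df$clavien_dindo_grade[2] <- NA
  expect_error(cusum_curve(as_cohort(df)), "B")
})

test_that("the final cusum value telescopes for any cohort", {
  for (seed in c(3, 9)) {
    g <- generate_cohort(generator_config(n_patients = 60, seed = seed))
    cs <- cusum_curve(g$cohort, p0 = 0.56)
    n_obs <- sum(is_major_complication(g$cohort$clavien_dindo_grade))
    expect_equal(cs$points$cumulative[60], n_obs - 60 * 0.56,
                 tolerance = 1e-9)
    # tie-group boundaries are invariant to within-group order
    shuffled <- as_cohort(as.data.frame(g$cohort)[sample(60), ],
                          "shuffled")
    cs2 <- cusum_curve(shuffled, p0 = 0.56)
    ends <- function(cs) {
      idx <- cumsum(table(cs$points$visceral_resections))
      unname(cs$points$cumulative[idx])
    }
    expect_equal(ends(cs2), ends(cs), tolerance = 1e-9)
  }
})

test_that("the curve keeps climbing among high-resection patients", {
  g <- big_cohort(seed = 1)
  cs <- cusum_curve(g$cohort, p0 = 0.56)
  high <- cs$points$visceral_resections >= 8
  slope <- mean(diff(cs$points$cumulative[high]))
  expect_gte(slope, 0)
})

test_that("spearman_rho matches the rank-formula oracle and cor.test", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)

  x <- c(1, 2, 2, 3); y <- c(10, 20, 15, 30)
  r <- spearman_rho(x, y)
  expect_equal(r$rho, 0.9486833, tolerance = 1e-6)
  expect_equal(r$rho, spearman_bruteforce(x, y))

  set.seed(41)
  for (i in 1:10) {
    x <- sample(0:10, 30, replace = TRUE)
    y <- x + rnorm(30, sd = 3)
    r <- spearman_rho(x, y)
    expect_equal(r$rho, spearman_bruteforce(x, y))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    expect_equal(r$rho, unname(ct$estimate))
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-8)
    # invariance under strictly increasing transforms
    expect_equal(spearman_rho(exp(x), y)$rho, r$rho)
    expect_equal(spearman_rho(x, y^3 + 100 * y)$rho, r$rho)
  }
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("make_report assembles every section and rounds only at the edge", {
  g <- generate_cohort(generator_config(n_patients = 80, seed = 4,
                                        lap_avail_prob = 1))
  rep <- make_report(g$cohort, cutoff = 20, reference_prevalence = 0.138,
                     p0 = 0.56)
  expect_equal(sum(rep$cohort_summary$pci_band_counts), 80)
  expect_equal(sum(rep$cohort_summary$outcome_counts), 80)
  expect_true(all(c("ct", "laparoscopy", "laparotomy", "combined") %in%
                    names(rep$diagnostics)))
  expect_equal(nrow(rep$projection), 5)
  expect_equal(rep$cusum$p0, 0.56)
  expect_false(is.null(rep$spearman))
  # summaries carry proportions; percentages appear only in printed output
  expect_true(all(vapply(rep$diagnostics, function(d)
    d$sen <= 1 && d$spc <= 1 && d$ppv_std <= 1, logical(1))))

  # a cohort without laparoscopy still reports, minus the combined parts
  df <- as.data.frame(g$cohort)
  df$lap_pci_total <- NA_integer_
  df[paste0("lap_r", 0:12)] <- NA_integer_
  rep2 <- make_report(as_cohort(df), p0 = 0.56)
  expect_null(rep2$projection)
  expect_false("combined" %in% names(rep2$diagnostics))

  # writing emits the tabular sections
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("summary.json",
                                               "diagnostics.csv",
                                               "projection.csv",
                                               "cusum.csv")))))
  proj <- read.csv(file.path(dir, "projection.csv"))
  expect_equal(nrow(proj), 5)
})

test_that("a fixed-sen/spc projection reproduces the five-row table", {
  tab <- predictive_value_table(0.38, 0.98, seq(0.1, 0.5, 0.1), ci_n = 80)
  expect_equal(as_pct(tab$ppv), c(68, 83, 89, 93, 95))
  expect_equal(as_pct(tab$npv), c(93, 86, 79, 70, 61))
})
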