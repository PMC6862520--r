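test_that("Mann-Whitney U uses exact enumeration for small tie-free groups", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_two_sided, 0.1)            # 2 * 3!3!/6! by enumeration
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_two_sided, 0.99)
  sep <- mann_whitney_u(1:3, 10:39)            # 3 vs 30, fully separated
  expect_equal(sep$U, 0)
  expect_equal(sep$p_two_sided, 2 / choose(33, 3), tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("AUROC is the pair-ordering probability with ties at one half", {
  expect_equal(auroc(c(1, 2, 10, 11), c(0, 0, 1, 1), n_boot = 0)$auc, 1.0)
  expect_equal(auroc(rep(1, 6), c(0, 1, 0, 1, 0, 1), n_boot = 0)$auc, 0.5)
  expect_equal(auroc(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1), n_boot = 0)$auc,
               0.75)                           # 3 of 4 pairs ordered
  expect_error(auroc(1:4, c(1, 1, 1, 1), n_boot = 0), "both label classes")
})

test_that("AUROC equals U/(n1*n2) and matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:10) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    scores <- c(rnorm(n1, 1), rnorm(n0))
    labels <- c(rep(1, n1), rep(0, n0))
    got <- auroc(scores, labels, n_boot = 0)$auc
    U <- mann_whitney_u(scores[labels == 1], scores[labels == 0])$U
    expect_equal(got, U / (n1 * n0), tolerance = 1e-12)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("bootstrap AUROC interval collapses under perfect separation", {
  scores <- c(rnorm(20, 0, 0.05), rnorm(10, 1.5, 0.05))
  labels <- c(rep(0, 20), rep(1, 10))
  au <- auroc(scores, labels, n_boot = 500, seed = 1)
  expect_equal(au$auc, 1.0)
  expect_equal(c(au$ci_low, au$ci_high), c(1, 1))
})

test_that("ROC points are monotone and integrate to the AUROC", {
  set.seed(21)
  for (i in 1:5) {
    scores <- round(rnorm(30), 1)              # ties likely
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) next
    pts <- roc_points(scores, labels)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0),
                 ignore_attr = TRUE)
    trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                   utils::tail(pts$tpr, -1)) / 2)
    expect_equal(trap, auroc(scores, labels, n_boot = 0)$auc,
                 tolerance = 1e-12)
  }
  tiny <- roc_points(c(1, 2), c(0, 1))
  expect_equal(tiny$fpr, c(0, 0, 1))
  expect_equal(tiny$tpr, c(0, 1, 1))
})

test_that("linear fit reproduces closed-form least squares", {
  exact <- linear_fit(0:5, 2 * (0:5))
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
  hand <- linear_fit(c(0, 1, 2), c(0, 1, 3))
  expect_equal(hand$slope, 1.5)
  expect_equal(hand$intercept, -1 / 6, tolerance = 1e-12)
  expect_equal(hand$r_squared, 81 / 84, tolerance = 1e-12)
  theo <- linear_fit(c(0, 0.05, 0.1, 0.3, 0.5, 0.7, 1),
                     expected_ratio(c(0, 0.05, 0.1, 0.3, 0.5, 0.7, 1)))
  expect_equal(theo$slope, 0.5, tolerance = 1e-12)
  expect_equal(theo$intercept, 1, tolerance = 1e-12)
  expect_error(linear_fit(rep(2, 5), 1:5), "degenerate")
})

test_that("r-squared is invariant to affine rescaling of x", {
  set.seed(31)
  x <- runif(12); y <- 1 + 0.5 * x + rnorm(12, 0, 0.05)
  base <- linear_fit(x, y)$r_squared
  expect_equal(linear_fit(10 + 7 * x, y)$r_squared, base, tolerance = 1e-12)
  expect_equal(linear_fit(-x, y)$r_squared, base, tolerance = 1e-12)
})

test_that("detection limit is the onset of stable cutoff exceedance", {
  grid <- seq(0.1, 1, by = 0.1)
  means <- expected_ratio(grid)
  expect_equal(detection_limit(grid, means, cutoff = 1.068), 0.2)
  expect_equal(detection_limit(grid, means, cutoff = 1.145), 0.3)
  expect_true(is.na(detection_limit(grid, means, cutoff = 2.0)))
  # non-increasing as the cutoff decreases
  lims <- vapply(c(1.4, 1.2, 1.1, 1.02), function(ct)
    detection_limit(grid, means, ct), numeric(1))
  expect_true(all(diff(lims) <= 0))
  # a dip above the cutoff does not count without stable exceedance
  dip <- c(1.2, 1.05, 1.2, 1.3)
  expect_equal(detection_limit(c(0.1, 0.2, 0.3, 0.4), dip, 1.1), 0.3)
  # CI-lower mode is at least as conservative
  reps <- lapply(grid, function(f) expected_ratio(f) + c(-0.05, 0, 0.05))
  expect_gte(detection_limit(grid, reps, 1.068, use_ci_lower = TRUE),
             detection_limit(grid, reps, 1.068))
})

test_that("cohort evaluation handles empty classes and shuffled labels", {
  co <- simulate_cohort(cohort_spec(n_t21 = 0, n_t18 = 0, n_t13 = 0,
                                    n_monosomy_x = 0, n_xxxy = 0,
                                    n_euploid_male = 3,
                                    n_euploid_female = 3), seed = 4)
  reps <- call_samples(co)
  ev <- cohort_summary(reps, co$samples, n_boot = 0)
  expect_match(ev$T21$note, "not-applicable")
  # permuted labels destroy the association
  set.seed(6)
  scores <- rnorm(200)
  labels <- sample(rep(0:1, 100))
  expect_lt(abs(auroc(scores, labels, n_boot = 0)$auc - 0.5), 0.15)
  expect_error(cohort_summary(reps, co$samples[-1, ], n_boot = 0), "truth")
})
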