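test_that("mixture copy numbers and theoretical ratios are linear in f", {
  expect_equal(effective_copy_number(2, 0), 2.0)
  expect_equal(effective_copy_number(2, 1), 3.0)
  expect_equal(effective_copy_number(2, 0.3), 2.3)
  expect_equal(expected_ratio(c(0, 0.2, 1)), c(1.0, 1.10, 1.5))
})

test_that("simulated chips follow the Poisson well-occupancy model", {
  # empty reaction, noise off: every well negative
  empty <- simulate_chip(c(FAM = 0, VIC = 0), noise = noise_off(), seed = 1)
  expect_equal(empty$n_negative, 20000L)
  # FAM positives near the closed-form expectation N * (1 - exp(-C * Vp))
  chip <- simulate_chip(c(FAM = 1000, VIC = 0), noise = noise_off(), seed = 7)
  p <- 1 - exp(-0.809)
  expect_lt(abs((chip$n_fam_only + chip$n_double) - 20000 * p),
            3 * sqrt(20000 * p * (1 - p)))
  # saturation regime
  sat <- simulate_chip(c(FAM = 50000, VIC = 50000), noise = noise_off(),
                       seed = 2)
  expect_gte((sat$n_fam_only + sat$n_double) / 20000, 0.999)
  expect_error(simulate_chip(c(FAM = -5, VIC = 10)), "non-negative")
})

test_that("every generated chip conserves well counts", {
  set.seed(11)
  for (i in 1:25) {
    conc <- stats::runif(2, 0, 3000)
    chip <- simulate_chip(c(FAM = conc[1], VIC = conc[2]),
                          noise = noise_params())
    expect_equal(chip$n_fam_only + chip$n_vic_only + chip$n_double +
                   chip$n_negative, chip$n_wells)
  }
  cohort <- simulate_cohort(cohort_spec(n_t21 = 1, n_t18 = 1, n_t13 = 1,
                                        n_monosomy_x = 1, n_xxxy = 1,
                                        n_euploid_male = 2,
                                        n_euploid_female = 2), seed = 5)
  expect_silent(validate_chips(cohort$chips))
})

test_that("identical spec and seed give byte-identical datasets", {
  a <- simulate_cohort(cohort_spec0(n_t21 = 2, n_euploid_female = 3), seed = 42)
  b <- simulate_cohort(cohort_spec0(n_t21 = 2, n_euploid_female = 3), seed = 42)
  expect_identical(a, b)
  s1 <- simulate_dilution_series(mixture_spec("18"), seed = 9)
  s2 <- simulate_dilution_series(mixture_spec("18"), seed = 9)
  expect_identical(s1, s2)
})

test_that("sample simulation reproduces karyotype dosage in expectation", {
  cfg <- run_config()
  # euploid male: autosome ratios ~1, SRY clearly positive
  em <- simulate_sample(karyotype_profile("euploid", "male", "em"),
                        noise = noise_off(), replicates = 10, seed = 1)
  rt <- chip_ratios(em, cfg)
  expect_lt(abs(mean(rt$ratio_fam_vic[rt$panel == "13-21"]) - 1), 0.02)
  p3 <- em[em$panel == "X-SRY", ]
  expect_true(all(p3$n_fam_only + p3$n_double > 1000))
  # pure trisomy 21: chr21:chr13 ratio ~1.5
  t21 <- simulate_sample(karyotype_profile("T21", "male", "t21"),
                         noise = noise_off(), replicates = 10, seed = 2)
  rt21 <- chip_ratios(t21, cfg)
  expect_lt(abs(mean(rt21$ratio_fam_vic[rt21$panel == "13-21"]) - 1.5), 0.02)
})

test_that("maternal contamination pulls the trisomy ratio toward euploid", {
  # contaminated T21 male, m = 0.61: expected ratio 1 + (1 - m)/2 = 1.195,
  # the regime of the intermediate clinical case (observed 1.193)
  prof <- karyotype_profile("T21", "male", "mcc",
                            contamination_fraction = 0.61)
  chips <- simulate_sample(prof, noise = noise_off(), replicates = 20,
                           seed = 3)
  rt <- chip_ratios(chips)
  m21 <- mean(rt$ratio_fam_vic[rt$panel == "13-21"])
  expect_lt(abs(m21 - 1.195), 0.02)
  # full contamination erases the fetal signal regardless of profile
  full <- karyotype_profile("T21", "male", "full", contamination_fraction = 1)
  expect_equal(unname(dpcrscreen:::blended_copy_numbers(full)),
               c(2, 2, 2, 2, 0))
})

test_that("mean simulated ratio converges to 1 + f/2", {
  set.seed(33)
  for (f in c(0.3, 0.7)) {
    spec <- mixture_spec("21", fractions = c(0, f), replicates_per_point = 100)
    fit <- dilution_fit(simulate_dilution_series(spec, noise = noise_off()))
    got <- fit$table$mean_ratio[fit$table$fraction == f]
    expect_lt(abs(got - (1 + f / 2)), 0.01)
  }
})

test_that("the default cohort matches the validation-study composition", {
  spec <- cohort_spec()
  expect_equal(spec$n_total, 133)
  expect_equal(unname(spec$counts[c("T21", "T18", "T13", "monosomy_X",
                                    "XXXY")]), c(17, 9, 3, 1, 1))
  co <- simulate_cohort(cohort_spec0(n_t21 = 1, n_euploid_female = 1), seed = 1)
  # triplicate chips on each of three panels per sample
  expect_equal(nrow(co$chips), 2 * 3 * 3)
  expect_equal(sort(unique(co$chips$panel)), c("13-18", "13-21", "X-SRY"))
})
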