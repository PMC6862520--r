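test_that("ratio bands classify euploid, trisomy and the gap", {
  expect_equal(classify_autosome(0.981)$class, "euploid")
  full <- classify_autosome(1.505)
  expect_equal(full$class, "trisomy")
  expect_length(full$flags, 0)
  expect_equal(classify_autosome(1.12)$class, "inconclusive")
  # intermediate ratio: trisomy call flagged as possible mosaic/contamination
  mid <- classify_autosome(1.193)
  expect_equal(mid$class, "trisomy")
  expect_true("intermediate_possible_mosaic_or_contamination" %in% mid$flags)
  low <- classify_autosome(0.6)
  expect_equal(low$class, "inconclusive")
  expect_true("below_euploid_range" %in% low$flags)
})

test_that("every positive ratio maps to exactly one class", {
  bands <- classification_bands()
  for (r in seq(0.05, 2.5, by = 0.012)) {
    cls <- classify_autosome(r, bands)$class
    expect_true(cls %in% c("euploid", "trisomy", "inconclusive"))
    # band arithmetic is mutually exclusive by construction; spot-check edges
  }
  expect_equal(classify_autosome(0.9)$class, "euploid")
  expect_equal(classify_autosome(1.1)$class, "euploid")
  expect_equal(classify_autosome(1.15)$class, "trisomy")
})

test_that("aneuploid fraction inverts the mixture relation", {
  f <- seq(0, 1, by = 0.01)
  expect_equal(estimate_aneuploid_fraction(expected_ratio(f)), f,
               tolerance = 1e-12)
  expect_equal(estimate_aneuploid_fraction(1.193), 0.386, tolerance = 1e-12)
  expect_warning(got <- estimate_aneuploid_fraction(0.97), "baseline")
  expect_equal(got, 0)
  expect_equal(estimate_aneuploid_fraction(1.8), 1)  # clamped
})

test_that("sex-chromosome calls compose X dosage with SRY detection", {
  bands <- classification_bands()
  call <- function(r, sry_conc, wells)
    call_sex_chromosomes(r * 500, sry_conc, 500, bands,
                         sry_positive_wells = wells)$class
  expect_equal(call(0.5, 250, 4000), "XY")
  expect_equal(call(0.5, 0.2, 3), "monosomy_X")
  expect_equal(call(1.0, 0.2, 3), "XX")
  expect_equal(call(1.5, 250, 4000), "multiple_X_with_Y")
  expect_equal(call(0.75, 250, 4000), "inconclusive")  # between bands
  expect_equal(call(1.0, 250, 4000), "inconclusive")   # XX with Y signal
  # SRY floor: concentration alone is not enough
  expect_equal(call(0.5, 50, 10), "monosomy_X")
  expect_error(call_sex_chromosomes(250, 250, 0, bands,
                                    sry_positive_wells = 100),
               "reference")
})

test_that("chip QC flags count mismatches, saturation and range excursions", {
  cfg <- run_config()
  good <- simulate_chip(c(FAM = 500, VIC = 500), seed = 1)
  expect_true(qc_chip(good, cfg)$pass)
  bad <- good; bad$n_negative <- bad$n_negative + 5L
  expect_equal(qc_chip(bad, cfg)$reasons, "count_mismatch")
  sat <- chip_readout("s", "c", "13-21", 100, 0, 0, 100, 0)
  expect_true("saturation" %in% qc_chip(sat, cfg)$reasons)
  # out-of-range reference is a warning by default, a failure when strict
  lowc <- simulate_chip(c(FAM = 50, VIC = 50), seed = 2)
  q <- qc_chip(lowc, cfg)
  expect_true(q$pass)
  expect_match(q$warnings, "out_of_range")
  expect_false(qc_chip(lowc, cfg, strict_range = TRUE)$pass)
})

test_that("replicate aggregation classifies the mean and flags discordance", {
  a <- aggregate_replicates(c(1.49, 1.51, 1.50), chromosome = "21")
  expect_equal(a$ratio, 1.50)
  expect_equal(a$class, "trisomy")
  b <- aggregate_replicates(c(0.98, 1.02))
  expect_equal(b$class, "euploid")
  d <- aggregate_replicates(c(0.98, 1.52))
  expect_equal(d$class, "inconclusive")
  expect_true("repeat_test" %in% d$flags)
  expect_error(aggregate_replicates(numeric(0)), "no QC-passing")
})

test_that("simulated karyotypes round-trip through the caller", {
  for (seed in 1:5) {
    t21 <- simulate_sample(karyotype_profile("T21", "female", "t"),
                           noise = noise_off(), seed = seed)
    rep_t <- call_samples(t21)
    expect_equal(rep_t$call_21, "trisomy")
    expect_equal(rep_t$call_18, "euploid")
    eu <- simulate_sample(karyotype_profile("euploid", "male", "e"),
                          noise = noise_off(), seed = seed)
    rep_e <- call_samples(eu)
    expect_equal(rep_e$call_21, "euploid")
    expect_equal(rep_e$call_sex, "XY")
  }
})

test_that("sample reports carry every panel and the QC verdict", {
  co <- simulate_cohort(cohort_spec0(n_t21 = 1, n_monosomy_x = 1, n_xxxy = 1,
                                    n_euploid_female = 1), seed = 8)
  reps <- call_samples(co)
  expect_equal(nrow(reps), 4)
  expect_true(all(c("chr13_ratio", "chr18_ratio", "chr21_ratio", "sex_ratio",
                    "sry_detected", "call_13", "call_18", "call_21",
                    "call_sex", "flags", "qc") %in% names(reps)))
  expect_true(all(reps$qc == "9/9"))
  k <- co$samples$karyotype
  expect_equal(reps$call_sex[k == "monosomy_X"], "monosomy_X")
  expect_equal(reps$call_sex[k == "XXXY"], "multiple_X_with_Y")
  expect_equal(reps$call_sex[k == "euploid" & co$samples$sex == "female"], "XX")
})
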