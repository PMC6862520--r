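# Run code with a locally-set RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Well-level and chip-level noise parameters for the simulator
#'
#' @param chip_cv Coefficient of variation of the per-chip lognormal
#'   pipetting/loading factor applied to the genome concentration
#'   (default 2%). The factor is shared by both dye channels of a chip, so
#'   chromosomal ratios within a chip are unaffected; cross-chip
#'   comparisons (X:autosome dosage) are not.
#' @param fp_rate Probability that a truly negative well is called
#'   positive (default 2e-4) — sparse "rain" above the threshold.
#' @param fn_rate Probability that a truly positive well is called
#'   negative (default 1e-3).
#' @return Object of class `dpcr_noise`.
#' @export
noise_params <- function(chip_cv = 0.02, fp_rate = 2e-4, fn_rate = 1e-3) {
  stopifnot(chip_cv >= 0, chip_cv < 1,
            fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate < 1)
  structure(list(chip_cv = chip_cv, fp_rate = fp_rate, fn_rate = fn_rate),
            class = "dpcr_noise")
}

#' Noise-free simulator settings
#' @return A [noise_params()] object with all rates zero.
#' @export
noise_off <- function() noise_params(0, 0, 0)

#' Effective copy number of a chromosome in a mosaic mixture
#'
#' In a mixture where a fraction `f` of genomes carries one extra copy of
#' a chromosome, the population-average copy number of that chromosome is
#' `base*(1-f) + (base+1)*f`. Chromosomes not involved keep their base.
#'
#' @param base Copies per genome in the unaffected population (0-3).
#' @param extra_fraction Fraction `f` of genomes with the extra copy.
#' @return Average copies per genome (dimensionless).
#' @examples
#' effective_copy_number(2, 0.3)  # 2.3
#' @export
effective_copy_number <- function(base, extra_fraction) {
  stopifnot(base %in% 0:3, extra_fraction >= 0, extra_fraction <= 1)
  base * (1 - extra_fraction) + (base + 1) * extra_fraction
}

#' Theoretical chromosomal ratio of a trisomy mixture
#'
#' For a mixture with trisomic fraction `f` over a disomic reference the
#' expected target:reference ratio is `1 + f/2`: 1 for euploid material,
#' 1.5 for pure trisomy.
#'
#' @param f Trisomic fraction in \[0, 1\] (vectorised).
#' @return Expected ratio(s).
#' @export
expected_ratio <- function(f) {
  stopifnot(all(f >= 0), all(f <= 1))
  1 + f / 2
}

#' Ground-truth profile of one simulated sample
#'
#' Describes what is actually in the reaction: per-chromosome copy numbers
#' of the aberrant karyotype, the fraction `f` of genomes carrying it
#' (mosaicism; the remaining `1-f` are euploid of the same sex), a
#' maternal-contamination fraction `m` of euploid female genomes, and the
#' genome concentration.
#'
#' @param sample_id Label.
#' @param copy_numbers Named integer vector over chromosomes
#'   `c("13","18","21","X","Y")`: copies per genome of the (possibly
#'   aberrant) karyotype, e.g. `c("13"=2,"18"=2,"21"=3,"X"=1,"Y"=1)` for a
#'   trisomy-21 male.
#' @param trisomic_fraction Fraction `f` in \[0,1\] of genomes carrying the
#'   profile karyotype; `1` for a non-mosaic sample.
#' @param contamination_fraction Fraction `m` in \[0,1\] of euploid female
#'   (maternal) genomes admixed into the reaction.
#' @param genome_conc Genome equivalents per uL; scaled so that a disomic
#'   autosome channel at `genome_conc = 500` measures 500 copies/uL
#'   (concentration of a locus = `genome_conc * copies / 2`).
#' @return Object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, copy_numbers,
                           trisomic_fraction = 1,
                           contamination_fraction = 0,
                           genome_conc = 500) {
  chroms <- c("13", "18", "21", "X", "Y")
  if (!all(chroms %in% names(copy_numbers)))
    stop("copy_numbers must name chromosomes ",
         paste(chroms, collapse = ", "), call. = FALSE)
  cn <- copy_numbers[chroms]
  if (any(cn < 0) || any(cn != floor(cn)))
    stop("copy numbers must be non-negative integers", call. = FALSE)
  stopifnot(trisomic_fraction >= 0, trisomic_fraction <= 1,
            contamination_fraction >= 0, contamination_fraction <= 1,
            genome_conc > 0)
  structure(list(sample_id = as.character(sample_id),
                 copy_numbers = cn,
                 trisomic_fraction = trisomic_fraction,
                 contamination_fraction = contamination_fraction,
                 genome_conc = genome_conc),
            class = "sample_profile")
}

#' Preset karyotype profiles
#'
#' Convenience constructor for the karyotype classes of the screening
#' cohort.
#'
#' @param karyotype One of `"euploid"`, `"T13"`, `"T18"`, `"T21"`,
#'   `"monosomy_X"`, `"XXXY"`.
#' @param sex `"male"` or `"female"` (ignored for `monosomy_X`/`XXXY`).
#' @param sample_id Label.
#' @param ... Passed to [sample_profile()] (`trisomic_fraction`,
#'   `contamination_fraction`, `genome_conc`).
#' @return A [sample_profile()].
#' @export
karyotype_profile <- function(karyotype = c("euploid", "T13", "T18", "T21",
                                            "monosomy_X", "XXXY"),
                              sex = c("female", "male"),
                              sample_id = karyotype, ...) {
  karyotype <- match.arg(karyotype)
  sex <- match.arg(sex)
  cn <- c("13" = 2, "18" = 2, "21" = 2,
          "X" = if (sex == "male") 1 else 2,
          "Y" = if (sex == "male") 1 else 0)
  cn <- switch(karyotype,
    euploid = cn,
    T13 = {cn["13"] <- 3; cn},
    T18 = {cn["18"] <- 3; cn},
    T21 = {cn["21"] <- 3; cn},
    monosomy_X = c("13" = 2, "18" = 2, "21" = 2, "X" = 1, "Y" = 0),
    XXXY = c("13" = 2, "18" = 2, "21" = 2, "X" = 3, "Y" = 1))
  sample_profile(sample_id, cn, ...)
}

# Population-average copy numbers after blending mosaicism and maternal
# contamination. The euploid complement of a mosaic sample keeps the
# fetal sex; the maternal contaminant is euploid female.
blended_copy_numbers <- function(profile) {
  male <- profile$copy_numbers["Y"] > 0
  baseline <- c("13" = 2, "18" = 2, "21" = 2,
                "X" = if (male) 1 else 2, "Y" = if (male) 1 else 0)
  maternal <- c("13" = 2, "18" = 2, "21" = 2, "X" = 2, "Y" = 0)
  f <- profile$trisomic_fraction
  m <- profile$contamination_fraction
  fetal <- f * profile$copy_numbers + (1 - f) * baseline
  (1 - m) * fetal + m * maternal
}

#' Simulate one duplex chip
#'
#' Generative counterpart of the Poisson quantification model. Each well
#' receives each target independently with occupancy
#' `lambda = C * Vp / D`; the well is channel-positive with probability
#' `1 - exp(-lambda)`. False-positive/false-negative call flips are
#' applied at the configured well-level rates. The four joint counts are
#' drawn from the implied multinomial, so count conservation holds by
#' construction.
#'
#' @param channel_concs Named numeric `c(FAM = ..., VIC = ...)` in
#'   copies/uL.
#' @param config A [run_config()].
#' @param noise A [noise_params()] (chip_cv is not applied here; it
#'   belongs to sample-level simulation).
#' @param n_wells Wells on the chip.
#' @param dilution_factor D (>= 1).
#' @param sample_id,chip_id,panel Labels stored in the readout.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return One-row chip readout data.frame.
#' @examples
#' simulate_chip(c(FAM = 1000, VIC = 500), seed = 1)
#' @export
simulate_chip <- function(channel_concs, config = run_config(),
                          noise = noise_params(),
                          n_wells = config$n_wells_default,
                          dilution_factor = 1,
                          sample_id = "sim", chip_id = "chip1",
                          panel = "13-21", seed = NULL) {
  if (!all(c("FAM", "VIC") %in% names(channel_concs)))
    stop("channel_concs must name FAM and VIC", call. = FALSE)
  if (any(channel_concs < 0) || any(!is.finite(channel_concs)))
    stop("channel concentrations must be finite and non-negative",
         call. = FALSE)
  with_seed(seed, {
    lam <- channel_concs[c("FAM", "VIC")] *
      config$partition_volume_ul / dilution_factor
    p <- -expm1(-lam)
    # call flips fold into the per-well positive probability
    p <- p * (1 - noise$fn_rate) + (1 - p) * noise$fp_rate
    probs <- c(double   = p[["FAM"]] * p[["VIC"]],
               fam_only = p[["FAM"]] * (1 - p[["VIC"]]),
               vic_only = (1 - p[["FAM"]]) * p[["VIC"]],
               negative = (1 - p[["FAM"]]) * (1 - p[["VIC"]]))
    cnt <- stats::rmultinom(1, size = n_wells, prob = probs)[, 1]
    chip_readout(sample_id, chip_id, panel, n_wells,
                 n_fam_only = cnt[["fam_only"]],
                 n_vic_only = cnt[["vic_only"]],
                 n_double = cnt[["double"]],
                 n_negative = cnt[["negative"]],
                 dilution_factor = dilution_factor)
  })
}

#' Simulate all chips of one sample
#'
#' Emits `replicates` chips per panel. Channel concentrations follow the
#' blended copy numbers of the profile (mosaicism and maternal
#' contamination applied), scaled by `genome_conc` and a per-chip
#' lognormal pipetting factor (mean 1, CV `noise$chip_cv`) shared by the
#' two channels of each chip.
#'
#' @param profile A [sample_profile()].
#' @param panels List of [duplex_assay()]s; default [default_panels()].
#' @param replicates Chips per panel (default 3, the triplicate design).
#' @param config A [run_config()].
#' @param noise A [noise_params()].
#' @param seed Optional integer seed.
#' @return data.frame of chip readouts (`replicates * length(panels)`
#'   rows).
#' @export
simulate_sample <- function(profile, panels = default_panels(),
                            replicates = 3, config = run_config(),
                            noise = noise_params(), seed = NULL) {
  stopifnot(inherits(profile, "sample_profile"), replicates >= 1)
  cn <- blended_copy_numbers(profile)
  sdlog <- sqrt(log1p(noise$chip_cv^2))
  with_seed(seed, {
    chips <- list()
    for (r in seq_len(replicates)) {
      for (pa in panels) {
        fac <- if (sdlog > 0)
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
        conc <- c(FAM = unname(profile$genome_conc * cn[pa$fam_chrom] / 2),
                  VIC = unname(profile$genome_conc * cn[pa$vic_chrom] / 2)) * fac
        chips[[length(chips) + 1L]] <- simulate_chip(
          conc, config, noise,
          sample_id = profile$sample_id,
          chip_id = paste(profile$sample_id, pa$panel_id, r, sep = "_"),
          panel = pa$panel_id)
      }
    }
    do.call(rbind, chips)
  })
}

#' Specification of a trisomy dilution series
#'
#' @param trisomy_chrom `"13"`, `"18"` or `"21"`.
#' @param fractions Strictly increasing trisomic fractions in \[0,1\];
#'   default the seven-point design 0, 5, 10, 30, 50, 70, 100%.
#' @param replicates_per_point Chips per fraction (default 2, technical
#'   duplicates).
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(trisomy_chrom = c("21", "18", "13"),
                         fractions = c(0, 0.05, 0.1, 0.3, 0.5, 0.7, 1),
                         replicates_per_point = 2) {
  trisomy_chrom <- match.arg(trisomy_chrom)
  stopifnot(all(fractions >= 0), all(fractions <= 1),
            all(diff(fractions) > 0), replicates_per_point >= 1)
  structure(list(trisomy_chrom = trisomy_chrom,
                 fractions = fractions,
                 replicates_per_point = as.integer(replicates_per_point)),
            class = "mixture_spec")
}

#' Simulate an aneuploid/euploid dilution series
#'
#' One duplex chip per replicate per mixture fraction. The target
#' chromosome's average copy number at fraction `f` is `2 + f`
#' ([effective_copy_number()]); the reference stays at 2, so the expected
#' ratio is `1 + f/2`. For trisomy 13 the target sits on the VIC channel
#' (chr13 is the VIC reference of the autosomal duplexes); for 18 and 21
#' on FAM.
#'
#' @param spec A [mixture_spec()].
#' @param config A [run_config()].
#' @param noise A [noise_params()].
#' @param genome_conc Genome equivalents per uL of the mixture.
#' @param seed Optional integer seed.
#' @return data.frame of chip readouts with extra columns `fraction`,
#'   `replicate` and `target_channel`; attribute `trisomy_chrom`.
#' @export
simulate_dilution_series <- function(spec, config = run_config(),
                                     noise = noise_params(),
                                     genome_conc = 500, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  panel_id <- if (spec$trisomy_chrom == "18") "13-18" else "13-21"
  target_channel <- if (spec$trisomy_chrom == "13") "VIC" else "FAM"
  sdlog <- sqrt(log1p(noise$chip_cv^2))
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(spec$fractions)) {
      f <- spec$fractions[i]
      for (r in seq_len(spec$replicates_per_point)) {
        fac <- if (sdlog > 0)
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
        target <- genome_conc * effective_copy_number(2, f) / 2 * fac
        ref <- genome_conc * 1 * fac
        conc <- if (target_channel == "FAM") c(FAM = target, VIC = ref)
                else c(FAM = ref, VIC = target)
        chip <- simulate_chip(
          conc, config, noise,
          sample_id = sprintf("mix_T%s_f%03.0f", spec$trisomy_chrom, 100 * f),
          chip_id = sprintf("mix_T%s_f%03.0f_r%d", spec$trisomy_chrom,
                            100 * f, r),
          panel = panel_id)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(fraction = f, replicate = r,
                           target_channel = target_channel,
                           stringsAsFactors = FALSE), chip)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "trisomy_chrom") <- spec$trisomy_chrom
    out
  })
}

#' Specification of a simulated screening cohort
#'
#' Defaults reproduce the validation cohort composition: 133 samples of
#' which 17 trisomy 21, 9 trisomy 18, 3 trisomy 13, one monosomy X and
#' one XXXY, the remaining 102 euploid (split evenly by sex), each run in
#' triplicate per panel.
#'
#' @param n_t21,n_t18,n_t13,n_monosomy_x,n_xxxy,n_euploid_male,n_euploid_female
#'   Class counts.
#' @param replicates_per_sample Chips per panel per sample.
#' @param genome_conc Genome equivalents per uL for every sample.
#' @param noise A [noise_params()].
#' @return Object of class `cohort_spec`; `n_total` is the sum of counts.
#' @export
cohort_spec <- function(n_t21 = 17, n_t18 = 9, n_t13 = 3,
                        n_monosomy_x = 1, n_xxxy = 1,
                        n_euploid_male = 51, n_euploid_female = 51,
                        replicates_per_sample = 3,
                        genome_conc = 500,
                        noise = noise_params()) {
  counts <- c(T21 = n_t21, T18 = n_t18, T13 = n_t13,
              monosomy_X = n_monosomy_x, XXXY = n_xxxy,
              euploid_male = n_euploid_male,
              euploid_female = n_euploid_female)
  stopifnot(all(counts >= 0), all(counts == floor(counts)),
            sum(counts) > 0, replicates_per_sample >= 1, genome_conc > 0)
  structure(list(counts = counts, n_total = sum(counts),
                 replicates_per_sample = as.integer(replicates_per_sample),
                 genome_conc = genome_conc, noise = noise),
            class = "cohort_spec")
}

#' Simulate a labeled screening cohort
#'
#' Emits one [sample_profile()] and triplicate chip sets per sample, with
#' ground-truth karyotype labels retained for downstream evaluation.
#' Trisomy samples alternate fetal sex deterministically.
#'
#' @param spec A [cohort_spec()].
#' @param config A [run_config()].
#' @param panels Panel list.
#' @param seed Optional integer seed; fixed seed gives a byte-identical
#'   dataset on rerun.
#' @return Object of class `dpcr_cohort`: list with `samples` (one row
#'   per sample: `sample_id`, `karyotype`, `sex`, `trisomy_chrom`,
#'   `trisomic_fraction`, `contamination_fraction`) and `chips` (all chip
#'   readouts).
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = run_config(),
                            panels = default_panels(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- rep(names(spec$counts), spec$counts)
  with_seed(seed, {
    samples <- list(); chips <- list()
    for (i in seq_along(classes)) {
      cls <- classes[i]
      sid <- sprintf("S%03d", i)
      sex <- switch(cls,
        euploid_male = "male", euploid_female = "female",
        monosomy_X = "female", XXXY = "male",
        if (i %% 2 == 0) "male" else "female")
      kary <- switch(cls,
        euploid_male = "euploid", euploid_female = "euploid", cls)
      prof <- karyotype_profile(kary, sex, sample_id = sid,
                                genome_conc = spec$genome_conc)
      chips[[i]] <- simulate_sample(prof, panels,
                                    spec$replicates_per_sample,
                                    config, spec$noise)
      samples[[i]] <- data.frame(
        sample_id = sid, karyotype = kary, sex = sex,
        trisomy_chrom = switch(cls, T13 = "13", T18 = "18", T21 = "21",
                               NA_character_),
        trisomic_fraction = if (kary %in% c("T13", "T18", "T21")) 1 else 0,
        contamination_fraction = 0,
        stringsAsFactors = FALSE)
    }
    structure(list(samples = do.call(rbind, samples),
                   chips = do.call(rbind, chips)),
              class = "dpcr_cohort")
  })
}

#' @export
print.dpcr_cohort <- function(x, ...) {
  cat(sprintf("simulated dPCR cohort: %d samples, %d chips\n",
              nrow(x$samples), nrow(x$chips)))
  print(table(x$samples$karyotype))
  invisible(x)
}
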