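#' Poisson occupancy from partition counts
#'
#' In digital PCR each well receives a Poisson-distributed number of target
#' molecules; a well is positive if it received at least one. With `P`
#' positive wells out of `N`, the mean occupancy (molecules per well) is
#' estimated as `lambda = -log(1 - P/N)`.
#'
#' @param P Number of positive partitions (0 <= P < N).
#' @param N Total number of partitions.
#' @return Estimated occupancy (dimensionless), strictly increasing in `P`.
#' @examples
#' occupancy_from_counts(10000, 20000)  # log(2)
#' @export
occupancy_from_counts <- function(P, N) {
  if (length(P) != 1 || length(N) != 1 || is.na(P) || is.na(N) ||
      P != floor(P) || N != floor(N) || N <= 0 || P < 0 || P > N)
    stop("invalid partition counts: need 0 <= P <= N, N > 0", call. = FALSE)
  if (P == N)
    stop("all partitions positive: occupancy undefined (chip saturated); ",
         "dilute the sample and rerun", call. = FALSE)
  -log1p(-P / N)
}

# Wilson score interval for a binomial proportion; exact at P = 0 lower end.
wilson_interval <- function(P, N, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- P / N
  denom <- 1 + z^2 / N
  centre <- (p + z^2 / (2 * N)) / denom
  half <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Confidence interval for a dPCR concentration
#'
#' Builds a Wilson score interval on the positive fraction `p = P/N` and
#' maps its endpoints through the strictly monotone transform
#' `p -> -(D/Vp) * log(1 - p)`. Monotonicity guarantees the transformed
#' endpoints bracket the point estimate.
#'
#' @param P,N Positive and total partition counts, `0 <= P < N`.
#' @param Vp Partition volume in microliters.
#' @param D Dilution factor (>= 1).
#' @param level Two-sided confidence level.
#' @return Numeric length-2 vector `c(low, high)` in copies/uL.
#' @export
concentration_ci <- function(P, N, Vp, D = 1, level = 0.95) {
  if (P == N) stop("saturated channel: interval undefined", call. = FALSE)
  occupancy_from_counts(P, N)  # validates counts
  stopifnot(Vp > 0, D >= 1, level > 0, level < 1)
  ends <- wilson_interval(P, N, level)
  (D / Vp) * (-log1p(-ends))
}

#' Absolute quantification of one dye channel
#'
#' Converts the called well counts of one channel of a duplex chip into an
#' absolute target concentration `T = -(D/Vp) * log(1 - P/N)` in copies/uL,
#' with a Wilson-based confidence interval.
#'
#' @param readout One-row data.frame chip readout (see [chip_readout()]).
#' @param channel `"FAM"` or `"VIC"`.
#' @param config A [run_config()].
#' @return Object of class `dpcr_quant` with fields `channel`, `p_hat`,
#'   `occupancy`, `concentration`, `ci_low`, `ci_high`, `n_wells`,
#'   `dilution_factor` and the chip identifiers.
#' @examples
#' chip <- chip_readout("s1", "c1", "13-21", 20000, 3000, 3000, 1000, 13000)
#' poisson_concentration(chip, "FAM", run_config())
#' @export
poisson_concentration <- function(readout, channel, config = run_config()) {
  validate_chips(readout)
  if (nrow(readout) != 1)
    stop("poisson_concentration expects a single chip", call. = FALSE)
  channel <- match.arg(channel, c("FAM", "VIC"))
  P <- channel_positives(readout, channel)
  N <- readout$n_wells
  D <- readout$dilution_factor
  Vp <- config$partition_volume_ul
  lambda <- occupancy_from_counts(P, N)
  ci <- concentration_ci(P, N, Vp, D, config$confidence_level)
  structure(list(sample_id = readout$sample_id,
                 chip_id = readout$chip_id,
                 panel = readout$panel,
                 channel = channel,
                 p_hat = P / N,
                 occupancy = lambda,
                 concentration = (D / Vp) * lambda,
                 ci_low = ci[1], ci_high = ci[2],
                 n_wells = N, dilution_factor = D),
            class = "dpcr_quant")
}

#' @export
print.dpcr_quant <- function(x, ...) {
  cat(sprintf(
    "dPCR quantification [%s / chip %s / %s]\n  p = %.4f, lambda = %.4f\n  %.1f copies/uL (CI %.1f - %.1f)\n",
    x$sample_id, x$chip_id, x$channel, x$p_hat, x$occupancy,
    x$concentration, x$ci_low, x$ci_high))
  invisible(x)
}

#' Quantify both channels of many chips
#'
#' Vectorised quantification over a chip table; the workhorse behind the
#' pipeline's quantification CSV.
#'
#' @param chips data.frame of chip readouts.
#' @param config A [run_config()].
#' @return data.frame with one row per chip and channel:
#'   `sample_id, chip_id, panel, channel, p_hat, lambda,
#'   conc_copies_per_ul, ci_low, ci_high`.
#' @export
quantify_chips <- function(chips, config = run_config()) {
  validate_chips(chips)
  Vp <- config$partition_volume_ul
  lvl <- config$confidence_level
  out <- lapply(c("FAM", "VIC"), function(ch) {
    P <- channel_positives(chips, ch)
    N <- chips$n_wells
    if (any(P == N))
      stop("saturated ", ch, " channel (all wells positive) on chip(s): ",
           paste(chips$chip_id[P == N], collapse = ", "),
           "; dilute the sample and rerun", call. = FALSE)
    p <- P / N
    lam <- -log1p(-p)
    ci <- t(mapply(function(pp, nn) wilson_interval(pp, nn, lvl), P, N))
    D <- chips$dilution_factor
    data.frame(sample_id = chips$sample_id, chip_id = chips$chip_id,
               panel = chips$panel, channel = ch, p_hat = p, lambda = lam,
               conc_copies_per_ul = (D / Vp) * lam,
               ci_low = (D / Vp) * (-log1p(-ci[, 1])),
               ci_high = (D / Vp) * (-log1p(-ci[, 2])),
               stringsAsFactors = FALSE)
  })
  res <- rbind(out[[1]], out[[2]])
  res[order(match(res$chip_id, chips$chip_id)), , drop = FALSE]
}

#' Chromosomal dosage ratio of two quantified channels
#'
#' The ratio of the analyzed chromosome's concentration to the reference
#' chromosome's, the screening statistic of the assay: ~1 for euploid
#' samples, ~1.5 for a full trisomy of the analyzed chromosome. The
#' confidence interval uses the delta method on the log ratio, treating
#' the two channel occupancies as independent (they are measured from the
#' same wells but different dyes; co-loading is independent under the
#' Poisson model).
#'
#' @param target `dpcr_quant` for the analyzed chromosome.
#' @param reference `dpcr_quant` for the reference chromosome.
#' @param level Confidence level.
#' @param numerator_chrom,denominator_chrom Optional chromosome labels.
#' @return Object of class `ratio_estimate` with `ratio`, `ci_low`,
#'   `ci_high`.
#' @export
chromosome_ratio <- function(target, reference, level = 0.95,
                             numerator_chrom = NA_character_,
                             denominator_chrom = NA_character_) {
  stopifnot(inherits(target, "dpcr_quant"), inherits(reference, "dpcr_quant"))
  if (reference$concentration <= 0)
    stop("reference concentration is zero: ratio undefined", call. = FALSE)
  ratio <- target$concentration / reference$concentration
  # relative variance of a Poisson dPCR estimate: Var(lambda-hat)/lambda^2
  relvar <- function(q) {
    if (q$occupancy == 0) return(Inf)
    q$p_hat / ((1 - q$p_hat) * q$n_wells * q$occupancy^2)
  }
  se_log <- sqrt(relvar(target) + relvar(reference))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(numerator_chrom = numerator_chrom,
                 denominator_chrom = denominator_chrom,
                 ratio = ratio,
                 ci_low = if (is.finite(se_log)) ratio * exp(-z * se_log) else 0,
                 ci_high = if (is.finite(se_log)) ratio * exp(z * se_log) else Inf,
                 se_log = se_log),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  lab <- if (!is.na(x$numerator_chrom))
    sprintf("chr%s:chr%s ", x$numerator_chrom, x$denominator_chrom) else ""
  cat(sprintf("chromosomal ratio %s= %.4f (CI %.4f - %.4f)\n",
              lab, x$ratio, x$ci_low, x$ci_high))
  invisible(x)
}

#' Per-chip chromosomal ratios for a chip table
#'
#' Quantifies both channels of every chip and returns the FAM:VIC and
#' VIC:FAM concentration ratios together with the channel concentrations.
#'
#' @param chips data.frame of chip readouts.
#' @param config A [run_config()].
#' @return data.frame with columns `sample_id, chip_id, panel, conc_fam,
#'   conc_vic, ratio_fam_vic, ratio_vic_fam`.
#' @export
chip_ratios <- function(chips, config = run_config()) {
  q <- quantify_chips(chips, config)
  fam <- q[q$channel == "FAM", ]
  vic <- q[q$channel == "VIC", ]
  m <- match(fam$chip_id, vic$chip_id)
  vic <- vic[m, ]
  # empty channels yield NA ratios (e.g. SRY in female samples)
  rf <- ifelse(vic$conc_copies_per_ul > 0,
               fam$conc_copies_per_ul / vic$conc_copies_per_ul, NA_real_)
  rv <- ifelse(fam$conc_copies_per_ul > 0,
               vic$conc_copies_per_ul / fam$conc_copies_per_ul, NA_real_)
  data.frame(sample_id = fam$sample_id, chip_id = fam$chip_id,
             panel = fam$panel,
             conc_fam = fam$conc_copies_per_ul,
             conc_vic = vic$conc_copies_per_ul,
             ratio_fam_vic = rf, ratio_vic_fam = rv,
             stringsAsFactors = FALSE)
}
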