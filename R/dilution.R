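#' Fit the dilution-series linearity model
#'
#' The mosaicism/contamination validation experiment: chips measured at a
#' grid of trisomic fractions are reduced to observed chromosomal ratios,
#' the per-fraction mean ratios are regressed on the theoretical ratios
#' `1 + f/2` by ordinary least squares, and the detection limit (smallest
#' fraction with a stable exceedance of the per-chromosome cutoff) is
#' located.
#'
#' @param series Output of [simulate_dilution_series()], or any
#'   data.frame with columns `fraction` and `ratio` holding precomputed
#'   observed ratios (plus optional `replicate`).
#' @param config A [run_config()] (used to quantify chips when `series`
#'   holds raw readouts).
#' @param bands A [classification_bands()]; supplies the per-chromosome
#'   cutoff when `cutoff` is missing.
#' @param cutoff Ratio cutoff for the detection limit; default the
#'   chromosome's entry in `bands$chrom_cutoffs`.
#' @param use_ci_lower Passed to [detection_limit()].
#' @param level Confidence level for per-fraction t-intervals.
#' @return Object of class `dilution_fit` with components `data`
#'   (per-chip fraction/ratio/theoretical), `table` (per-fraction mean,
#'   sd, CI), `slope`, `intercept`, `pearson_r`, `r_squared`,
#'   `detection_limit`, `cutoff`, `trisomy_chrom`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `residuals()`, `fitted()` and
#'   `plot()`.
#' @examples
#' series <- simulate_dilution_series(mixture_spec("21"), seed = 1)
#' fit <- dilution_fit(series)
#' coef(fit); fit$r_squared
#' @export
dilution_fit <- function(series, config = run_config(),
                         bands = classification_bands(), cutoff = NULL,
                         use_ci_lower = FALSE, level = 0.95) {
  chrom <- attr(series, "trisomy_chrom")
  if (!"ratio" %in% names(series)) {
    stopifnot(all(c("fraction", "target_channel") %in% names(series)))
    rt <- chip_ratios(series[, setdiff(names(series),
                                       c("fraction", "replicate",
                                         "target_channel"))], config)
    obs <- ifelse(series$target_channel == "FAM",
                  rt$ratio_fam_vic, rt$ratio_vic_fam)
    dat <- data.frame(fraction = series$fraction,
                      replicate = if ("replicate" %in% names(series))
                        series$replicate else seq_len(nrow(series)),
                      ratio = obs)
  } else {
    dat <- data.frame(fraction = series$fraction,
                      replicate = if ("replicate" %in% names(series))
                        series$replicate else seq_len(nrow(series)),
                      ratio = series$ratio)
  }
  dat$theoretical <- expected_ratio(dat$fraction)
  fr <- sort(unique(dat$fraction))
  tab <- do.call(rbind, lapply(fr, function(f) {
    r <- dat$ratio[dat$fraction == f]
    r <- r[!is.na(r)]
    n <- length(r); m <- mean(r); s <- if (n > 1) stats::sd(r) else NA_real_
    half <- if (n > 1 && is.finite(s))
      stats::qt(1 - (1 - level) / 2, n - 1) * s / sqrt(n) else NA_real_
    data.frame(fraction = f, n = n, mean_ratio = m, sd = s,
               ci_low = m - half, ci_high = m + half,
               theoretical = expected_ratio(f))
  }))
  if (nrow(tab) >= 3) {
    lf <- linear_fit(tab$theoretical, tab$mean_ratio)
    lm_fit <- stats::lm(mean_ratio ~ theoretical, data = tab)
  } else {
    lf <- list(slope = NA_real_, intercept = NA_real_,
               pearson_r = NA_real_, r_squared = NA_real_)
    lm_fit <- NULL
  }
  if (is.null(cutoff) && !is.null(chrom) &&
      chrom %in% names(bands$chrom_cutoffs))
    cutoff <- unname(bands$chrom_cutoffs[chrom])
  dl <- if (is.null(cutoff)) NA_real_ else
    detection_limit(tab$fraction,
                    lapply(tab$fraction, function(f)
                      dat$ratio[dat$fraction == f]),
                    cutoff, use_ci_lower = use_ci_lower, level = level)
  structure(list(trisomy_chrom = chrom, data = dat, table = tab,
                 slope = lf$slope, intercept = lf$intercept,
                 pearson_r = lf$pearson_r, r_squared = lf$r_squared,
                 detection_limit = dl, cutoff = cutoff,
                 lm = lm_fit, level = level),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  lab <- if (!is.null(x$trisomy_chrom)) paste0(" (trisomy ", x$trisomy_chrom, ")")
         else ""
  cat(sprintf("dilution-series linear fit%s\n", lab))
  cat(sprintf("  observed = %.4f + %.4f * theoretical;  r = %.4f, R2 = %.4f\n",
              x$intercept, x$slope, x$pearson_r, x$r_squared))
  if (!is.null(x$cutoff))
    cat(sprintf("  detection limit at cutoff %.3f: %s\n", x$cutoff,
                if (is.na(x$detection_limit)) "not reached"
                else sprintf("%.0f%% trisomic DNA", 100 * x$detection_limit)))
  invisible(x)
}

#' @export
summary.dilution_fit <- function(object, ...) {
  print(object)
  cat("\nper-fraction summary:\n")
  print(object$table, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.dilution_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
fitted.dilution_fit <- function(object, ...) {
  stats::fitted(object$lm)
}

#' @export
residuals.dilution_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' Predict mean observed ratios at new trisomic fractions
#'
#' @param object A `dilution_fit`.
#' @param newdata data.frame with a `fraction` column (or numeric
#'   fractions); missing `newdata` returns fitted values.
#' @param ... Unused.
#' @return Predicted mean observed ratios.
#' @export
predict.dilution_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  f <- if (is.data.frame(newdata)) newdata$fraction else newdata
  unname(object$intercept + object$slope * expected_ratio(f))
}

#' Plot a dilution-series fit
#'
#' Per-chip observed ratios against the percentage of trisomic DNA, the
#' per-fraction means, the fitted line and (when set) the detection
#' cutoff.
#'
#' @param x A `dilution_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dilution_fit <- function(x, ...) {
  pct <- 100 * x$data$fraction
  graphics::plot(pct, x$data$ratio,
                 xlab = "% trisomic DNA", ylab = "chromosomal ratio",
                 main = if (!is.null(x$trisomy_chrom))
                   paste0("Dilution series, trisomy ", x$trisomy_chrom)
                 else "Dilution series", ...)
  graphics::points(100 * x$table$fraction, x$table$mean_ratio, pch = 19)
  fgrid <- seq(0, 1, length.out = 101)
  graphics::lines(100 * fgrid, predict(x, fgrid), col = "red")
  if (!is.null(x$cutoff))
    graphics::abline(h = x$cutoff, col = "blue", lty = 2)
  invisible(x)
}

#' Export a dilution series as TSV
#'
#' Columns: `fraction`, `replicate`, `ratio`, `theoretical_ratio`.
#'
#' @param fit A `dilution_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dilution_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "dilution_fit"))
  out <- fit$data
  names(out)[names(out) == "theoretical"] <- "theoretical_ratio"
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
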