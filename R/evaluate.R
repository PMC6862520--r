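#' Mann-Whitney U test between two ratio groups
#'
#' Rank-sum comparison with midrank tie handling. The p-value is exact
#' (full enumeration) when the smaller group has at most 8 observations
#' and there are no ties, and uses the normal approximation with tie
#' correction otherwise. Backed by [stats::wilcox.test()].
#'
#' @param a,b Numeric vectors (e.g. chromosomal ratios of the aneuploid
#'   and euploid groups).
#' @return List with `U` (the statistic of group `a`) and `p_two_sided`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact))
  list(U = unname(wt$statistic), p_two_sided = wt$p.value)
}

#' Area under the ROC curve with bootstrap confidence interval
#'
#' The pair-ordering (concordance) estimator: the fraction of
#' positive-negative pairs in which the positive sample scores higher,
#' ties counting one half. Equals the Mann-Whitney U of the positive
#' group divided by `n_pos * n_neg`. The confidence interval is a
#' percentile bootstrap over samples; degenerate single-class resamples
#' are redrawn.
#'
#' @param scores Numeric scores (higher = more aneuploid-like).
#' @param labels Binary labels (1/TRUE = positive class).
#' @param n_boot Bootstrap resamples (0 skips the CI).
#' @param seed Optional seed for the bootstrap.
#' @param level Confidence level.
#' @return List with `auc`, `ci_low`, `ci_high`.
#' @export
auroc <- function(scores, labels, n_boot = 2000, seed = NULL, level = 0.95) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both label classes must be present", call. = FALSE)
  point <- auc_estimate(scores, labels)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- with_seed(seed, {
      n <- length(scores)
      stat <- numeric(n_boot)
      for (i in seq_len(n_boot)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(labels[idx])) == 2) break
        }
        stat[i] <- auc_estimate(scores[idx], labels[idx])
      }
      alpha <- (1 - level) / 2
      unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
    })
  }
  list(auc = point, ci_low = ci[1], ci_high = ci[2])
}

# rank-based concordance estimator (midranks handle ties as 1/2)
auc_estimate <- function(scores, labels) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Points of the empirical ROC curve
#'
#' One point per distinct threshold (plus the two trivial endpoints),
#' monotone non-decreasing from (0,0) to (1,1). The trapezoid integral of
#' these points equals the [auroc()] point estimate.
#'
#' @param scores,labels As in [auroc()].
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("both label classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  pts <- t(vapply(thr, function(t) {
    pos_call <- scores >= t
    c(fpr = sum(pos_call & labels == 0) / n_neg,
      tpr = sum(pos_call & labels == 1) / n_pos)
  }, numeric(2)))
  out <- rbind(c(0, 0), pts, c(1, 1))
  out <- as.data.frame(unique(out))
  names(out) <- c("fpr", "tpr")
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Ordinary least-squares line with correlation summaries
#'
#' Fits `y ~ x` by OLS ([stats::lm()]) and reports slope, intercept,
#' Pearson correlation and its square (for a simple linear fit,
#' `r_squared == pearson_r^2`).
#'
#' @param x,y Numeric vectors, at least 3 points, `x` not constant.
#' @return List with `slope`, `intercept`, `pearson_r`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant: fit degenerate", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = r, r_squared = r^2)
}

#' Detection limit of a dilution series
#'
#' The smallest grid fraction whose mean ratio (and, optionally, the
#' lower bound of its 95% t-interval) exceeds the cutoff, with every
#' larger fraction also exceeding it — i.e. the onset of a stable
#' exceedance.
#'
#' @param fractions Strictly increasing trisomic fractions.
#' @param ratios List (parallel to `fractions`) of replicate ratio
#'   vectors, or a numeric vector of per-fraction means.
#' @param cutoff Ratio cutoff (per-chromosome, see
#'   [classification_bands()]).
#' @param use_ci_lower Require the CI lower bound, not just the mean, to
#'   clear the cutoff. With technical duplicates the t-interval is very
#'   wide, so the default uses the mean only.
#' @param level Confidence level of the t-interval.
#' @return The detection-limit fraction, or `NA` if no stable exceedance
#'   exists.
#' @export
detection_limit <- function(fractions, ratios, cutoff,
                            use_ci_lower = FALSE, level = 0.95) {
  stopifnot(all(diff(fractions) > 0))
  if (!is.list(ratios)) ratios <- as.list(ratios)
  stopifnot(length(ratios) == length(fractions))
  exceeds <- vapply(ratios, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) return(FALSE)
    m <- mean(r)
    ok <- m > cutoff
    if (use_ci_lower && length(r) >= 2 && stats::sd(r) > 0) {
      half <- stats::qt(1 - (1 - level) / 2, df = length(r) - 1) *
        stats::sd(r) / sqrt(length(r))
      ok <- ok && (m - half) > cutoff
    }
    ok
  }, logical(1))
  # onset of stable exceedance: all larger fractions must exceed too
  stable <- rev(cumprod(rev(exceeds))) > 0
  if (!any(stable)) return(NA_real_)
  fractions[which(stable)[1]]
}

#' Evaluate sample calls against ground truth
#'
#' The statistical validation layer applied to a (simulated) cohort: for
#' each trisomy, a Mann-Whitney comparison of the chromosomal ratio
#' between that trisomy's samples and euploid samples, the AUROC with
#' bootstrap confidence interval, and sensitivity/specificity with
#' confusion counts at the calling threshold.
#'
#' @param reports `sample_report` data.frame from [call_samples()].
#' @param truth data.frame with `sample_id` and `trisomy_chrom` (`"13"`,
#'   `"18"`, `"21"` or `NA`), e.g. the `samples` table of
#'   [simulate_cohort()]; samples with non-trisomy aberrations are
#'   excluded from each trisomy's comparison.
#' @param threshold Calling threshold (default the global 1.15).
#' @param n_boot,seed Bootstrap settings for the AUROC CI.
#' @return Object of class `cohort_eval`: per-trisomy list with `U`, `p`,
#'   `auroc`, `auroc_ci`, `sensitivity`, `specificity`, `tp/fp/tn/fn`.
#' @export
cohort_summary <- function(reports, truth, threshold = 1.15,
                           n_boot = 2000, seed = NULL) {
  m <- match(reports$sample_id, truth$sample_id)
  if (any(is.na(m)))
    stop("every report needs a truth label", call. = FALSE)
  truth <- truth[m, ]
  euploid <- if ("karyotype" %in% names(truth)) truth$karyotype == "euploid"
             else is.na(truth$trisomy_chrom)
  res <- list()
  for (chrom in c("13", "18", "21")) {
    col <- paste0("chr", chrom, "_ratio")
    is_tri <- !is.na(truth$trisomy_chrom) & truth$trisomy_chrom == chrom
    keep <- (is_tri | euploid) & !is.na(reports[[col]])
    scores <- reports[[col]][keep]
    labels <- as.integer(is_tri[keep])
    if (sum(labels) == 0 || sum(labels == 0) == 0) {
      res[[paste0("T", chrom)]] <- list(U = NA, p = NA, auroc = NA,
                                        auroc_ci = c(NA, NA),
                                        sensitivity = NA, specificity = NA,
                                        tp = 0, fp = 0, tn = 0, fn = 0,
                                        note = "not-applicable: a class is empty")
      next
    }
    mw <- mann_whitney_u(scores[labels == 1], scores[labels == 0])
    au <- auroc(scores, labels, n_boot = n_boot, seed = seed)
    pos_call <- scores >= threshold
    tp <- sum(pos_call & labels == 1); fn <- sum(!pos_call & labels == 1)
    fp <- sum(pos_call & labels == 0); tn <- sum(!pos_call & labels == 0)
    res[[paste0("T", chrom)]] <- list(
      U = mw$U, p = mw$p_two_sided,
      auroc = au$auc, auroc_ci = c(au$ci_low, au$ci_high),
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      tp = tp, fp = fp, tn = tn, fn = fn)
  }
  structure(res, class = "cohort_eval", threshold = threshold)
}

#' @export
print.cohort_eval <- function(x, ...) {
  cat(sprintf("cohort evaluation at ratio threshold %.3g\n",
              attr(x, "threshold")))
  for (nm in names(x)) {
    e <- x[[nm]]
    if (!is.null(e$note)) { cat(sprintf("  %s: %s\n", nm, e$note)); next }
    cat(sprintf(
      "  %s: U=%.1f p=%.3g AUROC=%.3f [%.3f, %.3f] sens=%.0f%% spec=%.0f%% (tp %d fp %d tn %d fn %d)\n",
      nm, e$U, e$p, e$auroc, e$auroc_ci[1], e$auroc_ci[2],
      100 * e$sensitivity, 100 * e$specificity, e$tp, e$fp, e$tn, e$fn))
  }
  invisible(x)
}

#' Write a cohort evaluation as JSON
#'
#' @param eval_result A `cohort_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(eval_result, path) {
  out <- lapply(eval_result, function(e) e[!vapply(e, is.null, logical(1))])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
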