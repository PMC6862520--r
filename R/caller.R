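#' Classify a chromosomal ratio as euploid, trisomy or inconclusive
#'
#' Band logic of the screening test: ratios inside the euploid band are
#' euploid; ratios at or above the aneuploid threshold are trisomic, with
#' an `intermediate_possible_mosaic_or_contamination` flag when the ratio
#' falls short of a typical full trisomy (mosaicism or maternal-cell
#' contamination pulls the ratio toward 1). Everything else is
#' inconclusive; ratios below the euploid band additionally carry a
#' `below_euploid_range` flag (autosomal monosomy is not called).
#'
#' @param ratio Positive numeric ratio or a `ratio_estimate`.
#' @param bands A [classification_bands()].
#' @param chromosome Optional chromosome label carried into the call.
#' @return Object of class `autosome_call`: `chromosome`, `ratio`,
#'   `class` (`"euploid"`, `"trisomy"`, `"inconclusive"`) and `flags`.
#' @examples
#' classify_autosome(1.505)$class   # trisomy
#' classify_autosome(0.981)$class   # euploid
#' @export
classify_autosome <- function(ratio, bands = classification_bands(),
                              chromosome = NA_character_) {
  if (inherits(ratio, "ratio_estimate")) {
    if (is.na(chromosome)) chromosome <- ratio$numerator_chrom
    ratio <- ratio$ratio
  }
  stopifnot(is.numeric(ratio), length(ratio) == 1, ratio > 0)
  flags <- character()
  if (ratio >= bands$euploid_low && ratio <= bands$euploid_high) {
    cls <- "euploid"
  } else if (ratio >= bands$aneuploid_threshold) {
    cls <- "trisomy"
    if (ratio < bands$typical_trisomy_low)
      flags <- "intermediate_possible_mosaic_or_contamination"
  } else {
    cls <- "inconclusive"
    if (ratio < bands$euploid_low) flags <- "below_euploid_range"
  }
  structure(list(chromosome = chromosome, ratio = ratio,
                 class = cls, flags = flags),
            class = "autosome_call")
}

#' @export
print.autosome_call <- function(x, ...) {
  cat(sprintf("chr%s ratio %.3f -> %s%s\n",
              x$chromosome, x$ratio, x$class,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Aneuploid (trisomic) fraction implied by a chromosomal ratio
#'
#' Inverts the mixture relation `ratio = 1 + f/2`: `f = 2 * (ratio - 1)`,
#' clamped to \[0, 1\]. Used to annotate intermediate trisomy calls with
#' the mosaic/fetal fraction they would correspond to.
#'
#' @param ratio Chromosomal ratio (vectorised).
#' @return Implied trisomic fraction(s) in \[0, 1\]; ratios below 1 return
#'   0 with a warning.
#' @examples
#' estimate_aneuploid_fraction(1.193)  # 0.386
#' @export
estimate_aneuploid_fraction <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(ratio < 1))
    warning("ratio(s) below the disomic baseline; fraction clamped to 0")
  pmin(1, pmax(0, 2 * (ratio - 1)))
}

#' Call sex-chromosome constitution from X and SRY quantifications
#'
#' X dosage is read as the X:autosome concentration ratio (the autosome
#' reference is the chr13 channel of the same sample's autosomal chips,
#' assuming equal DNA input per chip); Y presence as SRY signal above a
#' limit-of-blank (minimum concentration and minimum positive wells).
#' Bands: one X in `[0.4, 0.6]`, two X in `[0.9, 1.1]`, three or more X
#' at or above 1.4.
#'
#' @param x_quant `dpcr_quant` (or copies/uL) of the X channel.
#' @param sry_quant `dpcr_quant` of the SRY channel; if numeric, supply
#'   `sry_positive_wells` too.
#' @param autosome_ref `dpcr_quant` (or copies/uL) of the autosome
#'   reference.
#' @param bands A [classification_bands()].
#' @param sry_positive_wells Positive-well count behind `sry_quant` when
#'   given numerically.
#' @return Object of class `sex_call`: `x_autosome_ratio`,
#'   `sry_detected`, `class` in `XX`, `XY`, `monosomy_X`,
#'   `multiple_X_with_Y`, `inconclusive`.
#' @export
call_sex_chromosomes <- function(x_quant, sry_quant, autosome_ref,
                                 bands = classification_bands(),
                                 sry_positive_wells = NULL) {
  conc_of <- function(q) if (inherits(q, "dpcr_quant")) q$concentration else q
  auto <- conc_of(autosome_ref)
  if (is.null(auto) || is.na(auto) || auto <= 0)
    stop("missing or empty autosome reference channel ",
         "(cross-chip reference required)", call. = FALSE)
  x_conc <- conc_of(x_quant)
  sry_conc <- conc_of(sry_quant)
  if (inherits(sry_quant, "dpcr_quant"))
    sry_positive_wells <- round(sry_quant$p_hat * sry_quant$n_wells)
  if (is.null(sry_positive_wells))
    stop("sry_positive_wells required when sry_quant is numeric",
         call. = FALSE)
  sry_detected <- sry_conc >= bands$sry_min_conc &&
    sry_positive_wells >= bands$sry_min_wells
  r <- x_conc / auto
  n_x <- if (r >= bands$x_one[1] && r <= bands$x_one[2]) 1L
         else if (r >= bands$x_two[1] && r <= bands$x_two[2]) 2L
         else if (r >= bands$x_multi_min) 3L
         else NA_integer_
  cls <- if (is.na(n_x)) "inconclusive"
         else if (n_x == 1L && sry_detected) "XY"
         else if (n_x == 1L) "monosomy_X"
         else if (n_x == 2L && !sry_detected) "XX"
         else if (n_x >= 3L && sry_detected) "multiple_X_with_Y"
         else "inconclusive"
  structure(list(x_autosome_ratio = r, sry_detected = sry_detected,
                 class = cls),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("X:autosome %.3f, SRY %s -> %s\n", x$x_autosome_ratio,
              if (x$sry_detected) "detected" else "absent", x$class))
  invisible(x)
}

#' Chip-level quality control
#'
#' Fails a chip whose counts are inconsistent or whose channels are
#' saturated; the reference (VIC) concentration outside the validated
#' window is a warning by default (`strict_range = TRUE` turns it into a
#' failure). Failures are returned, not raised.
#'
#' @param readout One-row chip readout.
#' @param config A [run_config()].
#' @param strict_range Treat an out-of-range reference concentration as a
#'   failure.
#' @return List with `pass` (logical), `reasons` (failure codes) and
#'   `warnings`.
#' @export
qc_chip <- function(readout, config = run_config(), strict_range = FALSE) {
  reasons <- character(); warns <- character()
  ok <- tryCatch({validate_chips(readout); TRUE}, error = function(e) FALSE)
  if (!ok || nrow(readout) != 1) {
    return(list(pass = FALSE, reasons = "count_mismatch",
                warnings = character()))
  }
  for (ch in c("FAM", "VIC")) {
    if (channel_positives(readout, ch) == readout$n_wells)
      reasons <- c(reasons, "saturation")
  }
  if (!("saturation" %in% reasons)) {
    ref <- poisson_concentration(readout, "VIC", config)$concentration
    if (ref < config$valid_conc_range[1] || ref > config$valid_conc_range[2]) {
      msg <- sprintf("reference_conc_out_of_range (%.0f copies/uL)", ref)
      if (strict_range) reasons <- c(reasons, msg) else warns <- c(warns, msg)
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons, warnings = warns)
}

#' Aggregate replicate chip ratios into one sample-level call
#'
#' The sample-level ratio is the mean of the QC-passing replicate ratios
#' and the classification is applied to that mean. If any two replicates
#' disagree at the euploid-versus-trisomy level the sample is returned as
#' inconclusive with a `repeat_test` flag.
#'
#' @param ratios Numeric vector of QC-passing replicate ratios.
#' @param bands A [classification_bands()].
#' @param chromosome Chromosome label.
#' @return An `autosome_call` with extra fields `replicate_ratios` and
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(ratios, bands = classification_bands(),
                                 chromosome = NA_character_) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0)
    stop("no QC-passing replicate ratios: sample cannot be called",
         call. = FALSE)
  per_rep <- vapply(ratios, function(r)
    classify_autosome(r, bands, chromosome)$class, character(1))
  call <- classify_autosome(mean(ratios), bands, chromosome)
  if ("euploid" %in% per_rep && "trisomy" %in% per_rep) {
    call$class <- "inconclusive"
    call$flags <- unique(c(call$flags, "repeat_test"))
  }
  call$replicate_ratios <- ratios
  call$n_replicates <- length(ratios)
  call
}

#' Call every sample of a chip table
#'
#' The full calling layer: quantifies all chips, applies chip QC, forms
#' per-sample chromosomal ratios (chr21 from the 13-21 duplex, chr18 from
#' the 13-18 duplex, chr13 as the mean of the inverse ratios chr13:chr21
#' and chr13:chr18 across both autosomal duplexes), aggregates
#' replicates, classifies against the global threshold and calls the sex
#' chromosomes from the X-SRY duplex with the chr13 channel as autosome
#' reference.
#'
#' @param chips Chip readout data.frame (all panels of all samples) or a
#'   `dpcr_cohort`.
#' @param config A [run_config()].
#' @param bands A [classification_bands()].
#' @return data.frame of class `sample_report`, one row per sample:
#'   `sample_id, chr13_ratio, chr18_ratio, chr21_ratio, sex_ratio,
#'   sry_detected, call_13, call_18, call_21, call_sex, flags, qc,
#'   est_aneuploid_fraction`.
#' @export
call_samples <- function(chips, config = run_config(),
                         bands = classification_bands()) {
  if (inherits(chips, "dpcr_cohort")) chips <- chips$chips
  validate_chips(chips)
  qc <- lapply(seq_len(nrow(chips)), function(i)
    qc_chip(chips[i, , drop = FALSE], config))
  qc_pass <- vapply(qc, `[[`, logical(1), "pass")
  rt <- chip_ratios(chips[qc_pass, , drop = FALSE], config)
  sry_pos <- channel_positives(chips, "FAM")
  rows <- lapply(unique(chips$sample_id), function(sid) {
    p1 <- rt[rt$sample_id == sid & rt$panel == "13-21", ]
    p2 <- rt[rt$sample_id == sid & rt$panel == "13-18", ]
    p3 <- rt[rt$sample_id == sid & rt$panel == "X-SRY", ]
    n_chips <- sum(chips$sample_id == sid)
    n_pass <- sum(qc_pass[chips$sample_id == sid])
    qc_str <- sprintf("%d/%d", n_pass, n_chips)
    flags <- character()
    one_call <- function(ratios, chrom) {
      if (length(ratios) == 0 || all(is.na(ratios)))
        return(list(ratio = NA_real_, class = "no_call", flags = "qc_fail"))
      aggregate_replicates(ratios, bands, chrom)
    }
    c21 <- one_call(p1$ratio_fam_vic, "21")
    c18 <- one_call(p2$ratio_fam_vic, "18")
    c13 <- one_call(c(p1$ratio_vic_fam, p2$ratio_vic_fam), "13")
    flags <- unique(c(flags, c13$flags, c18$flags, c21$flags))
    # sex call from mean X / mean chr13 concentration across chips
    sex_ratio <- NA_real_; sry <- NA; sex_class <- "no_call"
    auto_conc <- mean(c(p1$conc_vic, p2$conc_vic))
    if (nrow(p3) > 0 && is.finite(auto_conc) && auto_conc > 0) {
      x_conc <- mean(p3$conc_vic)
      sry_conc <- mean(p3$conc_fam)
      wells <- mean(sry_pos[chips$sample_id == sid & chips$panel == "X-SRY"])
      sc <- call_sex_chromosomes(x_conc, sry_conc, auto_conc, bands,
                                 sry_positive_wells = wells)
      sex_ratio <- sc$x_autosome_ratio; sry <- sc$sry_detected
      sex_class <- sc$class
    }
    est_f <- NA_real_
    if ("intermediate_possible_mosaic_or_contamination" %in% flags) {
      r_max <- max(c(c13$ratio, c18$ratio, c21$ratio), na.rm = TRUE)
      est_f <- estimate_aneuploid_fraction(r_max)
    }
    data.frame(sample_id = sid,
               chr13_ratio = c13$ratio, chr18_ratio = c18$ratio,
               chr21_ratio = c21$ratio, sex_ratio = sex_ratio,
               sry_detected = sry,
               call_13 = c13$class, call_18 = c18$class,
               call_21 = c21$class, call_sex = sex_class,
               flags = paste(flags, collapse = ";"),
               qc = qc_str,
               est_aneuploid_fraction = est_f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sample_report", class(out))
  out
}

#' Write sample reports as TSV
#'
#' @param reports A `sample_report` data.frame from [call_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_reports <- function(reports, path) {
  utils::write.table(reports, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
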