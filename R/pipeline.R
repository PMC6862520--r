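#' Assemble a full pipeline configuration
#'
#' Bundles the run constants, classification bands, panel set, simulated
#' cohort specification and seed into one validated object. Seeds are
#' explicit — the pipeline never seeds from the wall clock.
#'
#' @param run A [run_config()].
#' @param bands A [classification_bands()].
#' @param cohort A [cohort_spec()] used when the pipeline simulates its
#'   input.
#' @param panels Panel list.
#' @param seed Integer seed for all simulation and bootstrap randomness.
#' @param n_boot Bootstrap resamples for AUROC intervals.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(run = run_config(),
                            bands = classification_bands(),
                            cohort = cohort_spec(),
                            panels = default_panels(),
                            seed = 1L, n_boot = 2000L) {
  stopifnot(inherits(run, "dpcr_run_config"),
            inherits(bands, "classification_bands"),
            inherits(cohort, "cohort_spec"),
            is.numeric(seed), length(seed) == 1, is.finite(seed))
  structure(list(run = run, bands = bands, cohort = cohort,
                 panels = panels, seed = as.integer(seed),
                 n_boot = as.integer(n_boot)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the constructor arguments:
#' `run_config` (partition_volume_ul, n_wells_default, confidence_level,
#' valid_conc_range), `bands` (euploid_low, euploid_high,
#' aneuploid_threshold, chrom_cutoffs, typical_trisomy_low, ...),
#' `cohort` (class counts, replicates_per_sample, genome_conc, noise:
#' chip_cv/fp_rate/fn_rate), `seed`, `n_boot`. Omitted keys keep their
#' defaults; malformed values fail validation with the constructor's
#' error.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, fn) {
    if (is.null(block)) return(fn())
    do.call(fn, block)
  }
  co <- y$cohort
  if (!is.null(co$noise)) co$noise <- do.call(noise_params, co$noise)
  if (!is.null(y$bands$chrom_cutoffs))
    y$bands$chrom_cutoffs <- unlist(y$bands$chrom_cutoffs)
  pipeline_config(run = take(y$run_config, run_config),
                  bands = take(y$bands, classification_bands),
                  cohort = take(co, cohort_spec),
                  seed = if (is.null(y$seed)) 1L else y$seed,
                  n_boot = if (is.null(y$n_boot)) 2000L else y$n_boot)
}

#' Print a pipeline configuration as YAML
#'
#' Emits every effective setting in the YAML layout accepted by
#' [read_pipeline_config()] — a provenance record of the run.
#'
#' @param config A [pipeline_config()].
#' @param file Connection or "" for stdout; `NULL` suppresses printing.
#' @return The YAML string, invisibly.
#' @export
show_config <- function(config = pipeline_config(), file = "") {
  y <- list(
    run_config = unclass(config$run),
    bands = unclass(config$bands)[c("euploid_low", "euploid_high",
                                    "aneuploid_threshold", "chrom_cutoffs",
                                    "typical_trisomy_low", "sry_min_conc",
                                    "sry_min_wells")],
    cohort = c(stats::setNames(as.list(config$cohort$counts),
                               c("n_t21", "n_t18", "n_t13", "n_monosomy_x",
                                 "n_xxxy", "n_euploid_male",
                                 "n_euploid_female")),
               list(replicates_per_sample = config$cohort$replicates_per_sample,
                    genome_conc = config$cohort$genome_conc,
                    noise = unclass(config$cohort$noise))),
    seed = config$seed, n_boot = config$n_boot)
  txt <- yaml::as.yaml(y)
  if (!is.null(file)) cat(txt, file = file)
  invisible(txt)
}

#' Run the full screening pipeline
#'
#' Chains simulate (unless chips are supplied), quantify, call and — when
#' ground truth is available — evaluate. Writes the quantification CSV,
#' the sample-report TSV, the per-chip QC log and, for simulated cohorts,
#' the evaluation JSON into `out_dir`. Deterministic for a fixed seed:
#' the same configuration produces identical output files.
#'
#' @param config A [pipeline_config()].
#' @param chips Optional chip readout data.frame (e.g. from
#'   [read_chip_csv()]); when `NULL` a cohort is simulated from
#'   `config$cohort`.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   file output.
#' @return List with `chips`, `quantification`, `reports`, `evaluation`
#'   (NULL without truth) and `truth`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), chips = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(chips)) {
    cohort <- simulate_cohort(config$cohort, config$run, config$panels,
                              seed = config$seed)
    chips <- cohort$chips
    truth <- cohort$samples
  } else {
    validate_chips(chips)
  }
  quant <- tryCatch(quantify_chips(chips, config$run),
                    error = function(e)
                      stop("quantification stage: ", conditionMessage(e),
                           call. = FALSE))
  reports <- tryCatch(call_samples(chips, config$run, config$bands),
                      error = function(e)
                        stop("calling stage: ", conditionMessage(e),
                             call. = FALSE))
  evaluation <- NULL
  if (!is.null(truth))
    evaluation <- tryCatch(
      cohort_summary(reports, truth,
                     threshold = config$bands$aneuploid_threshold,
                     n_boot = config$n_boot, seed = config$seed),
      error = function(e)
        stop("evaluation stage: ", conditionMessage(e), call. = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_chip_csv(chips, file.path(out_dir, "chips.csv"))
    utils::write.csv(quant, file.path(out_dir, "quantification.csv"),
                     row.names = FALSE, quote = FALSE)
    write_sample_reports(reports, file.path(out_dir, "sample_reports.tsv"))
    qc_log <- do.call(rbind, lapply(seq_len(nrow(chips)), function(i) {
      q <- qc_chip(chips[i, , drop = FALSE], config$run)
      data.frame(chip_id = chips$chip_id[i],
                 qc = if (q$pass) "pass" else "fail",
                 detail = paste(c(q$reasons, q$warnings), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(qc_log, file.path(out_dir, "chip_qc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(evaluation))
      write_evaluation_json(evaluation, file.path(out_dir, "evaluation.json"))
  }
  invisible(list(chips = chips, quantification = quant, reports = reports,
                 evaluation = evaluation, truth = truth))
}
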