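#' Run configuration for a chip-based dPCR experiment
#'
#' Physical and statistical constants of a run: the per-well partition
#' volume, the nominal chip size, the confidence level used for all
#' intervals and the validated concentration window used by chip QC.
#'
#' @param partition_volume_ul Volume of one well in microliters (Vp).
#'   Default 0.000809 (809 pL, the nominal well volume of the 20,000-well
#'   chip platform). All absolute concentrations scale with 1/Vp;
#'   chromosomal ratios are Vp-invariant.
#' @param n_wells_default Nominal number of wells per chip.
#' @param confidence_level Two-sided confidence level for concentration and
#'   ratio intervals.
#' @param valid_conc_range Length-2 numeric, the validated copies/uL window
#'   for the reference channel; chips outside it are flagged by [qc_chip()].
#' @return An object of class `dpcr_run_config`.
#' @examples
#' run_config()
#' @export
run_config <- function(partition_volume_ul = 0.000809,
                       n_wells_default = 20000L,
                       confidence_level = 0.95,
                       valid_conc_range = c(200, 2000)) {
  stopifnot(partition_volume_ul > 0,
            n_wells_default > 0,
            confidence_level > 0, confidence_level < 1,
            length(valid_conc_range) == 2,
            valid_conc_range[1] > 0,
            valid_conc_range[1] < valid_conc_range[2])
  structure(list(partition_volume_ul = partition_volume_ul,
                 n_wells_default = as.integer(n_wells_default),
                 confidence_level = confidence_level,
                 valid_conc_range = valid_conc_range),
            class = "dpcr_run_config")
}

#' @export
print.dpcr_run_config <- function(x, ...) {
  cat("dPCR run configuration\n")
  cat(sprintf("  partition volume : %.6f uL (%.0f pL)\n",
              x$partition_volume_ul, x$partition_volume_ul * 1e6))
  cat(sprintf("  wells per chip   : %d\n", x$n_wells_default))
  cat(sprintf("  confidence level : %.2f\n", x$confidence_level))
  cat(sprintf("  valid range      : %g-%g copies/uL\n",
              x$valid_conc_range[1], x$valid_conc_range[2]))
  invisible(x)
}

#' Define a duplex assay panel
#'
#' A duplex chip interrogates two targets, one per reporter dye (VIC and
#' FAM). The two targets must sit on different chromosomes so that their
#' concentration ratio carries dosage information.
#'
#' @param panel_id Short label, e.g. `"13-21"`.
#' @param vic_chrom,vic_locus Chromosome and locus name of the VIC target.
#' @param fam_chrom,fam_locus Chromosome and locus name of the FAM target.
#' @return An object of class `duplex_assay`.
#' @seealso [default_panels()]
#' @export
duplex_assay <- function(panel_id, vic_chrom, vic_locus, fam_chrom, fam_locus) {
  if (identical(as.character(vic_chrom), as.character(fam_chrom)))
    stop("duplex targets must sit on different chromosomes", call. = FALSE)
  structure(list(panel_id = as.character(panel_id),
                 vic_chrom = as.character(vic_chrom),
                 vic_locus = as.character(vic_locus),
                 fam_chrom = as.character(fam_chrom),
                 fam_locus = as.character(fam_locus)),
            class = "duplex_assay")
}

#' @export
print.duplex_assay <- function(x, ...) {
  cat(sprintf("duplex panel '%s': VIC chr%s (%s) + FAM chr%s (%s)\n",
              x$panel_id, x$vic_chrom, x$vic_locus, x$fam_chrom, x$fam_locus))
  invisible(x)
}

#' Default duplex panel set
#'
#' The three duplexes of the screening assay: chr13 (VIC, MBNL2) paired
#' with chr21 (FAM, PRDM15); chr13 (VIC, MBNL2) paired with chr18 (FAM,
#' EHZF); and a noncoding chrX sequence (VIC) paired with the Y-linked SRY
#' gene (FAM) for sex-chromosome assessment. chr13 serves as the reference
#' chromosome of both autosomal duplexes.
#'
#' @return Named list of [duplex_assay()] objects.
#' @export
default_panels <- function() {
  list(
    "13-21" = duplex_assay("13-21", "13", "MBNL2", "21", "PRDM15"),
    "13-18" = duplex_assay("13-18", "13", "MBNL2", "18", "EHZF"),
    "X-SRY" = duplex_assay("X-SRY", "X", "Xnc",   "Y",  "SRY")
  )
}

#' Classification bands for chromosomal-ratio calling
#'
#' Encodes the decision bands of the screening test: ratios in
#' `[euploid_low, euploid_high]` are euploid, ratios at or above
#' `aneuploid_threshold` are trisomic, the gap between the bands is
#' inconclusive. Trisomy calls below `typical_trisomy_low` are flagged as
#' possibly mosaic or maternally contaminated. `chrom_cutoffs` holds the
#' per-chromosome cutoffs used for dilution-series detection-limit
#' analysis (not for clinical calling, which uses the global threshold).
#' X-dosage bands and the SRY limit-of-blank govern sex-chromosome calls.
#'
#' @param euploid_low,euploid_high Euploid band (default 0.9-1.1).
#' @param aneuploid_threshold Global trisomy threshold (default 1.15).
#' @param chrom_cutoffs Named numeric, per-chromosome dilution cutoffs.
#' @param typical_trisomy_low Smallest ratio regarded as a typical full
#'   trisomy; lower trisomy calls carry a mosaicism/contamination flag.
#' @param x_one,x_two X:autosome bands for one and two X copies;
#'   `x_multi_min` is the lower bound for three or more X copies.
#' @param sry_min_conc,sry_min_wells SRY detection floor: minimum estimated
#'   copies/uL and minimum positive FAM wells.
#' @return Object of class `classification_bands`.
#' @export
classification_bands <- function(euploid_low = 0.9,
                                 euploid_high = 1.1,
                                 aneuploid_threshold = 1.15,
                                 chrom_cutoffs = c("13" = 1.145,
                                                   "18" = 1.077,
                                                   "21" = 1.068),
                                 typical_trisomy_low = 1.35,
                                 x_one = c(0.4, 0.6),
                                 x_two = c(0.9, 1.1),
                                 x_multi_min = 1.4,
                                 sry_min_conc = 10,
                                 sry_min_wells = 20L) {
  if (!(euploid_low < euploid_high))
    stop("euploid_low must be below euploid_high", call. = FALSE)
  if (!(euploid_high <= aneuploid_threshold))
    stop("aneuploid_threshold must be at or above euploid_high", call. = FALSE)
  if (!(aneuploid_threshold <= typical_trisomy_low))
    stop("typical_trisomy_low must be at or above aneuploid_threshold",
         call. = FALSE)
  stopifnot(all(chrom_cutoffs > 0), x_one[1] < x_one[2],
            x_two[1] < x_two[2], x_one[2] <= x_two[1],
            x_two[2] <= x_multi_min)
  structure(list(euploid_low = euploid_low,
                 euploid_high = euploid_high,
                 aneuploid_threshold = aneuploid_threshold,
                 chrom_cutoffs = chrom_cutoffs,
                 typical_trisomy_low = typical_trisomy_low,
                 x_one = x_one, x_two = x_two, x_multi_min = x_multi_min,
                 sry_min_conc = sry_min_conc,
                 sry_min_wells = as.integer(sry_min_wells)),
            class = "classification_bands")
}

#' @export
print.classification_bands <- function(x, ...) {
  cat("chromosomal-ratio classification bands\n")
  cat(sprintf("  euploid      : [%.3g, %.3g]\n", x$euploid_low, x$euploid_high))
  cat(sprintf("  trisomy      : >= %.3g (flagged if < %.3g)\n",
              x$aneuploid_threshold, x$typical_trisomy_low))
  cat("  dilution cutoffs:",
      paste(sprintf("chr%s %.3f", names(x$chrom_cutoffs), x$chrom_cutoffs),
            collapse = ", "), "\n")
  invisible(x)
}
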