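#' @keywords internal
chip_csv_header <- c("sample_id", "chip_id", "panel", "n_wells",
                     "n_fam_only", "n_vic_only", "n_double", "n_negative",
                     "dilution_factor")

#' Construct a single chip readout
#'
#' A chip readout is the called well-count summary of one duplex chip:
#' counts of FAM-only, VIC-only, double-positive and negative wells. The
#' four counts must sum to the total well count. Channel positives are
#' single-positive plus double-positive wells.
#'
#' @param sample_id,chip_id Labels.
#' @param panel Panel id (character) matching a configured duplex assay.
#' @param n_wells Total wells on the chip.
#' @param n_fam_only,n_vic_only,n_double,n_negative Well counts by call.
#' @param dilution_factor Dilution factor D applied during sample
#'   adjustment; >= 1, default 1.
#' @return One-row data.frame with the chip readout schema.
#' @export
chip_readout <- function(sample_id, chip_id, panel, n_wells,
                         n_fam_only, n_vic_only, n_double, n_negative,
                         dilution_factor = 1) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chip_id = as.character(chip_id),
                   panel = as.character(panel),
                   n_wells = as.integer(n_wells),
                   n_fam_only = as.integer(n_fam_only),
                   n_vic_only = as.integer(n_vic_only),
                   n_double = as.integer(n_double),
                   n_negative = as.integer(n_negative),
                   dilution_factor = as.numeric(dilution_factor),
                   stringsAsFactors = FALSE)
  validate_chips(df)
  df
}

#' Validate a table of chip readouts
#'
#' Checks the count-conservation identity
#' `n_fam_only + n_vic_only + n_double + n_negative == n_wells`,
#' non-negativity, positive well totals and dilution factors >= 1 on every
#' row. Violations raise an error naming the offending row(s).
#'
#' @param chips data.frame with the chip readout schema.
#' @return The validated data.frame, invisibly usable in pipelines.
#' @export
validate_chips <- function(chips) {
  missing_cols <- setdiff(chip_csv_header, names(chips))
  if (length(missing_cols))
    stop("chip table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cnt <- c("n_wells", "n_fam_only", "n_vic_only", "n_double", "n_negative")
  for (cl in cnt) {
    v <- chips[[cl]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)))
      stop("column '", cl, "' must hold non-missing integer counts",
           call. = FALSE)
  }
  bad <- which(chips$n_wells <= 0 |
               chips$n_fam_only < 0 | chips$n_vic_only < 0 |
               chips$n_double < 0 | chips$n_negative < 0)
  if (length(bad))
    stop("negative or zero well counts in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  s <- chips$n_fam_only + chips$n_vic_only + chips$n_double + chips$n_negative
  bad <- which(s != chips$n_wells)
  if (length(bad))
    stop("well counts do not sum to n_wells in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(chips$dilution_factor) | chips$dilution_factor < 1)
  if (length(bad))
    stop("dilution_factor must be >= 1 in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  chips
}

#' Read chip readouts from CSV
#'
#' Expects the exact header
#' `sample_id,chip_id,panel,n_wells,n_fam_only,n_vic_only,n_double,n_negative,dilution_factor`.
#' Every row is validated; rows violating the count invariants are
#' reported with their row number.
#'
#' @param path Path to a CSV file.
#' @return data.frame of validated chip readouts (possibly zero rows).
#' @export
read_chip_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), chip_csv_header))
    stop("chip CSV header must be exactly: ",
         paste(chip_csv_header, collapse = ","), call. = FALSE)
  chips <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character",
                                          chip_id = "character",
                                          panel = "character",
                                          dilution_factor = "numeric"))
  if (nrow(chips) == 0) return(chips)
  validate_chips(chips)
}

#' Write chip readouts to CSV
#'
#' @param chips data.frame of chip readouts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chip_csv <- function(chips, path) {
  validate_chips(chips)
  utils::write.csv(chips[chip_csv_header], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# positives per dye channel: single-positive + double-positive wells
channel_positives <- function(chips, channel) {
  channel <- match.arg(channel, c("FAM", "VIC"))
  if (channel == "FAM") chips$n_fam_only + chips$n_double
  else chips$n_vic_only + chips$n_double
}
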