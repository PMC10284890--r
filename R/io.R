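# Data model and delimited-text readers/writers for peak lists, absorbance
# spectra, fluorescence EEMs and the sample metadata table.
#
# File dialect: UTF-8, comma-delimited with a header row; tab-delimited input
# is accepted via `sep = "\t"`. Numeric fields are written with full double
# precision (17 significant digits) so write -> read round-trips losslessly.

.read_delim <- function(path, sep = ",") {
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(sprintf("format error in '%s': missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
}

#' Construct a validated peak list
#'
#' A peak list is the centroided output of one FT-ICR MS acquisition:
#' one row per detected ion with m/z (Th), intensity (arbitrary units) and
#' signal-to-noise ratio. Only negative-mode data are supported; peaks are
#' sorted ascending in m/z and duplicate m/z values closer than 0.1 ppm are
#' rejected as an input error.
#'
#' @param sample_id Sample identifier.
#' @param peaks Data frame with numeric columns `mz`, `intensity`, `snr`.
#' @param polarity Must be `"negative"`.
#' @return An object of class `peaklist`.
#' @export
peaklist <- function(sample_id, peaks, polarity = "negative") {
  if (!identical(polarity, "negative"))
    stop("only negative-mode peak lists are supported")
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) > 0) {
    for (col in c("mz", "intensity", "snr")) {
      v <- peaks[[col]]
      if (is.null(v) || !is.numeric(v) || any(!is.finite(v)))
        stop(sprintf("column '%s' must be finite numeric", col))
    }
    bad <- which(peaks$mz <= 0 | peaks$intensity < 0 | peaks$snr < 0)
    if (length(bad) > 0)
      stop(sprintf(
        "validation error: row %d violates mz > 0, intensity >= 0, snr >= 0",
        bad[1]))
    peaks <- peaks[order(peaks$mz), c("mz", "intensity", "snr"), drop = FALSE]
    rownames(peaks) <- NULL
    if (nrow(peaks) > 1) {
      rel <- diff(peaks$mz) / peaks$mz[-nrow(peaks)]
      if (any(rel < 1e-7))
        stop("validation error: duplicate m/z within 0.1 ppm")
    }
  } else {
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0),
                        snr = numeric(0))
  }
  structure(list(sample_id = sample_id, polarity = polarity, peaks = peaks),
            class = "peaklist")
}

#' Read a peak list from delimited text
#'
#' @param path File with header columns `mz`, `intensity`, `snr`.
#' @param sample_id Identifier attached to the returned object.
#' @param sep Field separator (`","` default, `"\t"` accepted).
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, sample_id, sep = ",") {
  df <- .read_delim(path, sep)
  .require_columns(df, c("mz", "intensity", "snr"), path)
  for (col in c("mz", "intensity", "snr")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (nrow(df) > 0 && any(is.na(v)))
      stop(sprintf("validation error in '%s': non-numeric '%s' at row %d",
                   path, col, which(is.na(v))[1]))
    df[[col]] <- v
  }
  peaklist(sample_id, df)
}

#' Construct a validated absorbance spectrum
#'
#' Stores decadic absorbance as measured on the spectrophotometer; conversion
#' to Napierian absorption coefficients happens only in the optical-index
#' functions.
#'
#' @param sample_id Sample identifier.
#' @param wavelength_nm Strictly increasing wavelengths (nm).
#' @param absorbance Non-negative decadic absorbance values.
#' @param path_length_m Cuvette path length in metres (> 0).
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(sample_id, wavelength_nm, absorbance,
                                path_length_m) {
  stopifnot(length(wavelength_nm) == length(absorbance),
            is.numeric(path_length_m), length(path_length_m) == 1,
            path_length_m > 0)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(absorbance < 0))
    stop("absorbance must be non-negative")
  structure(list(sample_id = sample_id,
                 wavelength_nm = as.numeric(wavelength_nm),
                 absorbance = as.numeric(absorbance),
                 path_length_m = path_length_m),
            class = "absorbance_spectrum")
}

#' Read an absorbance spectrum from delimited text
#'
#' @param path File with header columns `wavelength_nm`, `absorbance` and
#'   either a `path_length_m` column (constant) or none.
#' @param sample_id Identifier attached to the returned object.
#' @param path_length_m Path length (m); required when the file carries no
#'   `path_length_m` column.
#' @param sep Field separator.
#' @return An [absorbance_spectrum()].
#' @export
read_spectrum <- function(path, sample_id, path_length_m = NULL, sep = ",") {
  df <- .read_delim(path, sep)
  .require_columns(df, c("wavelength_nm", "absorbance"), path)
  if (is.null(path_length_m)) {
    if (!"path_length_m" %in% names(df))
      stop(sprintf("'%s' has no path_length_m column and none was supplied",
                   path))
    path_length_m <- df$path_length_m[1]
  }
  absorbance_spectrum(sample_id, df$wavelength_nm, df$absorbance,
                      path_length_m)
}

#' Construct a validated excitation-emission matrix
#'
#' @param sample_id Sample identifier.
#' @param excitation_nm Strictly increasing excitation grid (nm).
#' @param emission_nm Strictly increasing emission grid (nm).
#' @param intensity Non-negative matrix, rows = excitation, cols = emission.
#' @return An object of class `eem`.
#' @export
eem <- function(sample_id, excitation_nm, emission_nm, intensity) {
  intensity <- as.matrix(intensity)
  if (any(diff(excitation_nm) <= 0) || any(diff(emission_nm) <= 0))
    stop("excitation and emission grids must be strictly increasing")
  if (!all(dim(intensity) == c(length(excitation_nm), length(emission_nm))))
    stop("intensity matrix shape must match the grids")
  if (any(intensity < 0)) stop("EEM intensities must be non-negative")
  structure(list(sample_id = sample_id,
                 excitation_nm = as.numeric(excitation_nm),
                 emission_nm = as.numeric(emission_nm),
                 intensity = intensity),
            class = "eem")
}

#' Read an EEM stored in long format
#'
#' @param path File with header columns `excitation_nm`, `emission_nm`,
#'   `intensity`, one row per grid cell (complete grid required).
#' @param sample_id Identifier attached to the returned object.
#' @param sep Field separator.
#' @return An [eem()].
#' @export
read_eem <- function(path, sample_id, sep = ",") {
  df <- .read_delim(path, sep)
  .require_columns(df, c("excitation_nm", "emission_nm", "intensity"), path)
  ex <- sort(unique(df$excitation_nm))
  em <- sort(unique(df$emission_nm))
  if (nrow(df) != length(ex) * length(em))
    stop(sprintf("'%s' is not a complete excitation x emission grid", path))
  m <- matrix(NA_real_, length(ex), length(em))
  m[cbind(match(df$excitation_nm, ex), match(df$emission_nm, em))] <-
    df$intensity
  eem(sample_id, ex, em, m)
}

#' Validate a table of sample/incubation records
#'
#' One row per incubation microcosm: lake, light treatment, incubation
#' temperature, replicate, DOC and DON concentrations, cumulative headspace
#' CO2 (umol) measured on days 0/7/28 and a blank flag.
#'
#' @param df Data frame with columns `lake_id`, `treatment`, `temperature_C`,
#'   `replicate`, `doc_mgC_L`, `don_mg_L`, `co2_d0`, `co2_d7`, `co2_d28`,
#'   `is_blank`. CO2 columns may contain `NA` for unmeasured days, but day 0
#'   must be present whenever day 7 or day 28 is.
#' @return The validated data frame with class `sample_table` prepended.
#' @export
sample_table <- function(df) {
  cols <- c("lake_id", "treatment", "temperature_C", "replicate",
            "doc_mgC_L", "don_mg_L", "co2_d0", "co2_d7", "co2_d28",
            "is_blank")
  .require_columns(df, cols, "<sample table>")
  df$is_blank <- as.logical(df$is_blank)
  bad_trt <- !df$treatment %in% c("light", "dark")
  if (any(bad_trt))
    stop(sprintf(
      "unknown treatment '%s' at row %d; allowed tokens: light, dark",
      df$treatment[which(bad_trt)[1]], which(bad_trt)[1]))
  if (any(!df$is_blank & (is.na(df$doc_mgC_L) | df$doc_mgC_L <= 0)))
    stop("doc_mgC_L must be positive for non-blank samples")
  co2 <- as.matrix(df[, c("co2_d0", "co2_d7", "co2_d28")])
  if (any(co2 < 0, na.rm = TRUE))
    stop("cumulative CO2 values must be non-negative")
  later <- !is.na(df$co2_d7) | !is.na(df$co2_d28)
  orphan <- later & is.na(df$co2_d0)
  if (any(orphan))
    stop(sprintf(
      "row %d has a day-7/28 CO2 measurement but no day-0 baseline",
      which(orphan)[1]))
  class(df) <- c("sample_table", class(df))
  df
}

#' Read the sample metadata table
#'
#' @param path Delimited file with the [sample_table()] columns.
#' @param sep Field separator.
#' @return A validated `sample_table` data frame.
#' @export
read_samples <- function(path, sep = ",") {
  df <- .read_delim(path, sep)
  sample_table(df)
}

#' Write a tabular result to delimited text
#'
#' Writes any data frame (or the tabular payload of the package's S3 objects)
#' with full double precision so that the matching reader reproduces every
#' numeric field exactly. An empty table yields a header-only file.
#'
#' @param records A data frame, [peaklist()], [absorbance_spectrum()] or
#'   [eem()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, sep = ",") {
  df <- records
  if (inherits(records, "peaklist")) df <- records$peaks
  if (inherits(records, "absorbance_spectrum"))
    df <- data.frame(wavelength_nm = records$wavelength_nm,
                     absorbance = records$absorbance,
                     path_length_m = records$path_length_m)
  if (inherits(records, "eem"))
    df <- data.frame(
      excitation_nm = rep(records$excitation_nm,
                          times = length(records$emission_nm)),
      emission_nm = rep(records$emission_nm,
                        each = length(records$excitation_nm)),
      intensity = as.vector(records$intensity))
  stopifnot(is.data.frame(df))
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                 scientific = FALSE,
                                                 trim = TRUE))
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
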