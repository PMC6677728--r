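# Reflectance spectra: reading, validation, resampling to the 1 nm grid,
# per-individual averaging and group summaries.

#' Construct a reflectance spectrum on the fixed 1 nm grid
#'
#' A `refl_spectrum` holds reflectance as a proportion in \[0, 1\] on the
#' shared 300--700 nm grid (401 points, 1 nm step). All visual modelling in
#' the package consumes this type.
#'
#' @param reflectance Numeric vector of length 401 (values clipped to
#'   \[0, 1\]).
#' @param label Free-text label, typically an individual id.
#' @return An object of class `refl_spectrum` with fields `wl`,
#'   `reflectance`, `label`.
#' @export
refl_spectrum <- function(reflectance, label = "") {
  if (length(reflectance) != length(VIS_GRID)) {
    stop("reflectance must have exactly ", length(VIS_GRID),
         " values (300..700 nm, 1 nm step); got ", length(reflectance))
  }
  if (anyNA(reflectance)) stop("reflectance contains NA")
  structure(
    list(wl = VIS_GRID,
         reflectance = pmin(pmax(as.numeric(reflectance), 0), 1),
         label = as.character(label)),
    class = "refl_spectrum")
}

#' @export
print.refl_spectrum <- function(x, ...) {
  cat("<refl_spectrum> ", x$label, ": 300-700 nm, mean R = ",
      signif(mean(x$reflectance), 4), "\n", sep = "")
  invisible(x)
}

#' Read a raw spectrum table from delimited text
#'
#' Expects a header row with a wavelength column (named `wavelength_nm`, or
#' the first column) and one column per measurement, named
#' `<individual_id>_<rep>`. The field separator (comma or tab) is
#' auto-detected. Columns recorded on a percent scale (any value > 1.5) are
#' divided by 100 with a logged notice.
#'
#' @param path Path to a delimited text file.
#' @param metadata Optional data frame with one row per individual
#'   (columns: `individual_id` plus arbitrary grouping variables such as
#'   `treatment`, `blindfold`). When supplied, every measurement column must
#'   resolve to a row of it.
#' @return A `spectrum_table`: list with `wl` (numeric, strictly
#'   increasing), `measurements` (matrix, wavelength x column),
#'   `individual` (id per column), `rep` (replicate label per column) and
#'   `metadata`.
#' @export
read_spectra <- function(path, metadata = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("need a wavelength column plus >= 1 measurement column")
  wl_col <- if ("wavelength_nm" %in% names(tab)) "wavelength_nm" else names(tab)[1L]
  wl <- as.numeric(tab[[wl_col]])
  meas <- as.matrix(tab[, setdiff(names(tab), wl_col), drop = FALSE])
  storage.mode(meas) <- "double"
  spectrum_table(wl, meas, metadata = metadata)
}

#' Assemble and validate a raw spectrum table
#'
#' @param wl Wavelengths in nm, strictly increasing, spanning \[300, 700\]
#'   (2 nm edge tolerance is enforced downstream at resampling).
#' @param measurements Matrix of reflectances, one column per measurement,
#'   column names `<individual_id>_<rep>`.
#' @inheritParams read_spectra
#' @return A `spectrum_table` (see [read_spectra()]).
#' @export
spectrum_table <- function(wl, measurements, metadata = NULL) {
  wl <- as.numeric(wl)
  if (anyNA(wl) || any(diff(wl) <= 0)) stop("wavelengths not increasing")
  if (length(wl) < 2L) stop("need at least 2 wavelength points")
  measurements <- as.matrix(measurements)
  if (nrow(measurements) != length(wl)) {
    stop("measurement rows (", nrow(measurements),
         ") do not match wavelengths (", length(wl), ")")
  }
  cn <- colnames(measurements)
  if (is.null(cn) || any(!nzchar(cn))) stop("measurement columns must be named <individual_id>_<rep>")

  # percent-scale auto-detection, per column: any value > 1.5 means the
  # whole column was recorded in percent
  pct <- apply(measurements, 2L, function(x) any(x > 1.5, na.rm = TRUE))
  if (any(pct)) {
    measurements[, pct] <- measurements[, pct, drop = FALSE] / 100
    .msg("detected percent-scale reflectance in ", sum(pct),
         " column(s); divided by 100")
  }

  ids <- sub("_[^_]*$", "", cn)
  reps <- sub("^.*_", "", cn)
  no_rep <- !grepl("_", cn)
  ids[no_rep] <- cn[no_rep]
  reps[no_rep] <- "1"

  if (!is.null(metadata)) {
    if (!"individual_id" %in% names(metadata)) {
      stop("metadata must have an 'individual_id' column")
    }
    missing_md <- setdiff(unique(ids), metadata$individual_id)
    if (length(missing_md)) {
      stop("no metadata for column(s) of individual(s): ",
           paste(missing_md, collapse = ", "))
    }
  }
  structure(list(wl = wl, measurements = measurements,
                 individual = ids, rep = reps, metadata = metadata),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("<spectrum_table> ", ncol(x$measurements), " measurement(s) of ",
      length(unique(x$individual)), " individual(s), ",
      length(x$wl), " wavelengths (", min(x$wl), "-", max(x$wl), " nm)\n",
      sep = "")
  invisible(x)
}

#' Resample one measurement onto the 1 nm 300--700 nm grid
#'
#' Linear interpolation onto the integer grid, then clipping to \[0, 1\].
#' The native grid may stop short of 300 or 700 nm by at most 2 nm; edge
#' values are then extended flat. A larger gap is an error.
#'
#' @param raw A `spectrum_table`.
#' @param column Column index or name of the measurement to resample.
#' @return A [refl_spectrum()].
#' @export
resample_1nm <- function(raw, column = 1L) {
  stopifnot(inherits(raw, "spectrum_table"))
  if (is.character(column)) column <- match(column, colnames(raw$measurements))
  if (is.na(column) || column < 1L || column > ncol(raw$measurements)) {
    stop("no such measurement column")
  }
  y <- resample_matrix_1nm(raw$wl, raw$measurements[, column, drop = FALSE])
  refl_spectrum(y[, 1L], label = colnames(raw$measurements)[column])
}

# Vectorised workhorse: interpolate all columns of a wavelength x column
# matrix onto VIS_GRID with the 2 nm edge tolerance and [0, 1] clipping.
resample_matrix_1nm <- function(wl, mat) {
  lo <- min(VIS_GRID); hi <- max(VIS_GRID)
  if (min(wl) > lo + 2 || max(wl) < hi - 2) {
    stop(sprintf(
      "wavelength span [%.6g, %.6g] misses [%d, %d] by more than 2 nm (gap: %.3g nm low, %.3g nm high)",
      min(wl), max(wl), lo, hi,
      max(0, min(wl) - lo), max(0, hi - max(wl))))
  }
  out <- apply(mat, 2L, function(y)
    approx(wl, y, xout = VIS_GRID, method = "linear", rule = 2)$y)
  out <- matrix(pmin(pmax(out, 0), 1), nrow = length(VIS_GRID))
  colnames(out) <- colnames(mat)
  out
}

#' Average replicate spectra of one individual
#'
#' The standard protocol takes six measurements per individual (three per
#' lateral surface); a deviation from six is allowed but warned about.
#'
#' @param spectra List of [refl_spectrum()] objects on the shared grid.
#' @param label Label for the averaged spectrum (defaults to the first
#'   input's label stripped of its replicate suffix).
#' @return A [refl_spectrum()], the pointwise arithmetic mean.
#' @export
average_individual <- function(spectra, label = NULL) {
  if (length(spectra) == 0L) stop("empty list of spectra")
  stopifnot(all(vapply(spectra, inherits, logical(1), "refl_spectrum")))
  if (length(spectra) != 6L) {
    warning("expected 6 replicate measurements, got ", length(spectra))
  }
  m <- vapply(spectra, function(s) s$reflectance, numeric(length(VIS_GRID)))
  if (is.null(label)) label <- sub("_[^_]*$", "", spectra[[1L]]$label)
  refl_spectrum(rowMeans(m), label = label)
}

#' Pointwise mean and standard error for a group of individuals
#'
#' @param individuals List of [refl_spectrum()] (one per individual).
#' @param group Group label.
#' @return A `group_spectrum_summary`: list with `group`, `mean`, `se`
#'   (both length 401; SE = sd/sqrt(n), 0 when n = 1) and `n`.
#' @export
group_summary <- function(individuals, group = "") {
  if (length(individuals) == 0L) stop("need n >= 1 individuals")
  stopifnot(all(vapply(individuals, inherits, logical(1), "refl_spectrum")))
  m <- vapply(individuals, function(s) s$reflectance, numeric(length(VIS_GRID)))
  m <- matrix(m, nrow = length(VIS_GRID))
  n <- ncol(m)
  se <- if (n == 1L) rep(0, nrow(m)) else apply(m, 1L, sd) / sqrt(n)
  structure(list(group = group, wl = VIS_GRID,
                 mean = rowMeans(m), se = se, n = n),
            class = "group_spectrum_summary")
}

#' Per-individual mean spectra for a whole table
#'
#' Resamples every measurement to the 1 nm grid and averages replicates
#' within individual (or keeps each measurement when
#' `aggregate = "measurement"`).
#'
#' @param raw A `spectrum_table`.
#' @param aggregate `"individual"` (mean of replicates, the default) or
#'   `"measurement"` (one spectrum per measurement column).
#' @return Named list of [refl_spectrum()] objects.
#' @export
individual_spectra <- function(raw, aggregate = c("individual", "measurement")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(raw, "spectrum_table"))
  res <- resample_matrix_1nm(raw$wl, raw$measurements)
  if (aggregate == "measurement") {
    out <- lapply(seq_len(ncol(res)), function(j)
      refl_spectrum(res[, j], label = colnames(res)[j]))
    names(out) <- colnames(res)
    return(out)
  }
  ids <- unique(raw$individual)
  out <- lapply(ids, function(id) {
    cols <- which(raw$individual == id)
    if (length(cols) != 6L) {
      warning("individual ", id, ": expected 6 replicate measurements, got ",
              length(cols))
    }
    refl_spectrum(rowMeans(res[, cols, drop = FALSE]), label = id)
  })
  names(out) <- ids
  out
}

#' Write per-individual mean spectra as tidy long-format CSV
#'
#' @param spectra Named list of [refl_spectrum()].
#' @param path Output CSV path (columns: individual_id, wavelength_nm,
#'   reflectance).
#' @return The path, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- do.call(rbind, lapply(spectra, function(s)
    data.frame(individual_id = s$label, wavelength_nm = s$wl,
               reflectance = s$reflectance)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
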