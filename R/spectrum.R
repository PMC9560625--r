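#' Construct a MALDI-ToF spectrum
#'
#' A spectrum is a tibble with columns `mz` (strictly increasing, Th, singly
#' charged assumed) and `intensity` (non-negative, arbitrary units), carrying
#' the sample identifier, replicate index and acquisition m/z range as
#' attributes. The default acquisition range is 700--3500 Th, the usual window
#' for collagen peptide mass fingerprints.
#'
#' Duplicate m/z values are merged by intensity mean before validation, which
#' makes construction robust to instrument exports that repeat axis points.
#'
#' @param mz Numeric vector of m/z values (Th).
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param sample_id Sample identifier string.
#' @param replicate_index Integer replicate number (>= 1; 0 denotes an average
#'   across replicates).
#' @param mz_range Length-2 numeric, the acquisition window; points outside it
#'   are dropped with a message.
#' @return A `zooms_spectrum` tibble with columns `mz` and `intensity`.
#' @examples
#' s <- new_spectrum(c(700, 701, 702), c(1, 5, 2), sample_id = "demo")
#' s
#' @export
new_spectrum <- function(mz, intensity, sample_id = "sample",
                         replicate_index = 1L, mz_range = c(700, 3500)) {
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have the same length.", class = "zooms_format_error")
  }
  if (length(mz) == 0) {
    abort("Empty spectrum.", class = "zooms_format_error")
  }
  keep <- !is.na(mz) & !is.na(intensity)
  mz <- mz[keep]; intensity <- intensity[keep]
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  # merge exact duplicate axis points by mean intensity
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), mean))
    mz <- unique(mz)
  }
  inside <- mz >= mz_range[1] & mz <= mz_range[2]
  if (any(!inside)) {
    inform(sprintf("Dropped %d point(s) outside m/z range [%g, %g].",
                   sum(!inside), mz_range[1], mz_range[2]))
    mz <- mz[inside]; intensity <- intensity[inside]
  }
  if (length(mz) == 0) {
    abort("Spectrum empty after range filtering.", class = "zooms_format_error")
  }
  if (any(diff(mz) <= 0)) {
    abort("m/z axis not strictly increasing after sort and deduplication.",
          class = "zooms_format_error")
  }
  if (any(intensity < 0)) {
    abort("Negative intensities are not allowed.", class = "zooms_format_error")
  }
  out <- tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  structure(out,
            class = c("zooms_spectrum", class(out)),
            sample_id = as.character(sample_id),
            replicate_index = as.integer(replicate_index),
            mz_range = as.numeric(mz_range))
}

# Internal fast constructor: axis already validated (uniform grid produced by
# the package itself), skips the sort/dedup/range checks of new_spectrum().
spectrum_fast <- function(mz, intensity, at) {
  out <- tibble::new_tibble(list(mz = mz, intensity = intensity),
                            nrow = length(mz))
  structure(out, class = c("zooms_spectrum", class(out)),
            sample_id = at$sample_id,
            replicate_index = at$replicate_index,
            mz_range = at$mz_range)
}

spectrum_attrs <- function(s) {
  list(sample_id = attr(s, "sample_id"),
       replicate_index = attr(s, "replicate_index"),
       mz_range = attr(s, "mz_range"))
}

#' Read a spectrum from disk
#'
#' Supports plain two-column m/z--intensity text (whitespace or comma
#' delimited, optional header; `.txt`/`.csv`/`.xy`) and mzML (first MS1 scan;
#' requires the mzR package).
#'
#' @param path Path to the file.
#' @param format `"xy_text"` or `"mzml"`; `"auto"` guesses from the extension.
#' @inheritParams new_spectrum
#' @return A [new_spectrum()] object.
#' @export
read_spectrum <- function(path, format = c("auto", "xy_text", "mzml"),
                          sample_id = NULL, replicate_index = 1L,
                          mz_range = c(700, 3500)) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "zooms_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "xy_text"
  }
  sample_id <- sample_id %||% sub("\\.[^.]+$", "", basename(path))
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort("Reading mzML requires the mzR package.", class = "zooms_io_error")
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h), add = TRUE)
    pk <- mzR::peaks(h, 1L)
    return(new_spectrum(pk[, 1], pk[, 2], sample_id = sample_id,
                        replicate_index = replicate_index, mz_range = mz_range))
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- tryCatch(
    readr::read_delim(path, delim = NULL, col_names = has_header,
                      show_col_types = FALSE, progress = FALSE,
                      trim_ws = TRUE),
    error = function(e) abort(sprintf("Cannot parse %s: %s", path, conditionMessage(e)),
                              class = "zooms_io_error"))
  if (ncol(df) < 2) {
    # fall back to whitespace splitting
    df <- tryCatch(
      as_tibble(utils::read.table(path, header = has_header)),
      error = function(e) abort(sprintf("Cannot parse %s", path), class = "zooms_io_error"))
  }
  if (ncol(df) < 2 || nrow(df) == 0) {
    abort(sprintf("Expected two numeric columns in %s", path), class = "zooms_format_error")
  }
  mzv <- suppressWarnings(as.numeric(df[[1]]))
  intv <- suppressWarnings(as.numeric(df[[2]]))
  if (all(is.na(mzv)) || all(is.na(intv))) {
    abort(sprintf("Expected two numeric columns in %s", path),
          class = "zooms_format_error")
  }
  new_spectrum(mzv, intv, sample_id = sample_id,
               replicate_index = replicate_index, mz_range = mz_range)
}

#' Write a spectrum to disk
#'
#' Writes two-column text (tab separated) or mzML (via mzR, one MS1 profile
#' scan).
#'
#' @param s A spectrum.
#' @param path Output path.
#' @param format `"xy_text"` or `"mzml"`; `"auto"` guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "xy_text", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "xy_text"
  }
  if (format == "xy_text") {
    readr::write_tsv(tibble(mz = s$mz, intensity = s$intensity), path,
                     col_names = FALSE, progress = FALSE)
    return(invisible(path))
  }
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("Writing mzML requires the mzR package.", class = "zooms_io_error")
  }
  n <- nrow(s)
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = n, totIonCurrent = sum(s$intensity), retentionTime = 0,
    basePeakMZ = s$mz[which.max(s$intensity)],
    basePeakIntensity = max(s$intensity),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(s$mz), highMZ = max(s$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = attr(s, "mz_range")[1],
    scanWindowUpperLimit = attr(s, "mz_range")[2])
  mzR::writeMSData(list(cbind(s$mz, s$intensity)), path, header = hdr)
  invisible(path)
}

#' Resample a spectrum onto a uniform m/z grid
#'
#' Linear interpolation onto a regular grid spanning the acquisition range.
#' A uniform axis is required by the smoothing and baseline steps, and puts
#' replicates on a common axis for averaging. Outside the spectrum's own
#' coverage the intensity is taken as zero.
#'
#' @param s A spectrum.
#' @param step Grid step in Th (default 0.02, well below the ~1 Th isotope
#'   spacing).
#' @return A spectrum on the uniform grid.
#' @export
resample_to_grid <- function(s, step = 0.02) {
  rng <- attr(s, "mz_range")
  if (step <= 0) abort("`step` must be positive.", class = "zooms_parameter_error")
  if (step > diff(rng)) {
    abort("`step` exceeds the width of the m/z range.", class = "zooms_parameter_error")
  }
  grid <- seq(rng[1], rng[2], by = step)
  if (nrow(s) == 1) {
    intensity <- rep(0, length(grid))
    intensity[which.min(abs(grid - s$mz))] <- s$intensity
  } else {
    intensity <- approx(s$mz, s$intensity, xout = grid, rule = 1)$y
    intensity[is.na(intensity)] <- 0
  }
  spectrum_fast(grid, pmax(intensity, 0), spectrum_attrs(s))
}

is_uniform_grid <- function(s, tol = 1e-8) {
  d <- diff(s$mz)
  length(d) > 0 && (max(d) - min(d)) < tol * mean(d) * 10
}

#' Average technical replicates of one sample
#'
#' Each replicate is resampled onto the common grid and the pointwise
#' arithmetic mean is returned, mirroring the usual practice of averaging
#' duplicate MALDI acquisitions before peak picking. The result carries
#' `replicate_index = 0`.
#'
#' @param spectra A list of spectra sharing a `sample_id`.
#' @param step Resampling step in Th.
#' @return A spectrum on the uniform grid.
#' @export
average_replicates <- function(spectra, step = 0.02) {
  if (is.data.frame(spectra)) spectra <- list(spectra)
  if (length(spectra) == 0) {
    abort("Need at least one replicate.", class = "zooms_parameter_error")
  }
  ids <- unique(map_chr(spectra, ~ attr(.x, "sample_id")))
  if (length(ids) > 1) {
    abort("Replicates belong to different samples.", class = "zooms_parameter_error")
  }
  res <- map(spectra, resample_to_grid, step = step)
  m <- rowMeans(do.call(cbind, map(res, "intensity")))
  new_spectrum(res[[1]]$mz, m, sample_id = ids,
               replicate_index = 0L, mz_range = attr(res[[1]], "mz_range"))
}

#' @export
print.zooms_spectrum <- function(x, ...) {
  at <- spectrum_attrs(x)
  cat(sprintf("<zooms_spectrum> sample '%s' replicate %d, %d points, m/z [%g, %g]\n",
              at$sample_id, at$replicate_index, nrow(x),
              min(x$mz), max(x$mz)))
  NextMethod()
}
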