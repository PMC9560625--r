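#' Spectral preprocessing configuration
#'
#' Defaults follow common practice for ZooMS screening in mMass-style
#' processing: signal-to-noise threshold 3.5, baseline correction with 100
#' segments and relative offset 0, Savitzky-Golay smoothing with a 0.2 Th
#' window applied for 1.5 cycles, peak picking with a 0.5% relative intensity
#' threshold and 80% picking height, and deisotoping at the average peptide
#' isotope spacing of 1.00235 Th.
#'
#' @param sn_threshold Minimum signal-to-noise ratio for a picked peak.
#' @param baseline_segments Number of equal m/z windows used to anchor the
#'   baseline.
#' @param baseline_offset Fraction of each window's intensity range added to
#'   its anchor (0 = anchors at window minima).
#' @param smooth_window Savitzky-Golay window span in Th.
#' @param smooth_cycles Number of smoothing passes; a fractional part blends
#'   the flanking integer-pass results.
#' @param rel_intensity_threshold Minimum peak height as a fraction of the
#'   base peak.
#' @param picking_height Fraction of the apex height above which profile
#'   points enter the centroid.
#' @param isotope_spacing Th between successive isotopologues (z = 1).
#' @param isotope_tol Matching tolerance for isotope spacing, Th.
#' @param noise_window Width (Th) of the windows used for the robust noise
#'   estimate.
#' @param grid_step Uniform axis step in Th.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(sn_threshold = 3.5,
                              baseline_segments = 100L,
                              baseline_offset = 0,
                              smooth_window = 0.2,
                              smooth_cycles = 1.5,
                              rel_intensity_threshold = 0.005,
                              picking_height = 0.80,
                              isotope_spacing = ISOTOPE_SPACING,
                              isotope_tol = 0.05,
                              noise_window = 100,
                              grid_step = 0.02) {
  stopifnot(sn_threshold > 0, picking_height > 0, picking_height < 1,
            rel_intensity_threshold >= 0, rel_intensity_threshold < 1,
            baseline_segments >= 2, smooth_cycles > 0, smooth_window > 0)
  structure(list(sn_threshold = sn_threshold,
                 baseline_segments = as.integer(baseline_segments),
                 baseline_offset = baseline_offset,
                 smooth_window = smooth_window,
                 smooth_cycles = smooth_cycles,
                 rel_intensity_threshold = rel_intensity_threshold,
                 picking_height = picking_height,
                 isotope_spacing = isotope_spacing,
                 isotope_tol = isotope_tol,
                 noise_window = noise_window,
                 grid_step = grid_step),
            class = "preprocess_config")
}

sg_pass <- function(y, n, k = 0L) {
  if (k == 0L) return(y)
  for (i in seq_len(k)) y <- signal::sgolayfilt(y, p = 2, n = n)
  y
}

#' Savitzky-Golay smoothing with fractional cycles
#'
#' Second-order Savitzky-Golay filtering with a window spanning
#' `smooth_window` Th on the uniform grid. `smooth_cycles = 1.5` means the
#' average of the one-pass and two-pass results; in general the fractional
#' part is a convex blend between the flanking integer-pass outputs.
#'
#' @param s A spectrum on a uniform grid.
#' @param cfg A [preprocess_config()].
#' @return The smoothed spectrum.
#' @export
smooth_spectrum <- function(s, cfg = preprocess_config()) {
  if (!is_uniform_grid(s)) {
    abort("Smoothing requires a uniform grid; call resample_to_grid() first.",
          class = "zooms_precondition_error")
  }
  step <- s$mz[2] - s$mz[1]
  n <- max(5L, floor(cfg$smooth_window / step / 2) * 2 + 1)  # odd point count
  k <- floor(cfg$smooth_cycles)
  frac <- cfg$smooth_cycles - k
  y_lo <- sg_pass(s$intensity, n, k)
  y <- if (frac > 0) (1 - frac) * y_lo + frac * sg_pass(y_lo, n, 1L) else y_lo
  spectrum_fast(s$mz, pmax(y, 0), spectrum_attrs(s))
}

#' Segmented-minimum baseline correction
#'
#' The m/z axis is split into `baseline_segments` equal windows; each window
#' anchors the baseline at its intensity minimum, optionally shifted upward by
#' `baseline_offset` times the window's intensity range. The baseline is the
#' piecewise-linear interpolation through the anchors (constant beyond the
#' outer anchors) and is subtracted with clamping at zero.
#'
#' @inheritParams smooth_spectrum
#' @return The corrected spectrum, with the estimated baseline attached as
#'   attribute `"baseline"`.
#' @export
correct_baseline <- function(s, cfg = preprocess_config()) {
  if (!is_uniform_grid(s)) {
    abort("Baseline correction requires a uniform grid.",
          class = "zooms_precondition_error")
  }
  n <- nrow(s)
  nseg <- cfg$baseline_segments
  if (n < nseg) {
    abort("Fewer grid points than baseline segments.", class = "zooms_parameter_error")
  }
  seg <- cut(seq_len(n), breaks = nseg, labels = FALSE)
  idx_by_seg <- split(seq_len(n), seg)
  anchor_x <- numeric(nseg); anchor_y <- numeric(nseg)
  for (i in seq_len(nseg)) {
    idx <- idx_by_seg[[i]]
    v <- s$intensity[idx]
    j <- idx[which.min(v)]
    anchor_x[i] <- s$mz[j]
    anchor_y[i] <- s$intensity[j] + cfg$baseline_offset * (max(v) - min(v))
  }
  base <- approx(anchor_x, anchor_y, xout = s$mz, rule = 2)$y
  out <- spectrum_fast(s$mz, pmax(s$intensity - base, 0), spectrum_attrs(s))
  attr(out, "baseline") <- base
  out
}

# Robust per-point noise: MAD * 1.4826 in windows of `noise_window` Th,
# linearly interpolated between window centres.
estimate_noise <- function(s, noise_window = 100) {
  n <- nrow(s)
  span <- diff(range(s$mz))
  nwin <- max(2L, ceiling(span / noise_window))
  seg <- cut(seq_len(n), breaks = nwin, labels = FALSE)
  centre <- as.numeric(tapply(s$mz, seg, median))
  madv <- as.numeric(tapply(s$intensity, seg, function(v) mad(v, constant = 1.4826)))
  bad <- madv <= 0 | is.na(madv)
  if (all(bad)) madv[] <- 1e-12 else madv[bad] <- min(madv[!bad])
  approx(centre, madv, xout = s$mz, rule = 2)$y
}

#' @importFrom stats mad
NULL

#' Pick centroided peaks above a signal-to-noise threshold
#'
#' Noise is estimated as 1.4826 times the windowed median absolute deviation
#' of the intensity. Local maxima whose signal-to-noise ratio reaches
#' `sn_threshold` and whose height reaches `rel_intensity_threshold` of the
#' base peak are kept; each centroid is the intensity-weighted mean m/z of the
#' contiguous profile points above `picking_height` of the apex.
#'
#' @param s A smoothed, baseline-corrected spectrum on a uniform grid.
#' @param cfg A [preprocess_config()].
#' @param noise Optional per-point noise vector. Supply the estimate taken
#'   from the profile *before* smoothing (as [process_spectrum()] does):
#'   smoothing attenuates the noise floor, and an estimate taken after it
#'   lets smoothed noise maxima through the S/N gate. Defaults to estimating
#'   from `s` itself.
#' @return A `zooms_peaks` tibble: `sample_id`, `mz`, `intensity`, `sn`,
#'   `is_monoisotopic` (all `NA` before deisotoping), with the base-peak
#'   intensity as attribute.
#' @export
pick_peaks <- function(s, cfg = preprocess_config(), noise = NULL) {
  at <- spectrum_attrs(s)
  empty <- tibble(sample_id = character(), mz = numeric(),
                  intensity = numeric(), sn = numeric(),
                  is_monoisotopic = logical())
  y <- s$intensity
  if (all(y <= 0)) {
    return(structure(empty, class = c("zooms_peaks", class(empty)),
                     base_peak_intensity = 0))
  }
  noise <- noise %||% estimate_noise(s, cfg$noise_window)
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  base_peak <- max(y)
  cand <- which(is_max & y / noise >= cfg$sn_threshold &
                  y >= cfg$rel_intensity_threshold * base_peak)
  if (length(cand) == 0) {
    return(structure(empty, class = c("zooms_peaks", class(empty)),
                     base_peak_intensity = base_peak))
  }
  cent <- map_dbl(cand, function(i) {
    h <- cfg$picking_height * y[i]
    lo <- i; while (lo > 1 && y[lo - 1] >= h && y[lo - 1] <= y[lo]) lo <- lo - 1
    hi <- i; while (hi < n && y[hi + 1] >= h && y[hi + 1] <= y[hi]) hi <- hi + 1
    idx <- lo:hi
    weighted.mean(s$mz[idx], y[idx])
  })
  out <- tibble(sample_id = at$sample_id, mz = cent, intensity = y[cand],
                sn = y[cand] / noise[cand], is_monoisotopic = NA) |>
    arrange(.data$mz)
  structure(out, class = c("zooms_peaks", class(out)),
            base_peak_intensity = base_peak)
}

#' Collapse isotope envelopes to monoisotopic peaks
#'
#' Peaks spaced by `isotope_spacing` (within `isotope_tol`) are clustered
#' greedily from low m/z. Each cluster is reported as one monoisotopic peak
#' (its lowest-m/z member) carrying the full cluster in the `envelope`
#' list-column. A cluster is split when intensity rises again after the third
#' isotope, which signals a second overlapping envelope.
#'
#' @param pl A `zooms_peaks` tibble sorted by m/z.
#' @param cfg A [preprocess_config()].
#' @return A `zooms_peaks` tibble of monoisotopic peaks with an `envelope`
#'   list-column of per-cluster `(mz, intensity)` tibbles.
#' @export
deisotope_peaks <- function(pl, cfg = preprocess_config()) {
  if (nrow(pl) == 0) {
    out <- mutate(pl, envelope = list())
    return(structure(out, class = c("zooms_peaks", class(out)),
                     base_peak_intensity = attr(pl, "base_peak_intensity") %||% 0))
  }
  pl <- arrange(pl, .data$mz)
  n <- nrow(pl)
  used <- rep(FALSE, n)
  clusters <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    members <- i
    used[i] <- TRUE
    last <- i
    repeat {
      target <- pl$mz[last] + cfg$isotope_spacing
      nxt <- which(!used & abs(pl$mz - target) <= cfg$isotope_tol)
      if (length(nxt) == 0) break
      nxt <- nxt[which.min(abs(pl$mz[nxt] - target))]
      # envelope should decay after the 3rd isotope; a rise starts a new one
      if (length(members) >= 3 && pl$intensity[nxt] > pl$intensity[last]) break
      members <- c(members, nxt)
      used[nxt] <- TRUE
      last <- nxt
    }
    clusters[[length(clusters) + 1]] <- members
  }
  first <- map_dbl(clusters, 1)
  envs <- map(clusters, function(m) {
    tibble::new_tibble(list(mz = pl$mz[m], intensity = pl$intensity[m]),
                       nrow = length(m))
  })
  mono <- tibble::new_tibble(list(
    sample_id = pl$sample_id[first], mz = pl$mz[first],
    intensity = pl$intensity[first], sn = pl$sn[first],
    is_monoisotopic = rep(TRUE, length(first)), envelope = envs),
    nrow = length(first))
  ord <- order(mono$mz)
  mono <- mono[ord, ]
  structure(mono, class = c("zooms_peaks", class(mono)),
            base_peak_intensity = attr(pl, "base_peak_intensity") %||%
              max(pl$intensity))
}

#' Run the full spectral-processing chain
#'
#' Resample to a uniform grid, smooth, correct the baseline, pick peaks and
#' deisotope — the standard chain applied to each averaged ZooMS spectrum.
#'
#' @param s A spectrum (any axis; it is resampled first).
#' @param cfg A [preprocess_config()].
#' @return A deisotoped `zooms_peaks` tibble.
#' @export
process_spectrum <- function(s, cfg = preprocess_config()) {
  gridded <- resample_to_grid(s, step = cfg$grid_step)
  # noise level of the raw profile: smoothing shrinks the noise floor, so the
  # S/N gate must use the pre-smoothing estimate
  noise <- estimate_noise(gridded, cfg$noise_window)
  gridded |>
    smooth_spectrum(cfg) |>
    correct_baseline(cfg) |>
    pick_peaks(cfg, noise = noise) |>
    deisotope_peaks(cfg)
}

#' Write / read a peak list as CSV
#'
#' Columns: `sample_id`, `mz`, `intensity`, `sn`, `is_monoisotopic` (the
#' envelope list-column is not serialised).
#'
#' @param pl A `zooms_peaks` tibble.
#' @param path Output CSV path.
#' @return `path` (write) or the peak tibble (read).
#' @export
write_peaks <- function(pl, path) {
  readr::write_csv(select(as_tibble(pl), "sample_id", "mz", "intensity",
                          "sn", "is_monoisotopic"),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  structure(out, class = c("zooms_peaks", class(out)))
}
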