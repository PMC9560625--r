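#' Define a deamidation target peptide
#'
#' The two standard collagen targets for glutamine-deamidation screening are
#' the peptides observed at m/z 1105.6 and 1706.7. The theoretical isotope
#' envelope is taken from a supplied elemental composition when available and
#' otherwise from an averagine composition scaled to the neutral mass.
#'
#' @param name Peptide label, e.g. `"P1105"`.
#' @param mono_mz Monoisotopic m/z of the singly protonated ion (Th).
#' @param k Number of isotope positions modelled (default 5).
#' @param composition Optional named element-count vector.
#' @param n_gln_sites Number of glutamine sites (metadata; a single
#'   deamidation event is modelled).
#' @return A `target_peptide` list with the normalised envelope.
#' @export
target_peptide <- function(name, mono_mz, k = 5, composition = NULL,
                           n_gln_sites = 1L) {
  if (mono_mz <= 700 || mono_mz >= 3500) {
    abort("Target peptide m/z outside the acquisition range (700, 3500).",
          class = "zooms_parameter_error")
  }
  env <- theoretical_envelope(mass = mono_mz - PROTON_MASS, k = k,
                              composition = composition)
  structure(list(name = name, mono_mz = mono_mz, envelope = env, k = k,
                 n_gln_sites = as.integer(n_gln_sites)),
            class = "target_peptide")
}

#' Default deamidation targets
#'
#' @return A list of two [target_peptide()] objects: P1105 (m/z 1105.6) and
#'   P1706 (m/z 1706.7).
#' @export
default_targets <- function() {
  list(target_peptide("P1105", 1105.6), target_peptide("P1706", 1706.7))
}

# Intensity observed at each required envelope position: the strongest peak
# (or profile point) within `tol` of the position, NA when nothing is there.
# Positions with no observation are treated as missing, not as zero: a peak
# list censors everything below the picking threshold, and forcing those
# tail positions to zero penalises the longer (shifted) envelope and biases
# the mixture fraction upward.
extract_positions <- function(obj, positions, tol) {
  mz <- obj$mz
  int <- obj$intensity
  map_dbl(positions, function(p) {
    hit <- which(abs(mz - p) <= tol)
    if (length(hit) == 0) NA_real_ else max(int[hit])
  })
}

#' Estimate the undeamidated glutamine fraction of a target peptide
#'
#' The observed isotope envelope around the target is modelled as a
#' two-component mixture `c * (alpha * E0 + (1 - alpha) * E1)`: `E0` is the
#' theoretical envelope of the native (undeamidated) peptide at positions
#' `mono_mz + j * 1.00235`, and `E1` the same envelope displaced by the
#' deamidation shift of +0.98402 Th. The mixture is fitted by non-negative
#' least squares on the two component vectors; `gln_fraction = alpha` is the
#' fraction of undeamidated glutamine (1 = intact, 0 = fully deamidated).
#'
#' @param x A `zooms_peaks` tibble, spectrum, or any data frame with `mz` and
#'   `intensity` columns covering the target region.
#' @param peptide A [target_peptide()].
#' @param tol Matching tolerance around each isotope position (Th).
#' @param min_sn Minimum signal-to-noise of the monoisotopic peak for the
#'   result to be flagged usable (applied when `x` carries an `sn` column).
#' @return A `gln_fit` object; see [tidy.gln_fit()]. Fields: `sample_id`,
#'   `peptide`, `gln_fraction` in \[0, 1\] (`NA` when no signal), `fit_rss`,
#'   `usable`.
#' @export
fit_gln_fraction <- function(x, peptide, tol = 0.1, min_sn = 3.5) {
  k <- peptide$k
  # one extra position beyond the native envelope captures the shifted tail
  positions <- peptide$mono_mz + (0:k) * ISOTOPE_SPACING
  # a deisotoped list keeps the isotope cluster in the envelope list-column;
  # the fit needs the individual isotope intensities, so flatten it
  flat <- x
  if ("envelope" %in% names(x) && nrow(x) > 0 && is.list(x$envelope)) {
    flat <- list_rbind(x$envelope)
  }
  y <- extract_positions(flat, positions, tol)
  sample_id <- if ("sample_id" %in% names(x) && nrow(x) > 0) x$sample_id[1] else
    attr(x, "sample_id") %||% "sample"
  usable <- TRUE
  if ("sn" %in% names(x)) {
    hit <- which(abs(x$mz - peptide$mono_mz) <= tol)
    usable <- length(hit) > 0 && max(x$sn[hit], na.rm = TRUE) >= min_sn
  }
  obs <- !is.na(y)
  if (sum(y[obs]) <= 0 || sum(obs) < 3) {
    return(new_gln_fit(sample_id, peptide$name, NA_real_, NA_real_, FALSE,
                       y, positions))
  }
  e0 <- c(peptide$envelope, 0)[obs]
  e1 <- c(0, peptide$envelope)[obs]
  # a non-negative flat term absorbs residual chemical background under the
  # envelope; it is zero for clean data and keeps the mixture fit unbiased
  # when every extracted apex rides on the same noise floor
  fit <- pracma::lsqnonneg(cbind(e0, e1, rep(1, sum(obs))), y[obs])
  a <- fit$x
  total <- a[1] + a[2]
  alpha <- if (total > 0) min(1, max(0, a[1] / total)) else NA_real_
  new_gln_fit(sample_id, peptide$name, alpha, fit$resid.norm, usable,
              y, positions)
}

new_gln_fit <- function(sample_id, peptide, alpha, rss, usable, observed,
                        positions) {
  structure(list(sample_id = sample_id, peptide = peptide,
                 gln_fraction = alpha, fit_rss = rss, usable = usable,
                 observed = observed, positions = positions),
            class = "gln_fit")
}

#' @export
print.gln_fit <- function(x, ...) {
  cat(sprintf("<gln_fit> %s %s: %%Gln = %s (RSS %.3g, %s)\n",
              x$sample_id, x$peptide,
              ifelse(is.na(x$gln_fraction), "NA", sprintf("%.3f", x$gln_fraction)),
              ifelse(is.na(x$fit_rss), NA, x$fit_rss),
              if (isTRUE(x$usable)) "usable" else "not usable"))
  invisible(x)
}

#' Tidy a deamidation fit
#'
#' @param x A `gln_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `sample_id`, `peptide`, `gln_fraction`, `fit_rss`,
#'   `usable`.
#' @method tidy gln_fit
#' @export
tidy.gln_fit <- function(x, ...) {
  tibble(sample_id = x$sample_id, peptide = x$peptide,
         gln_fraction = x$gln_fraction, fit_rss = x$fit_rss,
         usable = x$usable)
}

#' @rdname tidy.gln_fit
#' @method glance gln_fit
#' @export
glance.gln_fit <- function(x, ...) {
  tibble(gln_fraction = x$gln_fraction, fit_rss = x$fit_rss,
         usable = x$usable, n_positions = length(x$positions),
         signal = sum(x$observed, na.rm = TRUE))
}

#' Fit both deamidation targets for a batch of samples
#'
#' @param peaklists A list of `zooms_peaks` tibbles (one per sample).
#' @param targets List of [target_peptide()]s (default [default_targets()]).
#' @inheritParams fit_gln_fraction
#' @return A tibble with one row per sample x target.
#' @export
batch_deamidation <- function(peaklists, targets = default_targets(),
                              tol = 0.1, min_sn = 3.5) {
  map(peaklists, function(pl) {
    map(targets, ~ tidy(fit_gln_fraction(pl, .x, tol = tol, min_sn = min_sn))) |>
      list_rbind()
  }) |> list_rbind()
}

#' Aggregate deamidation results per site
#'
#' For each (site, peptide) group of usable results reports n, mean, median
#' and twice the standard error of the mean (2 SE). Values are rounded to two
#' decimals in printed reports but returned at full precision.
#'
#' @param results Tibble from [batch_deamidation()] (columns `sample_id`,
#'   `peptide`, `gln_fraction`, `usable`).
#' @param sites Either a character vector aligned with `results` rows or a
#'   two-column tibble `sample_id`, `site`.
#' @return Tibble: `site`, `peptide`, `n`, `mean`, `median`, `two_se`.
#' @export
aggregate_site_stats <- function(results, sites) {
  if (is.data.frame(sites)) {
    results <- left_join(results, sites, by = "sample_id")
  } else {
    results$site <- sites
  }
  dropped <- results |>
    filter(!.data$usable | is.na(.data$gln_fraction)) |>
    distinct(.data$site, .data$peptide)
  ok <- results |> filter(.data$usable, !is.na(.data$gln_fraction))
  empty_groups <- dplyr::anti_join(dropped, distinct(ok, .data$site, .data$peptide),
                                   by = c("site", "peptide"))
  if (nrow(empty_groups) > 0) {
    warn(sprintf("Omitting %d site x peptide group(s) with no usable results.",
                 nrow(empty_groups)))
  }
  ok |>
    group_by(.data$site, .data$peptide) |>
    summarise(n = dplyr::n(),
              mean = mean(.data$gln_fraction),
              median = median(.data$gln_fraction),
              two_se = if (dplyr::n() > 1)
                2 * sd(.data$gln_fraction) / sqrt(dplyr::n()) else 0,
              .groups = "drop")
}
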