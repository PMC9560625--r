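# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Uniform-grid spectrum with constant intensity.
flat_spectrum <- function(value = 0, from = 700, to = 800, step = 0.02,
                          sample_id = "flat") {
  mz <- seq(from, to, by = step)
  new_spectrum(mz, rep(value, length(mz)), sample_id = sample_id,
               mz_range = c(from, to))
}

# Uniform-grid spectrum with Gaussian peaks at `centres` (heights `heights`,
# common sigma) on a constant-plus-ramp background.
gaussian_spectrum <- function(centres, heights, sigma = 0.08,
                              from = 700, to = 1500, step = 0.02,
                              background = 0, ramp = 0,
                              sample_id = "gauss") {
  mz <- seq(from, to, by = step)
  y <- background + ramp * (mz - from)
  for (i in seq_along(centres)) {
    y <- y + heights[i] * exp(-(mz - centres[i])^2 / (2 * sigma^2))
  }
  new_spectrum(mz, y, sample_id = sample_id, mz_range = c(from, to))
}

# Centroided peak table for a native/deamidated mixture of a target peptide,
# at exact isotope positions (the idealised, noiseless observation).
mixture_peaks <- function(peptide, alpha, scale = 100, sn = 50,
                          noise_sd = 0, sample_id = "mix") {
  k <- peptide$k
  pos <- peptide$mono_mz + (0:k) * 1.00235
  y <- scale * (alpha * c(peptide$envelope, 0) +
                  (1 - alpha) * c(0, peptide$envelope))
  if (noise_sd > 0) y <- pmax(0, y * (1 + rnorm(length(y), sd = noise_sd)))
  tibble::tibble(sample_id = sample_id, mz = pos, intensity = y,
                 sn = ifelse(y > 0, sn, 0), is_monoisotopic = NA)
}

# Independent grid-search oracle for the two-component envelope fit: scans
# alpha on a fixed grid, solves the scale c in closed form, returns the
# alpha minimising the residual sum of squares.
grid_search_alpha <- function(y, envelope, step = 0.001) {
  e0 <- c(envelope, 0)
  e1 <- c(0, envelope)
  alphas <- seq(0, 1, by = step)
  rss <- vapply(alphas, function(a) {
    m <- a * e0 + (1 - a) * e1
    cc <- sum(m * y) / sum(m * m)
    sum((y - cc * m)^2)
  }, numeric(1))
  alphas[which.min(rss)]
}

# Peak table containing every marker of one taxon (plus optional extras),
# bypassing spectral processing.
taxon_peaklist <- function(db, taxon, sample_id = taxon, extra_mz = NULL,
                           targets = TRUE) {
  m <- db$markers[db$markers$taxon == taxon, ]
  mz <- m$mono_mz
  if (targets) mz <- c(mz, 1105.6, 1706.7)
  mz <- sort(unique(c(mz, extra_mz)))
  tibble::tibble(sample_id = sample_id, mz = mz, intensity = 100,
                 sn = 50, is_monoisotopic = TRUE)
}

# Minimal bone-record tibble with all selection-criterion fields satisfied.
bone_record <- function(specimen_id = "B1", site = "S", size_cm = 3,
                        taxon = "unidentified", order_group = "indet",
                        trabeculae = TRUE, in_situ = TRUE, cortical = TRUE,
                        taphonomy = "") {
  tibble::tibble(specimen_id = specimen_id, site = site,
                 stratigraphic_unit = "SU1", size_cm = size_cm,
                 size_class = NA_character_, body_size_class = "medium",
                 taphonomy_flags = taphonomy,
                 trabeculae_visible = trabeculae,
                 in_situ_position_known = in_situ,
                 cortical_quality_ok = cortical,
                 morphological_taxon = taxon, order_group = order_group)
}

# Assemblage records matching published per-site totals: `nisp` determinate
# rows (optionally split by taxon/group), plus indeterminate and unidentified
# filler up to `total_nr`.
site_records <- function(site, total_nr, nisp_by_taxon, n_unidentified = 0) {
  det <- purrr::pmap(nisp_by_taxon, function(taxon, order_group, nisp) {
    tibble::tibble(site = site, morphological_taxon = taxon,
                   order_group = order_group)[rep(1, nisp), ]
  }) |> purrr::list_rbind()
  n_det <- nrow(det)
  n_indet <- total_nr - n_det - n_unidentified
  rest <- tibble::tibble(
    site = site,
    morphological_taxon = rep(c("indeterminate", "unidentified"),
                              c(n_indet, n_unidentified)),
    order_group = "indet")
  dplyr::bind_rows(det, rest)
}
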