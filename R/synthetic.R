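# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-spectrum generator
#'
#' The generator emulates singly charged MALDI-ToF collagen fingerprints over
#' 700--3500 m/z: Gaussian peaks with theoretical isotope envelopes at the
#' markers of one taxon, the two deamidation target peptides rendered as a
#' native/deamidated mixture, a smooth polynomial baseline, additive Gaussian
#' noise, and a peak-loss "degradation" process in which each marker is
#' dropped independently — the simplest mechanism reproducing the link
#' between poor collagen preservation and low screening success.
#'
#' @param seed Integer RNG seed.
#' @param taxon Taxon whose markers are rendered (must exist in the database).
#' @param gln_fraction Undeamidated glutamine fraction for the target
#'   peptides (1 = intact).
#' @param peak_sn Target signal-to-noise of a full-height marker peak.
#' @param peak_width_sigma Gaussian peak sigma in Th (default 0.08).
#' @param baseline_amplitude Baseline height relative to the reference peak
#'   height (default 0.2).
#' @param noise_sigma Noise standard deviation relative to the reference peak
#'   height (default 0.05; 0 disables noise).
#' @param marker_dropout_prob Probability that each marker peak is absent
#'   (degradation; default 0).
#' @param n_samples Number of samples (used by [simulate_assemblage()]).
#' @param mz_range Acquisition window.
#' @param grid_step Axis step in Th.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, taxon, gln_fraction = 1,
                       peak_sn = 20, peak_width_sigma = 0.08,
                       baseline_amplitude = 0.2, noise_sigma = 0.05,
                       marker_dropout_prob = 0, n_samples = 1L,
                       mz_range = c(700, 3500), grid_step = 0.02) {
  stopifnot(gln_fraction >= 0, gln_fraction <= 1,
            marker_dropout_prob >= 0, marker_dropout_prob <= 1,
            peak_width_sigma > 0)
  structure(list(seed = as.integer(seed), taxon = taxon,
                 gln_fraction = gln_fraction, peak_sn = peak_sn,
                 peak_width_sigma = peak_width_sigma,
                 baseline_amplitude = baseline_amplitude,
                 noise_sigma = noise_sigma,
                 marker_dropout_prob = marker_dropout_prob,
                 n_samples = as.integer(n_samples),
                 mz_range = mz_range, grid_step = grid_step),
            class = "sim_config")
}

# Add a Gaussian peak (apex `height`, sigma `sigma`) at `centre` to intensity
# vector `y` over grid `grid`, touching only points within 6 sigma.
add_gaussian <- function(y, grid, centre, height, sigma) {
  step <- grid[2] - grid[1]
  i0 <- max(1L, ceiling((centre - 6 * sigma - grid[1]) / step) + 1L)
  i1 <- min(length(grid), floor((centre + 6 * sigma - grid[1]) / step) + 1L)
  if (i0 > i1) return(y)
  idx <- i0:i1
  y[idx] <- y[idx] + height * exp(-(grid[idx] - centre)^2 / (2 * sigma^2))
  y
}

# Render one isotope envelope: relative abundances `env` (normalised to max 1
# internally) as Gaussians spaced ISOTOPE_SPACING from `mono_mz`, apex of the
# strongest isotope = `height`.
render_envelope <- function(y, grid, mono_mz, env, height, sigma) {
  rel <- env / max(env)
  for (j in seq_along(env)) {
    y <- add_gaussian(y, grid, mono_mz + (j - 1) * ISOTOPE_SPACING,
                      height * rel[j], sigma)
  }
  y
}

#' Simulate one MALDI-ToF collagen fingerprint
#'
#' @param cfg A [sim_config()].
#' @param db A [marker_db()]; the markers of `cfg$taxon` are rendered.
#' @param targets Deamidation target peptides ([default_targets()]); each is
#'   rendered as `gln_fraction` x native envelope plus
#'   `1 - gln_fraction` x envelope shifted by +0.98402 Th.
#' @param sample_id Sample identifier.
#' @return A list: `spectrum` (a [new_spectrum()]) and `truth` (one-row
#'   tibble: `sample_id`, `taxon`, `gln_fraction`, `n_markers_retained`,
#'   `n_markers_total`).
#' @export
simulate_spectrum <- function(cfg, db = example_marker_db(),
                              targets = default_targets(),
                              sample_id = "synthetic") {
  if (!cfg$taxon %in% db$taxa) {
    abort(sprintf("Unknown taxon '%s'.", cfg$taxon),
          class = "zooms_parameter_error")
  }
  markers <- filter(db$markers, .data$taxon == cfg$taxon)
  with_local_seed(cfg$seed, {
    grid <- seq(cfg$mz_range[1], cfg$mz_range[2], by = cfg$grid_step)
    y <- numeric(length(grid))
    ref_height <- if (cfg$noise_sigma > 0)
      cfg$peak_sn * cfg$noise_sigma * 100 else 100
    keep <- runif(nrow(markers)) >= cfg$marker_dropout_prob
    for (i in which(keep)) {
      env <- theoretical_envelope(markers$mono_mz[i] - PROTON_MASS, k = 5)
      h <- ref_height * runif(1, 0.6, 1.4)
      y <- render_envelope(y, grid, markers$mono_mz[i], env, h,
                           cfg$peak_width_sigma)
    }
    # target peptides are collagen peptides too: degradation drops them with
    # the same probability as the markers
    for (tp in targets) {
      if (runif(1) < cfg$marker_dropout_prob) next
      h <- ref_height * runif(1, 0.8, 1.2)
      if (cfg$gln_fraction > 0) {
        y <- render_envelope(y, grid, tp$mono_mz, tp$envelope,
                             h * cfg$gln_fraction, cfg$peak_width_sigma)
      }
      if (cfg$gln_fraction < 1) {
        y <- render_envelope(y, grid, tp$mono_mz + deamidation_mass_shift(),
                             tp$envelope, h * (1 - cfg$gln_fraction),
                             cfg$peak_width_sigma)
      }
    }
    # smooth polynomial baseline, highest at the low-mass end as in MALDI,
    # plus a constant chemical-noise floor that keeps the profile positive
    # (4 sigma of the additive noise) so the detector clamp does not truncate
    # the noise distribution
    x01 <- (grid - cfg$mz_range[1]) / diff(cfg$mz_range)
    y <- y + cfg$baseline_amplitude * ref_height * (1 - x01)^2 +
      4 * cfg$noise_sigma * 100
    if (cfg$noise_sigma > 0) {
      y <- y + rnorm(length(grid), sd = cfg$noise_sigma * 100)
    }
    spec <- new_spectrum(grid, pmax(y, 0), sample_id = sample_id,
                         replicate_index = 1L, mz_range = cfg$mz_range)
    list(spectrum = spec,
         truth = tibble(sample_id = sample_id, taxon = cfg$taxon,
                        gln_fraction = cfg$gln_fraction,
                        n_markers_retained = sum(keep),
                        n_markers_total = nrow(markers)))
  })
}

size_class_of <- function(size_cm) {
  cut(size_cm, breaks = c(0, 1, 2, 3, 4, 5, Inf),
      labels = c("0-1", "1-2", "2-3", "3-4", "4-5", ">5"), right = TRUE) |>
    as.character()
}

#' Simulate a multi-site screening assemblage with known ground truth
#'
#' Each site configuration sets the number of sampled fragments, the taxon
#' mix, the marker-dropout probability (collagen degradation) and the
#' deamidation level, so that preservation gradients across sites — and the
#' resulting success-rate and %Gln gradients — are reproducible from the seed
#' alone.
#'
#' @param site_configs A list of lists, each with elements `site`, `n`,
#'   `taxa` (character vector or named probability vector), `dropout`,
#'   `gln_fraction` (scalar or length-2 `c(mean, sd)` for per-sample
#'   variation), and optionally `peak_sn`, `noise_sigma`.
#' @param db A [marker_db()].
#' @param targets Deamidation targets.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @return A list: `bones` (bone-record tibble), `spectra` (named list of
#'   spectra), `truth` (tibble `sample_id`, `site`, `taxon`,
#'   `gln_fraction`, retained-marker counts).
#' @export
simulate_assemblage <- function(site_configs, db = example_marker_db(),
                                targets = default_targets(), seed = 1L) {
  site_configs <- purrr::keep(site_configs, ~ (.x$n %||% 0) > 0)
  if (length(site_configs) == 0) {
    abort("No site has n > 0.", class = "zooms_parameter_error")
  }
  with_local_seed(seed, {
    out_bones <- list(); out_truth <- list(); out_spectra <- list()
    for (sc in site_configs) {
      if (is.null(sc$taxa) || length(sc$taxa) == 0) {
        abort(sprintf("Site '%s' has an empty taxon mix.", sc$site),
              class = "zooms_parameter_error")
      }
      if (!is.null(names(sc$taxa)) && is.numeric(sc$taxa)) {
        taxa <- names(sc$taxa)
        prob <- sc$taxa / sum(sc$taxa)
      } else {
        taxa <- sc$taxa
        prob <- rep(1 / length(sc$taxa), length(sc$taxa))
      }
      for (i in seq_len(sc$n)) {
        sid <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", sc$site), i)
        taxon <- sample(taxa, 1, prob = prob)
        gf <- sc$gln_fraction %||% 1
        alpha <- if (length(gf) == 2) min(1, max(0, rnorm(1, gf[1], gf[2])))
        else gf
        sub_seed <- sample.int(.Machine$integer.max, 1)
        cfg <- sim_config(seed = sub_seed, taxon = taxon,
                          gln_fraction = alpha,
                          peak_sn = sc$peak_sn %||% 20,
                          noise_sigma = sc$noise_sigma %||% 0.05,
                          marker_dropout_prob = sc$dropout %||% 0)
        sim <- simulate_spectrum(cfg, db, targets, sample_id = sid)
        size <- runif(1, 2.1, 6.5)
        out_bones[[sid]] <- tibble(
          specimen_id = sid, site = sc$site, stratigraphic_unit = "SU1",
          size_cm = size, size_class = size_class_of(size),
          body_size_class = "medium", taphonomy_flags = "",
          trabeculae_visible = TRUE, in_situ_position_known = TRUE,
          cortical_quality_ok = TRUE,
          morphological_taxon = "unidentified", order_group = "indet")
        out_truth[[sid]] <- mutate(sim$truth, site = sc$site)
        out_spectra[[sid]] <- sim$spectrum
      }
    }
    list(bones = list_rbind(out_bones),
         spectra = out_spectra,
         truth = list_rbind(out_truth))
  })
}

#' Write a simulated assemblage to a directory
#'
#' Writes `bones.csv`, `truth.csv` and one spectrum file per sample
#' (`<sample_id>.txt` two-column text, or `.mzML` when `format = "mzml"`).
#'
#' @param assemblage Result of [simulate_assemblage()].
#' @param dir Output directory (created if needed).
#' @param format Spectrum format, `"xy_text"` or `"mzml"`.
#' @return `dir`, invisibly.
#' @export
write_assemblage <- function(assemblage, dir, format = c("xy_text", "mzml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(assemblage$bones, file.path(dir, "bones.csv"),
                   progress = FALSE)
  readr::write_csv(assemblage$truth, file.path(dir, "truth.csv"),
                   progress = FALSE)
  ext <- if (format == "mzml") ".mzML" else ".txt"
  for (sid in names(assemblage$spectra)) {
    write_spectrum(assemblage$spectra[[sid]], file.path(dir, paste0(sid, ext)),
                   format = format)
  }
  invisible(dir)
}
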