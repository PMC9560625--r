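#' Assemble a pipeline run configuration
#'
#' Collects paths and parameters for an end-to-end screening run. All
#' processing parameters default to the values of [preprocess_config()].
#'
#' @param spectra_dir Directory of spectrum files (`.txt`/`.csv`/`.mzML`).
#'   Replicates of one sample are recognised by a `_rep<k>` filename suffix
#'   and averaged.
#' @param bones Path to the bone-record CSV (may be `NULL`).
#' @param markers,groups Paths to the marker and ambiguity-group TSVs
#'   (default: the packaged illustrative tables).
#' @param out_dir Output directory.
#' @param preprocess A [preprocess_config()].
#' @param tol Marker-matching tolerance (Th).
#' @param min_diagnostic Diagnostic-marker minimum for species-level calls.
#' @param deamidation_tol Isotope-position matching tolerance (Th).
#' @param deamidation_min_sn Usability threshold for the monoisotopic peak.
#' @param extraction_protocol `"acid_demineralised"` or `"ambic_only"` —
#'   recorded with the outputs because acid demineralisation inflates
#'   deamidation; no correction is applied.
#' @return A `run_config` list.
#' @export
run_config <- function(spectra_dir, bones = NULL, markers = NULL,
                       groups = NULL, out_dir = tempfile("zooms_run_"),
                       preprocess = preprocess_config(), tol = 0.2,
                       min_diagnostic = 2, deamidation_tol = 0.1,
                       deamidation_min_sn = 3.5,
                       extraction_protocol = c("acid_demineralised",
                                               "ambic_only")) {
  extraction_protocol <- match.arg(extraction_protocol)
  structure(list(spectra_dir = spectra_dir, bones = bones,
                 markers = markers, groups = groups, out_dir = out_dir,
                 preprocess = preprocess, tol = tol,
                 min_diagnostic = min_diagnostic,
                 deamidation_tol = deamidation_tol,
                 deamidation_min_sn = deamidation_min_sn,
                 extraction_protocol = extraction_protocol),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; preprocessing
#' parameters live under a `preprocess:` section.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading YAML configs requires the yaml package.",
          class = "zooms_io_error")
  }
  y <- yaml::read_yaml(path)
  pp <- do.call(preprocess_config, y$preprocess %||% list())
  args <- y[setdiff(names(y), "preprocess")]
  do.call(run_config, c(args, list(preprocess = pp)))
}

list_sample_files <- function(dir) {
  files <- list.files(dir, pattern = "\\.(txt|csv|xy|mzml)$",
                      ignore.case = TRUE, full.names = TRUE)
  # metadata tables that may share the directory are not spectra
  reserved <- c("bones.csv", "truth.csv", "markers.tsv", "groups.tsv")
  files <- files[!tolower(basename(files)) %in% reserved]
  ids <- sub("_rep[0-9]+$", "", sub("\\.[^.]+$", "", basename(files)))
  split(files, ids)
}

#' Run the full screening pipeline
#'
#' Reads and (where replicated) averages all spectra in the configured
#' directory, processes each through the smoothing / baseline / peak-picking
#' / deisotoping chain, assigns taxa against the marker database, fits %Gln
#' for both deamidation targets, tallies bone records when provided, and
#' writes `assignments.csv`, `deamidation.csv`, `site_deamidation.csv`,
#' `combined_nisp.csv` (when bone records are available) plus a `run_log.txt`
#' recording every parameter used. Failed samples are logged and skipped,
#' never fatal.
#'
#' @param cfg A [run_config()].
#' @return A list with elements `assignments`, `success_rate`,
#'   `deamidation`, `site_deamidation`, `summary` (or `NULL`), `log` and
#'   `out_dir`, invisibly written to disk as well.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("zoomscreen pipeline run",
                 paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 paste0("spectra_dir: ", cfg$spectra_dir),
                 paste0("bones: ", cfg$bones %||% "<none>"),
                 paste0("markers: ", cfg$markers %||% "<packaged example>"),
                 paste0("groups: ", cfg$groups %||% "<packaged example>"),
                 paste0("tol: ", cfg$tol),
                 paste0("min_diagnostic: ", cfg$min_diagnostic),
                 paste0("deamidation_tol: ", cfg$deamidation_tol),
                 paste0("deamidation_min_sn: ", cfg$deamidation_min_sn),
                 paste0("extraction_protocol: ", cfg$extraction_protocol),
                 paste0("preprocess.", names(cfg$preprocess), ": ",
                        unlist(cfg$preprocess)))
  db <- if (is.null(cfg$markers)) example_marker_db()
  else load_markers(cfg$markers, cfg$groups)

  groups_files <- list_sample_files(cfg$spectra_dir)
  if (length(groups_files) == 0) {
    warn("No spectrum files found; producing empty outputs.")
  }
  peaklists <- list()
  for (sid in names(groups_files)) {
    pl <- tryCatch({
      reps <- imap(unname(groups_files[[sid]]),
                   ~ read_spectrum(.x, sample_id = sid,
                                   replicate_index = .y))
      avg <- average_replicates(reps, step = cfg$preprocess$grid_step)
      process_spectrum(avg, cfg$preprocess)
    }, error = function(e) {
      log_lines <<- c(log_lines,
                      sprintf("SKIPPED %s: %s", sid, conditionMessage(e)))
      NULL
    })
    if (!is.null(pl)) peaklists[[sid]] <- pl
  }

  if (length(peaklists) > 0) {
    idres <- batch_identify(peaklists, db, tol = cfg$tol,
                            min_diagnostic = cfg$min_diagnostic)
    assignments <- idres$assignments
    rate <- idres$success_rate
    deam <- batch_deamidation(peaklists, tol = cfg$deamidation_tol,
                              min_sn = cfg$deamidation_min_sn)
  } else {
    assignments <- tibble(sample_id = character(), assignment = character(),
                          n_diagnostic = integer(),
                          matched_markers = character(),
                          needs_morphological_review = logical())
    rate <- NA_integer_
    deam <- tibble(sample_id = character(), peptide = character(),
                   gln_fraction = numeric(), fit_rss = numeric(),
                   usable = logical())
  }
  deam$extraction_protocol <- rep(cfg$extraction_protocol, nrow(deam))

  bones <- NULL; summary <- NULL; site_deam <- NULL; combined <- NULL
  if (!is.null(cfg$bones) && file.exists(cfg$bones)) {
    bones <- readr::read_csv(cfg$bones, show_col_types = FALSE,
                             progress = FALSE)
    summary <- tally_counts(bones)
    sites <- select(bones, sample_id = "specimen_id", "site")
    if (nrow(deam) > 0) {
      site_deam <- aggregate_site_stats(deam, sites)
      readr::write_csv(site_deam, file.path(cfg$out_dir, "site_deamidation.csv"),
                       progress = FALSE)
    }
    combined <- integrate_zooms_nisp(summary, assignments, bones)
    readr::write_csv(combined, file.path(cfg$out_dir, "combined_nisp.csv"),
                     progress = FALSE)
    readr::write_csv(summary$totals, file.path(cfg$out_dir, "site_totals.csv"),
                     progress = FALSE)
  }
  write_assignments(assignments, file.path(cfg$out_dir, "assignments.csv"))
  readr::write_csv(deam, file.path(cfg$out_dir, "deamidation.csv"),
                   progress = FALSE)
  log_lines <- c(log_lines,
                 sprintf("samples_processed: %d", length(peaklists)),
                 sprintf("success_rate: %s", rate))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(assignments = assignments, success_rate = rate,
                 deamidation = deam, site_deamidation = site_deam,
                 summary = summary, combined_nisp = combined,
                 log = log_lines, out_dir = cfg$out_dir))
}
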