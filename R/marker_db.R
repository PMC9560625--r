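#' Build a collagen peptide-marker database
#'
#' A marker database couples a table of taxon-specific collagen peptide
#' markers (taxon, marker series label, monoisotopic m/z, diagnostic flag)
#' with named ambiguity groups: sets of taxa that the available markers cannot
#' separate (for example Bos/Bison, or the Carnivora/Sus scrofa/Lepus sp.
#' group that shares the 1453.7 peptide).
#'
#' @param markers Tibble with columns `taxon`, `series`, `mono_mz`,
#'   `diagnostic` (logical).
#' @param groups Tibble with columns `group_name`, `member_taxon`, or `NULL`.
#' @return A `marker_db` object.
#' @export
marker_db <- function(markers, groups = NULL) {
  markers <- as_tibble(markers)
  required <- c("taxon", "series", "mono_mz", "diagnostic")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0) {
    abort(sprintf("Marker table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "zooms_format_error")
  }
  markers$mono_mz <- as.numeric(markers$mono_mz)
  markers$diagnostic <- as.logical(markers$diagnostic)
  bad <- which(markers$mono_mz < 700 | markers$mono_mz > 3500 |
                 is.na(markers$mono_mz))
  if (length(bad) > 0) {
    abort(sprintf("Marker mass out of range (700-3500 Th) in row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "zooms_validation_error")
  }
  if (any(!nzchar(markers$series))) {
    abort("Marker series labels must be non-empty.", class = "zooms_validation_error")
  }
  dup <- markers |> count(.data$taxon, .data$series, .data$mono_mz) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort("Duplicate (taxon, series, mono_mz) marker rows.",
          class = "zooms_validation_error")
  }
  if (is.null(groups)) {
    groups <- tibble(group_name = character(), member_taxon = character())
  }
  groups <- as_tibble(groups)
  if (!all(c("group_name", "member_taxon") %in% names(groups))) {
    abort("Group table needs columns group_name, member_taxon.",
          class = "zooms_format_error")
  }
  structure(list(markers = markers,
                 taxa = sort(unique(markers$taxon)),
                 groups = groups),
            class = "marker_db")
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf("<marker_db> %d markers, %d taxa, %d ambiguity groups\n",
              nrow(x$markers), length(x$taxa),
              length(unique(x$groups$group_name))))
  invisible(x)
}

#' Load a marker database from TSV files
#'
#' `markers.tsv` needs columns `taxon`, `series`, `mono_mz`, `diagnostic`;
#' `groups.tsv` (optional) needs `group_name`, `member_taxon`. The package
#' ships an illustrative example pair under
#' `system.file("extdata", package = "zoomscreen")` — synthetic marker masses
#' for demonstration and testing, not a curated reference list.
#'
#' @param path Path to the marker TSV.
#' @param groups_path Optional path to the ambiguity-group TSV.
#' @return A [marker_db()] object.
#' @export
load_markers <- function(path, groups_path = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Marker table not found: %s", path), class = "zooms_io_error")
  }
  markers <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  groups <- NULL
  if (!is.null(groups_path)) {
    if (!file.exists(groups_path)) {
      abort(sprintf("Group table not found: %s", groups_path),
            class = "zooms_io_error")
    }
    groups <- readr::read_tsv(groups_path, show_col_types = FALSE, progress = FALSE)
  }
  marker_db(markers, groups)
}

#' The packaged illustrative marker database
#'
#' Loads the synthetic example marker and ambiguity-group tables shipped with
#' the package. Masses are illustrative placeholders in the ZooMS mass range
#' (including the shared 1453.7-class peptide and the 1105.6/1706.7
#' deamidation targets); real analyses should supply curated tables.
#'
#' @return A [marker_db()] object.
#' @export
example_marker_db <- function() {
  load_markers(system.file("extdata", "markers.tsv", package = "zoomscreen"),
               system.file("extdata", "groups.tsv", package = "zoomscreen"))
}

#' Markers compatible with an observed m/z
#'
#' @param db A [marker_db()].
#' @param mz Observed monoisotopic m/z (Th).
#' @param tol Matching tolerance (Th, default 0.2).
#' @return Tibble of matching rows (`taxon`, `series`, `mono_mz`,
#'   `diagnostic`); zero rows when nothing matches.
#' @export
candidates_for_peak <- function(db, mz, tol = 0.2) {
  if (tol <= 0) abort("`tol` must be positive.", class = "zooms_parameter_error")
  db$markers[abs(db$markers$mono_mz - mz) <= tol, ]
}

# Smallest registered ambiguity group containing all `taxa`; NA when none.
smallest_covering_group <- function(db, taxa) {
  gl <- split(db$groups$member_taxon, db$groups$group_name)
  covering <- names(gl)[map_lgl(gl, ~ all(taxa %in% .x))]
  if (length(covering) == 0) return(NA_character_)
  sizes <- map_dbl(covering, ~ length(gl[[.x]]))
  covering[order(sizes, covering)][1]
}
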