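#' Match monoisotopic peaks against the marker database
#'
#' Every monoisotopic peak in the list is queried against the marker table;
#' all hits within the tolerance are returned with their provenance (observed
#' m/z, taxon, series, diagnostic flag).
#'
#' @param pl A deisotoped `zooms_peaks` tibble.
#' @param db A [marker_db()].
#' @param tol Matching tolerance in Th (default 0.2).
#' @return Tibble: `mz_observed`, `taxon`, `series`, `mono_mz`, `diagnostic`.
#' @export
match_markers <- function(pl, db, tol = 0.2) {
  empty <- tibble(mz_observed = numeric(), taxon = character(),
                  series = character(), mono_mz = numeric(),
                  diagnostic = logical())
  if (nrow(pl) == 0) return(empty)
  mono <- pl
  if ("is_monoisotopic" %in% names(pl)) {
    mono <- filter(pl, is.na(.data$is_monoisotopic) | .data$is_monoisotopic)
  }
  if (nrow(mono) == 0) return(empty)
  hits <- map(mono$mz, function(m) {
    cand <- candidates_for_peak(db, m, tol)
    if (nrow(cand) == 0) return(NULL)
    tibble(mz_observed = m, taxon = cand$taxon, series = cand$series,
           mono_mz = cand$mono_mz, diagnostic = cand$diagnostic)
  })
  out <- list_rbind(purrr::compact(hits))
  if (nrow(out) == 0) empty else out
}

#' Assign a taxon or ambiguity group from marker matches
#'
#' Implements the screening decision rules used when reading collagen
#' fingerprints against a marker table:
#' \enumerate{
#'   \item candidate taxa are scored by their number of matched diagnostic
#'     markers;
#'   \item a unique taxon reaching `min_diagnostic` diagnostic matches and
#'     strictly dominating all others is assigned at species level;
#'   \item several top-scoring taxa that cannot be separated are escalated to
#'     the smallest registered ambiguity group covering them (e.g.
#'     "Bos/Bison", "Caprinae/Cervidae", "Ursus sp./Lynx lynx");
#'   \item when the evidence is a single shared diagnostic peptide (the
#'     1453.7-class situation) the group registered for that marker is
#'     assigned and the record is flagged for morphological review;
#'   \item matches that resolve only order-wide ungulate markers yield
#'     "Ungulata";
#'   \item anything else is "undetermined".
#' }
#'
#' @param matches Tibble from [match_markers()].
#' @param db The [marker_db()] the matches came from.
#' @param min_diagnostic Minimum number of diagnostic markers for a
#'   species-level call (default 2).
#' @param sample_id Sample identifier carried into the result.
#' @return One-row tibble: `sample_id`, `assignment`, `n_diagnostic`,
#'   `matched_markers` (semicolon-joined), `needs_morphological_review`.
#' @export
assign_taxon <- function(matches, db, min_diagnostic = 2,
                         sample_id = "sample") {
  unknown <- setdiff(unique(matches$taxon), db$taxa)
  if (length(unknown) > 0) {
    abort(sprintf("Matches reference taxa absent from the database: %s",
                  paste(unknown, collapse = ", ")),
          class = "zooms_consistency_error")
  }
  result <- function(assignment, n_diag, review = FALSE) {
    tibble(sample_id = sample_id,
           assignment = assignment,
           n_diagnostic = as.integer(n_diag),
           matched_markers = paste(
             sprintf("%.2f:%s:%s", matches$mz_observed, matches$taxon,
                     matches$series),
             collapse = ";"),
           needs_morphological_review = review)
  }
  if (nrow(matches) == 0) return(result("undetermined", 0))

  diag <- filter(matches, .data$diagnostic)
  if (nrow(diag) == 0) {
    # only non-diagnostic markers matched; mammal-wide peptides (present in
    # every collagen spectrum) carry no signal, so restrict to taxa that are
    # members of some registered group and call Ungulata when the order-wide
    # group covers them all
    grouped <- intersect(unique(matches$taxon), db$groups$member_taxon)
    if (length(grouped) > 0) {
      ung <- smallest_covering_group(db, grouped)
      if (!is.na(ung) && ung == "Ungulata") return(result("Ungulata", 0))
    }
    return(result("undetermined", 0))
  }

  score <- diag |>
    distinct(.data$taxon, .data$series, .data$mono_mz) |>
    count(.data$taxon, name = "n_diag") |>
    arrange(dplyr::desc(.data$n_diag))
  top <- score$n_diag[1]
  leaders <- score$taxon[score$n_diag == top]

  # single shared diagnostic peptide: assign the group registered for the
  # taxa sharing that marker and request morphological review
  n_distinct_diag_peaks <- nrow(distinct(diag, .data$mono_mz))
  if (n_distinct_diag_peaks == 1 && length(leaders) > 1) {
    grp <- smallest_covering_group(db, leaders)
    if (!is.na(grp)) return(result(grp, top, review = TRUE))
    return(result("undetermined", top, review = TRUE))
  }

  if (length(leaders) == 1 && top >= min_diagnostic) {
    # strict dominance: the runner-up (if any) must score lower, and the
    # leader's markers must not be wholly shared with another candidate
    return(result(leaders, top))
  }

  if (length(leaders) >= 1) {
    grp <- smallest_covering_group(db, leaders)
    if (!is.na(grp)) {
      review <- n_distinct_diag_peaks == 1
      return(result(grp, top, review = review))
    }
    # leaders not jointly covered: fall back to Ungulata if everything in
    # sight is ungulate, else undetermined
    grouped <- intersect(unique(matches$taxon), db$groups$member_taxon)
    if (length(grouped) > 0) {
      ung <- smallest_covering_group(db, grouped)
      if (!is.na(ung) && ung == "Ungulata") return(result("Ungulata", top))
    }
  }
  result("undetermined", top)
}

#' Identify a batch of samples and report the screening success rate
#'
#' @param peaklists List of deisotoped `zooms_peaks` tibbles (one per
#'   sample).
#' @param db A [marker_db()].
#' @param tol Matching tolerance (Th).
#' @param min_diagnostic Passed to [assign_taxon()].
#' @return A list with `assignments` (tibble, one row per sample) and
#'   `success_rate` — the percentage of samples not left "undetermined",
#'   rounded to the nearest integer, the convention used when reporting ZooMS
#'   screening success.
#' @export
batch_identify <- function(peaklists, db, tol = 0.2, min_diagnostic = 2) {
  if (length(peaklists) == 0) {
    abort("Need at least one peak list.", class = "zooms_parameter_error")
  }
  assignments <- imap(peaklists, function(pl, i) {
    sid <- if ("sample_id" %in% names(pl) && nrow(pl) > 0) pl$sample_id[1]
    else if (is.character(i)) i else paste0("sample_", i)
    assign_taxon(match_markers(pl, db, tol), db,
                 min_diagnostic = min_diagnostic, sample_id = sid)
  }) |> list_rbind()
  list(assignments = assignments,
       success_rate = success_rate(assignments))
}

#' Screening success rate of an assignment table
#'
#' `100 * determined / tested`, rounded to the nearest integer: the fraction
#' of screened samples that yielded any taxonomic information (a taxon or an
#' ambiguity group rather than "undetermined").
#'
#' @param assignments Tibble with an `assignment` column, or a character
#'   vector of assignments.
#' @return Integer percentage in \[0, 100\].
#' @examples
#' success_rate(c(rep("Bos/Bison", 84), rep("undetermined", 10)))  # 89
#' @export
success_rate <- function(assignments) {
  a <- if (is.data.frame(assignments)) assignments$assignment else assignments
  if (length(a) == 0) return(NA_integer_)
  as.integer(round(100 * sum(a != "undetermined") / length(a)))
}

#' Write an assignment table to CSV
#'
#' @param assignments Tibble from [batch_identify()].
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  readr::write_csv(assignments, path, progress = FALSE)
  invisible(path)
}
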