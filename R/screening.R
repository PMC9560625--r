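#' Select unidentified bone fragments for ZooMS screening
#'
#' Applies the five morphological screening criteria used to pick fragments
#' worth destructive sampling: (i) size above 2 cm; (ii) visible trabecular
#' arrangement; (iii) scarce taphonomic alteration (combustion, manganese
#' staining, concretion); (iv) excavation position known; (v) adequate
#' cortical bone quality. Only morphologically unidentified fragments are
#' considered.
#'
#' @param records Tibble of bone records with columns `specimen_id`,
#'   `morphological_taxon`, `size_cm`, `trabeculae_visible`,
#'   `in_situ_position_known`, `cortical_quality_ok`, `taphonomy_flags`
#'   (list-column or semicolon-joined string).
#' @param min_size_cm Size cutoff in cm (strictly greater; default 2).
#' @param max_taphonomy_flags Maximum number of taphonomic alterations
#'   tolerated (default 0 = none of combustion/manganese/concretion; raise to
#'   allow moderate alteration).
#' @return Character vector of selected `specimen_id`s in input order.
#' @export
select_for_zooms <- function(records, min_size_cm = 2,
                             max_taphonomy_flags = 0) {
  needed <- c("specimen_id", "morphological_taxon", "size_cm",
              "trabeculae_visible", "in_situ_position_known",
              "cortical_quality_ok")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("Bone records lack column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "zooms_format_error")
  }
  flags <- records$taphonomy_flags %||% vector("list", nrow(records))
  n_flags <- map_dbl(seq_len(nrow(records)), function(i) {
    f <- if (is.list(flags)) flags[[i]] else flags[i]
    if (is.null(f) || all(is.na(f))) return(0)
    if (is.character(f) && length(f) == 1) {
      f <- strsplit(f, ";", fixed = TRUE)[[1]]
    }
    sum(nzchar(trimws(f)))
  })
  crit <- records$morphological_taxon == "unidentified" &
    records$size_cm > min_size_cm &
    records$trabeculae_visible & records$in_situ_position_known &
    records$cortical_quality_ok & n_flags <= max_taphonomy_flags
  incomplete <- is.na(crit)
  if (any(incomplete)) {
    warn(sprintf("%d record(s) with missing criterion fields excluded.",
                 sum(incomplete)))
    crit[incomplete] <- FALSE
  }
  records$specimen_id[crit]
}

#' Tally a faunal assemblage into site summaries
#'
#' Computes, per site, the total number of remains (NR), the total NISP
#' (determinate specimens), the determinate percentage, NISP and %NISP per
#' order group (Lagomorpha / Carnivora / Ungulata) with the total NISP as
#' denominator, and per-taxon %NISP with the taxon's order-group NISP as
#' denominator — the denominator convention of standard NISP tables.
#'
#' A record is determinate when `morphological_taxon` is a taxon label,
#' indeterminate when it is `"indeterminate"`, unidentified when
#' `"unidentified"`.
#'
#' @param records Tibble with columns `site`, `morphological_taxon`, and
#'   `order_group` (one of Lagomorpha, Carnivora, Ungulata, indet).
#' @return A `site_summary` object: list of tibbles `totals`, `groups`,
#'   `taxa`.
#' @export
tally_counts <- function(records) {
  status <- dplyr::case_when(
    records$morphological_taxon == "indeterminate" ~ "indeterminate",
    records$morphological_taxon == "unidentified" ~ "unidentified",
    TRUE ~ "determinate")
  records$.status <- status
  totals <- records |>
    group_by(site = .data$site) |>
    summarise(total_nr = dplyr::n(),
              total_nisp = sum(.data$.status == "determinate"),
              indeterminate = sum(.data$.status == "indeterminate"),
              unidentified = sum(.data$.status == "unidentified"),
              .groups = "drop") |>
    mutate(determinate_pct = round_half_up(100 * .data$total_nisp /
                                             .data$total_nr, 1))
  det <- filter(records, .data$.status == "determinate")
  groups <- det |>
    count(site = .data$site, order_group = .data$order_group,
          name = "group_nisp") |>
    left_join(select(totals, "site", "total_nisp"), by = "site") |>
    mutate(group_pct = round_half_up(100 * .data$group_nisp /
                                       .data$total_nisp, 1)) |>
    select(-"total_nisp")
  taxa <- det |>
    count(site = .data$site, order_group = .data$order_group,
          taxon = .data$morphological_taxon, name = "nisp") |>
    left_join(select(groups, "site", "order_group", "group_nisp"),
              by = c("site", "order_group")) |>
    mutate(pct_within_group = round_half_up(100 * .data$nisp /
                                              .data$group_nisp, 1))
  structure(list(totals = totals, groups = groups, taxa = taxa),
            class = "site_summary")
}

# Round half away from zero (the convention of printed NISP tables), to
# `digits` decimals; base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.site_summary <- function(x, ...) {
  cat("<site_summary>\n")
  print(x$totals)
  invisible(x)
}

#' Percent NISP of a taxon within its order group
#'
#' `100 * taxon NISP / order-group NISP`, rounded half-up to one decimal;
#' whole numbers are returned without a decimal component (e.g. 112 of 509
#' ungulates gives 22).
#'
#' @param summary A [tally_counts()] result.
#' @param taxon Taxon label.
#' @param site Site label (needed when the summary spans several sites).
#' @return Percentage, or `NA` when the group NISP is zero or the taxon is
#'   absent.
#' @export
percent_within_group <- function(summary, taxon, site = NULL) {
  tab <- summary$taxa
  if (!is.null(site)) tab <- filter(tab, .data$site == !!site)
  row <- filter(tab, .data$taxon == !!taxon)
  if (nrow(row) == 0) return(NA_real_)
  row$pct_within_group[1]
}

#' Integrate ZooMS determinations into the morphological NISP table
#'
#' Adds ZooMS screening results (including group-level categories such as
#' "Caprinae/Cervidae") as counts alongside the morphological NISP. Specimens
#' already morphologically determined are never double-counted: a conflicting
#' ZooMS assignment triggers a warning and morphology wins.
#'
#' @param summary A [tally_counts()] result for one site.
#' @param assignments Assignment tibble from [batch_identify()]; the
#'   `sample_id` values are specimen ids of the same site.
#' @param records The bone-record tibble the summary was computed from (used
#'   to detect morphologically determined specimens).
#' @return Tibble: `category`, `nisp_morphology`, `nisp_zooms`,
#'   `nisp_combined`.
#' @export
integrate_zooms_nisp <- function(summary, assignments, records = NULL) {
  morph <- summary$taxa |>
    group_by(category = .data$taxon) |>
    summarise(nisp_morphology = sum(.data$nisp), .groups = "drop")
  zooms <- assignments |> filter(.data$assignment != "undetermined")
  if (!is.null(records)) {
    det_ids <- records$specimen_id[!records$morphological_taxon %in%
                                     c("indeterminate", "unidentified")]
    clash <- zooms$sample_id %in% det_ids
    if (any(clash)) {
      warn(sprintf(
        "%d specimen(s) already morphologically determined; morphology wins.",
        sum(clash)))
      zooms <- zooms[!clash, ]
    }
  }
  zcounts <- zooms |> count(category = .data$assignment, name = "nisp_zooms")
  out <- dplyr::full_join(morph, zcounts, by = "category") |>
    mutate(across(c("nisp_morphology", "nisp_zooms"),
                  ~ tidyr::replace_na(.x, 0L)),
           nisp_combined = .data$nisp_morphology + .data$nisp_zooms) |>
    arrange(.data$category)
  out
}

#' Attach ZooMS screening outcomes to a site summary
#'
#' @param summary A [tally_counts()] result.
#' @param tested Named integer vector (site -> number screened) or tibble
#'   `site`, `tested`, `determined`.
#' @param determined Named integer vector parallel to `tested` (ignored when
#'   `tested` is a tibble).
#' @return The totals tibble with `zooms_tested`, `zooms_determined`,
#'   `zooms_success_pct` columns.
#' @export
add_zooms_success <- function(summary, tested, determined = NULL) {
  if (is.data.frame(tested)) {
    z <- as_tibble(tested)
  } else {
    z <- tibble(site = names(tested), tested = as.integer(tested),
                determined = as.integer(determined[names(tested)]))
  }
  summary$totals |>
    left_join(z, by = "site") |>
    rename(zooms_tested = "tested", zooms_determined = "determined") |>
    mutate(zooms_success_pct = as.integer(round(
      100 * .data$zooms_determined / .data$zooms_tested)))
}
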