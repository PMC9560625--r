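test_that("the five screening criteria gate selection", {
  recs <- dplyr::bind_rows(
    bone_record("ok", size_cm = 3),
    bone_record("small", size_cm = 1.5),
    bone_record("at_cutoff", size_cm = 2),
    bone_record("identified", taxon = "Cervus elaphus", order_group = "Ungulata"),
    bone_record("no_trab", trabeculae = FALSE),
    bone_record("no_pos", in_situ = FALSE),
    bone_record("bad_cortex", cortical = FALSE),
    bone_record("burnt", taphonomy = "combustion"),
    bone_record("crusty", taphonomy = "concretion;manganese"),
    bone_record("ok2", size_cm = 5.5))
  sel <- select_for_zooms(recs)
  expect_identical(sel, c("ok", "ok2"))

  # brute-force enumeration oracle over the same rules
  oracle <- recs$specimen_id[
    recs$morphological_taxon == "unidentified" & recs$size_cm > 2 &
      recs$trabeculae_visible & recs$in_situ_position_known &
      recs$cortical_quality_ok & !nzchar(recs$taphonomy_flags)]
  expect_identical(sel, oracle)

  # moderate-taphonomy tolerance admits singly-flagged bones
  sel2 <- select_for_zooms(recs, max_taphonomy_flags = 1)
  expect_true("burnt" %in% sel2 && !"crusty" %in% sel2)

  # records with missing criterion fields are excluded with a warning
  recs$size_cm[1] <- NA
  expect_warning(sel3 <- select_for_zooms(recs), "missing")
  expect_false("ok" %in% sel3)
  expect_error(select_for_zooms(recs[, 1:3]), class = "zooms_format_error")
})

test_that("determinate fractions match the published site arithmetic", {
  recs <- dplyr::bind_rows(
    site_records("Uluzzo C", 6280,
                 tibble::tibble(taxon = "Various", order_group = "Ungulata",
                                nisp = 612)),
    site_records("Roccia San Sebastiano", 1998,
                 tibble::tibble(taxon = "Various", order_group = "Ungulata",
                                nisp = 515)),
    site_records("Riparo del Broion", 12114,
                 tibble::tibble(taxon = "Various", order_group = "Ungulata",
                                nisp = 174)))
  tot <- tally_counts(recs)$totals
  pct <- setNames(tot$determinate_pct, tot$site)
  expect_equal(pct[["Uluzzo C"]], 9.7)
  expect_equal(pct[["Roccia San Sebastiano"]], 25.8)
  expect_equal(pct[["Riparo del Broion"]], 1.4)
  expect_equal(sum(tot$total_nr), 20392)
})

test_that("%NISP uses the order-group denominator", {
  recs <- dplyr::bind_rows(
    site_records("RSS", 1998, tibble::tibble(
      taxon = c("Cervus elaphus", "Other ungulates", "Canis lupus"),
      order_group = c("Ungulata", "Ungulata", "Carnivora"),
      nisp = c(112, 397, 6))),
    site_records("UC", 6280, tibble::tibble(
      taxon = c("Vulpes vulpes", "Other carnivores", "Ungulate spp."),
      order_group = c("Carnivora", "Carnivora", "Ungulata"),
      nisp = c(44, 11, 557))))
  s <- tally_counts(recs)
  expect_equal(percent_within_group(s, "Cervus elaphus", "RSS"), 22)
  expect_equal(percent_within_group(s, "Vulpes vulpes", "UC"), 80)
  expect_true(is.na(percent_within_group(s, "Absent taxon", "UC")))

  # group percentages sum to ~100 per site and tallies are order-invariant
  sums <- s$groups |> dplyr::group_by(site) |>
    dplyr::summarise(p = sum(group_pct))
  expect_true(all(abs(sums$p - 100) <= 0.2))
  s2 <- tally_counts(recs[sample(nrow(recs)), ])
  expect_equal(dplyr::arrange(s2$taxa, site, taxon),
               dplyr::arrange(s$taxa, site, taxon))

  # conservation: status counts partition the assemblage
  expect_true(all(s$totals$total_nisp + s$totals$indeterminate +
                    s$totals$unidentified == s$totals$total_nr))
})

test_that("ZooMS determinations fold into the NISP table without double counting", {
  recs <- dplyr::bind_rows(
    site_records("S", 60, tibble::tibble(
      taxon = c("Cervus elaphus", "Bos primigenius"),
      order_group = "Ungulata", nisp = c(10, 5)), n_unidentified = 30),
    bone_record("known1", site = "S", taxon = "Cervus elaphus",
                order_group = "Ungulata"))
  recs$specimen_id <- paste0("sp", seq_len(nrow(recs)))
  recs$specimen_id[recs$morphological_taxon == "Cervus elaphus"][1] <- "known1"
  s <- tally_counts(recs)

  none <- integrate_zooms_nisp(s, tibble::tibble(sample_id = character(),
                                                 assignment = character()))
  expect_equal(sum(none$nisp_zooms), 0)
  expect_equal(sum(none$nisp_combined), sum(s$taxa$nisp))

  zo <- tibble::tibble(sample_id = paste0("zs", 1:5),
                       assignment = "Bos/Bison")
  comb <- integrate_zooms_nisp(s, zo, recs)
  expect_equal(comb$nisp_combined[comb$category == "Bos/Bison"], 5)

  # a specimen known morphologically is counted once, with a warning
  clash <- tibble::tibble(sample_id = "known1", assignment = "Bos/Bison")
  expect_warning(comb2 <- integrate_zooms_nisp(s, clash, recs),
                 "morphology wins")
  expect_false("Bos/Bison" %in%
                 comb2$category[comb2$nisp_zooms > 0])
})

test_that("screening success columns join per site", {
  recs <- site_records("A", 100, tibble::tibble(
    taxon = "T", order_group = "Ungulata", nisp = 10))
  s <- tally_counts(recs)
  out <- add_zooms_success(s, tibble::tibble(site = "A", tested = 46,
                                             determined = 21))
  expect_equal(out$zooms_success_pct, 46L)
})
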