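cfg <- preprocess_config()

test_that("Savitzky-Golay smoothing preserves constants and total signal", {
  s <- flat_spectrum(7)
  expect_equal(smooth_spectrum(s, cfg)$intensity, s$intensity, tolerance = 1e-9)

  spike <- gaussian_spectrum(1000, 100, sigma = 0.08, from = 900, to = 1100)
  sm <- smooth_spectrum(spike, cfg)
  expect_lt(max(sm$intensity), max(spike$intensity))
  expect_equal(sum(sm$intensity), sum(spike$intensity), tolerance = 0.01)
})

test_that("fractional smoothing cycles blend the flanking integer passes", {
  # positive background keeps the filter's small undershoot lobes above the
  # zero clamp, so the blend identity holds exactly
  spike <- gaussian_spectrum(c(1000, 1003), c(100, 60), sigma = 0.08,
                             from = 900, to = 1100, background = 10)
  y1 <- smooth_spectrum(spike, preprocess_config(smooth_cycles = 1))$intensity
  y2 <- smooth_spectrum(spike, preprocess_config(smooth_cycles = 2))$intensity
  y15 <- smooth_spectrum(spike, preprocess_config(smooth_cycles = 1.5))$intensity
  expect_equal(y15, (y1 + y2) / 2, tolerance = 1e-9)
  # the blend sits between the one- and two-pass outputs in L2 distance from raw
  d <- function(y) sqrt(sum((y - spike$intensity)^2))
  expect_true(d(y1) <= d(y15) && d(y15) <= d(y2))
})

test_that("smoothing rejects a non-uniform axis", {
  s <- new_spectrum(c(700, 700.5, 702), c(1, 2, 3), mz_range = c(700, 702))
  expect_error(smooth_spectrum(s, cfg), class = "zooms_precondition_error")
})

test_that("baseline correction removes a constant exactly and a ramp well", {
  s <- flat_spectrum(12, from = 700, to = 900)
  out <- correct_baseline(s, cfg)
  expect_true(all(out$intensity == 0))

  ramped <- gaussian_spectrum(800, 50, sigma = 0.08, from = 700, to = 900,
                              background = 5, ramp = 0.05)
  out2 <- correct_baseline(ramped, cfg)
  apex <- max(out2$intensity)
  expect_equal(apex, 50, tolerance = 0.05)
  # offset 0: anchors equal window minima, so a peakless region goes to ~0
  expect_lt(median(out2$intensity), 0.5)

  tiny <- flat_spectrum(1, from = 700, to = 700.5)
  expect_error(correct_baseline(tiny, cfg), class = "zooms_parameter_error")
})

test_that("peak picking applies the S/N gate at the stated threshold", {
  expect_equal(nrow(pick_peaks(flat_spectrum(0, to = 900), cfg)), 0)
  expect_equal(nrow(pick_peaks(flat_spectrum(4, to = 900), cfg)), 0)

  # known noise floor: peak with S/N 3.6 kept, 3.4 dropped
  s <- gaussian_spectrum(c(1000, 1200), c(3.6, 3.4), sigma = 0.08,
                         from = 900, to = 1300)
  pl <- pick_peaks(s, preprocess_config(rel_intensity_threshold = 0),
                   noise = rep(1, nrow(s)))
  expect_equal(nrow(pl), 1)
  expect_equal(pl$mz, 1000, tolerance = 0.02)
  expect_equal(pl$sn, 3.6, tolerance = 1e-6)
})

test_that("centroids recover a known peak position within 0.02 Th", {
  s <- gaussian_spectrum(1105.60, 100, sigma = 0.08, from = 1000, to = 1200)
  pl <- pick_peaks(s, cfg, noise = rep(5, nrow(s)))
  expect_equal(nrow(pl), 1)
  expect_lt(abs(pl$mz - 1105.60), 0.02)
  expect_equal(pl$sn, 20, tolerance = 0.01)
})

test_that("deisotoping collapses envelopes and splits overlapping ones", {
  mk <- function(mz, int) tibble::tibble(sample_id = "x", mz = mz,
                                         intensity = int, sn = 10,
                                         is_monoisotopic = NA)
  one <- deisotope_peaks(mk(1105.6 + 0:2 * 1.00235, c(100, 60, 20)), cfg)
  expect_equal(nrow(one), 1)
  expect_equal(one$mz, 1105.6)
  expect_equal(nrow(one$envelope[[1]]), 3)

  # two envelopes 2.5 Th apart stay separate
  two <- deisotope_peaks(
    mk(c(1105.6, 1106.6, 1108.1, 1109.1), c(100, 60, 80, 40)), cfg)
  expect_equal(nrow(two), 2)
  expect_equal(two$mz, c(1105.6, 1108.1), tolerance = 0.01)

  single <- deisotope_peaks(mk(1300.0, 50), cfg)
  expect_equal(nrow(single), 1)
  expect_equal(nrow(single$envelope[[1]]), 1)

  empty <- deisotope_peaks(mk(numeric(), numeric()), cfg)
  expect_equal(nrow(empty), 0)
})

test_that("deisotoping matches a brute-force clustering oracle", {
  # oracle: exhaustive left-to-right chaining on a sorted vector
  oracle_clusters <- function(mz, int, spacing = 1.00235, tol = 0.05) {
    n <- length(mz)
    used <- rep(FALSE, n)
    res <- list()
    for (i in seq_len(n)) {
      if (used[i]) next
      chain <- i; used[i] <- TRUE
      repeat {
        last <- chain[length(chain)]
        cand <- setdiff(which(!used & abs(mz - (mz[last] + spacing)) <= tol), chain)
        if (length(cand) == 0) break
        nxt <- cand[which.min(abs(mz[cand] - (mz[last] + spacing)))]
        if (length(chain) >= 3 && int[nxt] > int[last]) break
        chain <- c(chain, nxt); used[nxt] <- TRUE
      }
      res[[length(res) + 1]] <- mz[chain[1]]
    }
    sort(unlist(res))
  }
  set.seed(42)
  for (rep in 1:20) {
    base <- sort(runif(sample(3:10, 1), 1000, 1012))
    int <- runif(length(base), 10, 100)
    pl <- tibble::tibble(sample_id = "x", mz = base, intensity = int,
                         sn = 10, is_monoisotopic = NA)
    got <- deisotope_peaks(pl, cfg)
    expect_equal(sort(got$mz), oracle_clusters(base, int))
  }
})

test_that("monoisotopic count never exceeds the input peak count", {
  set.seed(9)
  for (rep in 1:10) {
    mz <- sort(runif(15, 1000, 1020))
    pl <- tibble::tibble(sample_id = "x", mz = mz,
                         intensity = runif(15, 5, 100), sn = 10,
                         is_monoisotopic = NA)
    expect_lte(nrow(deisotope_peaks(pl, cfg)), nrow(pl))
  }
})

test_that("the processing chain is deterministic and recovers true markers", {
  db <- example_marker_db()
  sim <- simulate_spectrum(sim_config(seed = 5, taxon = "Equus ferus",
                                      gln_fraction = 0.7))
  a <- process_spectrum(sim$spectrum)
  b <- process_spectrum(sim$spectrum)
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
  expect_true(all(diff(a$mz) > 0))

  # every true marker peak (all simulated well above S/N 10) is recovered
  # within 0.05 Th
  truth_mz <- c(db$markers$mono_mz[db$markers$taxon == "Equus ferus"],
                1105.6, 1706.7)
  n_hit <- 0; n_tot <- 0
  for (seed in 1:20) {
    sim <- simulate_spectrum(sim_config(seed = seed, taxon = "Equus ferus",
                                        gln_fraction = 0.7))
    pl <- process_spectrum(sim$spectrum)
    for (m in truth_mz) {
      n_tot <- n_tot + 1
      if (any(abs(pl$mz - m) <= 0.05)) n_hit <- n_hit + 1
    }
  }
  expect_gte(n_hit / n_tot, 0.99)
})
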