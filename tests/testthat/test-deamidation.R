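# Independent oracle: isotope distribution by direct enumeration over the
# number of heavy atoms of each element (binomial/multinomial products),
# rather than polynomial convolution.
enumerate_envelope <- function(composition, k = 5) {
  probs <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0001))
  offsets <- list(C = 0:1, H = 0:1, N = 0:1, O = c(0, 1, 2), S = c(0, 1, 2, 4))
  out <- numeric(k)
  per_element <- lapply(names(composition), function(el) {
    n <- composition[[el]]
    p <- probs[[el]]
    off <- offsets[[el]]
    # P(element contributes j extra neutrons), j = 0..k-1
    v <- numeric(k)
    counts_list <- expand.grid(rep(list(0:(k - 1)), length(p) - 1))
    for (r in seq_len(nrow(counts_list))) {
      heavy <- as.numeric(counts_list[r, ])
      if (sum(heavy) > n) next
      j <- sum(heavy * off[-1])
      if (j >= k) next
      v[j + 1] <- v[j + 1] +
        dmultinom(c(n - sum(heavy), heavy), prob = p)
    }
    v
  })
  total <- Reduce(function(a, b) {
    r <- numeric(k)
    for (i in seq_len(k)) for (j in seq_len(k - i + 1)) {
      r[i + j - 1] <- r[i + j - 1] + a[i] * b[j]
    }
    r
  }, per_element)
  total / sum(total)
}

test_that("theoretical envelopes are normalised and match direct enumeration", {
  for (m in c(800, 1104.6, 1705.7, 2500, 3400)) {
    env <- theoretical_envelope(m)
    expect_equal(sum(env), 1, tolerance = 1e-9)
    expect_true(all(env >= 0))
  }
  comp <- c(C = 49, H = 77, N = 13, O = 15)
  expect_equal(theoretical_envelope(composition = comp),
               enumerate_envelope(comp), tolerance = 1e-6)
  comp2 <- c(C = 20, H = 30, N = 6, O = 8, S = 1)
  expect_equal(theoretical_envelope(composition = comp2),
               enumerate_envelope(comp2), tolerance = 1e-6)
})

test_that("heavier peptides have relatively larger heavy-isotope peaks", {
  light <- theoretical_envelope(1104.6)
  heavy <- theoretical_envelope(1705.7)
  expect_gt(heavy[2] / heavy[1], light[2] / light[1])

  # doubling the composition never moves the envelope mode leftward
  for (m in seq(700, 3300, by = 650)) {
    comp <- averagine_composition(m)
    m1 <- which.max(theoretical_envelope(composition = comp))
    m2 <- which.max(theoretical_envelope(composition = comp * 2L, k = 8))
    expect_gte(m2, m1)
  }
  expect_error(theoretical_envelope(100), class = "zooms_parameter_error")
})

test_that("the deamidation shift equals +0.98402 Da from atomic masses", {
  expect_equal(round(deamidation_mass_shift(), 5), 0.98402)
})

test_that("pure components are recovered exactly", {
  p <- default_targets()[[1]]
  f1 <- fit_gln_fraction(mixture_peaks(p, 1), p)
  expect_equal(f1$gln_fraction, 1, tolerance = 1e-6)
  f0 <- fit_gln_fraction(mixture_peaks(p, 0), p)
  expect_equal(f0$gln_fraction, 0, tolerance = 1e-6)
  expect_true(f1$usable)
  # fully deamidated: no native monoisotopic peak, so the S/N gate trips
  expect_false(f0$usable)
})

test_that("a 50/50 noiseless mixture matches the grid-search oracle", {
  for (p in default_targets()) {
    y <- mixture_peaks(p, 0.5)
    fit <- fit_gln_fraction(y, p)
    expect_equal(fit$gln_fraction, 0.5, tolerance = 0.01)
    oracle <- grid_search_alpha(
      zoomscreen:::extract_positions(y, p$mono_mz + (0:p$k) * 1.00235, 0.1),
      p$envelope)
    expect_equal(fit$gln_fraction, oracle, tolerance = 0.001)
  }
})

test_that("alpha recovery is scale-invariant and bounded", {
  p <- default_targets()[[2]]
  y <- mixture_peaks(p, 0.37)
  f1 <- fit_gln_fraction(y, p)
  y$intensity <- y$intensity * 1234.5
  f2 <- fit_gln_fraction(y, p)
  expect_equal(f1$gln_fraction, f2$gln_fraction, tolerance = 1e-12)
  expect_true(f1$gln_fraction >= 0 && f1$gln_fraction <= 1)
})

test_that("noisy mixtures are recovered with small error and bias", {
  p <- default_targets()[[1]]
  for (alpha in c(0.2, 0.5, 0.8)) {
    est <- numeric(40)
    set.seed(100 + round(100 * alpha))
    for (i in seq_along(est)) {
      y <- mixture_peaks(p, alpha, noise_sd = 0.02)
      est[i] <- fit_gln_fraction(y, p)$gln_fraction
    }
    expect_lte(mean(abs(est - alpha)), 0.05)
    expect_lte(abs(mean(est) - alpha), 0.02)
  }
})

test_that("absent or weak signal is flagged unusable", {
  p <- default_targets()[[1]]
  empty <- tibble::tibble(sample_id = "e", mz = 900, intensity = 10, sn = 20,
                          is_monoisotopic = TRUE)
  f <- fit_gln_fraction(empty, p)
  expect_false(f$usable)
  expect_true(is.na(f$gln_fraction))

  weak <- mixture_peaks(p, 0.5, sn = 2)
  expect_false(fit_gln_fraction(weak, p)$usable)
})

test_that("tidy and glance expose the fit fields", {
  p <- default_targets()[[1]]
  f <- fit_gln_fraction(mixture_peaks(p, 0.5), p)
  td <- generics::tidy(f)
  expect_named(td, c("sample_id", "peptide", "gln_fraction", "fit_rss",
                     "usable"))
  expect_equal(nrow(td), 1)
  gl <- generics::glance(f)
  expect_equal(gl$n_positions, 6)
})

test_that("site aggregation computes n, mean, median and 2 SE", {
  res <- tibble::tibble(
    sample_id = c("a", "b", "c"), peptide = "P1105",
    gln_fraction = c(0.3, 0.5, 0.4), fit_rss = 0, usable = TRUE)
  st <- aggregate_site_stats(res[1:2, ], c("S1", "S1"))
  expect_equal(st$mean, 0.4)
  expect_equal(st$median, 0.4)
  expect_equal(st$two_se, 2 * sd(c(0.3, 0.5)) / sqrt(2))

  one <- aggregate_site_stats(res[3, ], "S2")
  expect_equal(one$mean, 0.4)
  expect_equal(one$two_se, 0)

  # permutation invariance
  perm <- aggregate_site_stats(res[c(2, 3, 1), ], c("S1", "S1", "S1"))
  ref <- aggregate_site_stats(res, c("S1", "S1", "S1"))
  expect_equal(perm, ref)

  # a group with zero usable results is omitted with a warning
  res$usable[1] <- FALSE
  expect_warning(
    st2 <- aggregate_site_stats(res, c("S1", "S2", "S2")),
    "no usable")
  expect_equal(st2$site, "S2")
  expect_equal(st2$n, 2)
})
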