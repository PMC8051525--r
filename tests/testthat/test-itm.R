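test_that("ramp input reproduces the hand-computed kappa exactly", {
  # unit-step ramp, lag 2 samples at 250 Hz = 8 ms: |dV| = 2 everywhere
  ks <- kappa_series(as.numeric(1:500), delay = 2, fs = 250)
  expect_equal(ks$n_valid, 498)
  expect_true(all(abs(ks$values - log(2) / log(8)) < 1e-12))
  expect_equal(mean_kappa(ks), log(2) / log(8), tolerance = 1e-12)
})

test_that("constant signals have no valid timepoints and an NA mean", {
  ks <- kappa_series(rep(5, 100), delay = 3, fs = 250)
  expect_equal(ks$n_valid, 0)
  expect_equal(ks$n_total, 97)
  expect_warning(m <- mean_kappa(ks), "undefined")
  expect_true(is.na(m))
})

test_that("kappa matches the brute-force loop oracle on i.i.d. noise", {
  set.seed(101)
  x <- rnorm(400)
  for (d in c(1L, 5L)) {
    ks <- kappa_series(x, delay = d, fs = 250)
    o <- naive_mean_kappa(x, d, 250)
    expect_equal(mean_kappa(ks), o$mean, tolerance = 1e-13)
    expect_equal(ks$n_valid, o$n_valid)
  }
})

test_that("kappa is invariant to the logarithm base", {
  set.seed(5)
  x <- cumsum(rnorm(300))
  d <- 4L; fs <- 250
  ks <- kappa_series(x, d, fs)
  dv <- abs(x[(d + 1):300] - x[1:(300 - d)])
  manual10 <- log10(dv[dv != 0]) / log10(1000 * d / fs)
  expect_equal(ks$values, manual10, tolerance = 1e-13)
})

test_that("a lag of exactly 1 ms is rejected (log 0 denominator)", {
  expect_error(kappa_series(rnorm(100), delay = 1, fs = 1000), "1 ms")
})

test_that("identical leads give kappa_itcr exactly 1; known ramps give 2", {
  x <- cumsum(rnorm(500))
  ks <- kappa_itcr_series(x, x, delay = 3)
  expect_true(all(ks$values == 1))
  expect_equal(mean_kappa(ks), 1.0)
  # source step 4 uV, dest step 2 uV: ln4/ln2 = 2 at every timepoint
  ks2 <- kappa_itcr_series(as.numeric(1:100) * 4, as.numeric(1:100) * 2, delay = 1)
  expect_true(all(abs(ks2$values - 2) < 1e-12))
})

test_that("kappa_itcr matches the naive oracle with the same exclusions", {
  set.seed(77)
  src <- round(cumsum(rnorm(300)), 1)   # rounding forces some |dV| = 0 and = 1
  dst <- round(cumsum(rnorm(300)), 0)
  ks <- kappa_itcr_series(src, dst, delay = 2)
  o <- naive_mean_itcr(src, dst, 2)
  expect_equal(mean_kappa(ks), o$mean, tolerance = 1e-13)
  expect_equal(ks$n_valid, o$n_valid)
  expect_equal(ks$n_total - ks$n_valid, o$excluded)
  expect_gt(o$excluded, 0)              # the guard actually triggered
})

test_that("scaling changes within-lead kappa but not the identity ratio", {
  set.seed(8)
  x <- cumsum(rnorm(400))
  k1 <- mean_kappa(kappa_series(x, 2, 250))
  k2 <- mean_kappa(kappa_series(10 * x, 2, 250))
  expect_gt(abs(k1 - k2), 1e-3)
  expect_equal(mean_kappa(kappa_itcr_series(10 * x, 10 * x, 2)), 1.0)
})

test_that("mean_kappa is the sum over valid points divided by n_valid", {
  ks <- structure(list(values = c(0.2, 0.4), n_total = 10L, n_valid = 2L,
                       delay = 1L, delay_ms = 4),
                  class = "kappa_series")
  expect_equal(mean_kappa(ks), 0.3)
})

test_that("itm_features enumerates L*D within and L*(L-1)*D between features", {
  set.seed(12)
  ep <- eeg_record(matrix(rnorm(10 * 1200), 10), fs = 250)
  tb <- itm_features(ep)
  expect_equal(sum(tb$kind == "within"), 50)
  expect_equal(sum(tb$kind == "between"), 450)
  expect_equal(nrow(tb), 500)
  expect_true(all(grepl("^itm_w_\\d+_\\d+$", tb$feature[tb$kind == "within"])))
  expect_true("itm_w_1_4" %in% tb$feature)        # lag 1 sample = 4 ms
  expect_true("itm_b_1_2_4000" %in% tb$feature)   # lag 1000 samples = 4 s
  expect_false(anyDuplicated(tb$feature) > 0)
  # ordered pairs: both directions present and not reciprocal in general
  ab <- tb$value[tb$feature == "itm_b_1_2_4"]
  ba <- tb$value[tb$feature == "itm_b_2_1_4"]
  expect_length(ab, 1); expect_length(ba, 1)
  expect_gt(abs(ab * ba - 1), 1e-6)
})

test_that("itm_features agrees with the single-series operations", {
  set.seed(13)
  ep <- eeg_record(matrix(rnorm(3 * 800), 3), fs = 250,
                   lead_labels = c("3", "56", "9"))
  tb <- itm_features(ep, within_delays = c(2L, 8L), between_delays = c(5L, 20L))
  w <- tb[tb$feature == "itm_w_56_8", ]
  expect_equal(w$value, mean_kappa(kappa_series(ep$samples["56", ], 2L, 250)))
  b <- tb[tb$feature == "itm_b_9_3_80", ]
  expect_equal(b$value,
               mean_kappa(kappa_itcr_series(ep$samples["9", ], ep$samples["3", ], 20L)))
})

test_that("a single lead yields an empty between map", {
  ep <- eeg_record(matrix(rnorm(600), 1), fs = 250)
  tb <- itm_features(ep, within_delays = c(1L, 2L), between_delays = c(1L, 2L))
  expect_equal(sum(tb$kind == "between"), 0)
  expect_equal(nrow(tb), 2)
})

test_that("delay grids validate and default as documented", {
  expect_equal(itm_within_grid(), c(1L, 2L, 4L, 8L, 16L))
  expect_equal(itm_between_grid(), c(1L, 6L, 32L, 178L, 1000L))
  expect_error(itm_features(eeg_record(matrix(rnorm(20), 1), fs = 250),
                            within_delays = c(2L, 1L)), "increasing")
  expect_error(kappa_series(rnorm(10), delay = 10, fs = 250), "smaller than")
})
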