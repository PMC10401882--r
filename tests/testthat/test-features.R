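test_that("ALFF matches constructed spectra and a direct FFT oracle", {
  tr <- 2
  nt <- 200L
  tt <- seq_len(nt) * tr
  # 0.05 Hz falls exactly on bin 20 of a 200-point, TR 2 s series; the
  # raw spectrum puts the full amplitude in that single bin (detrending,
  # the default for real drifting data, would redistribute ~1%)
  a <- 3.2
  x <- a * sin(2 * pi * 0.05 * tt)
  expect_equal(compute_alff(matrix(x, 1), tr, detrend = FALSE)[1], a, tolerance = 1e-6)

  # constant series: DC excluded even with band starting at 0
  expect_equal(compute_alff(matrix(5, 1, nt), tr, band = c(0, 0.1))[1], 0)

  # out-of-band sinusoid on an exact bin contributes nothing
  x_out <- sin(2 * pi * 0.2 * tt) # bin 80
  expect_lt(compute_alff(matrix(x_out, 1), tr, detrend = FALSE)[1], 1e-6)

  # arbitrary noisy series against the independent single-series oracle
  withr::with_seed(9L, {
    y <- rnorm(nt) + 0.5 * tt / nt
    expect_equal(compute_alff(matrix(y, 1), tr)[1],
      brute_alff(y, tr, c(0.01, 0.1)),
      tolerance = 1e-10
    )
  })

  expect_error(compute_alff(matrix(x, 1), tr, band = c(0.01, 0.3)), "Nyquist")
})

test_that("ALFF is absolutely homogeneous and additive over disjoint bands", {
  # t chosen so 0.05 Hz is an exact bin and the two bands partition the
  # full band's bin set
  withr::with_seed(10L, {
    ts <- array(rnorm(3 * 3 * 3 * 100), dim = c(3, 3, 3, 100))
  })
  tr <- 2
  a1 <- compute_alff(ts, tr)
  expect_equal(compute_alff(3.7 * ts, tr), 3.7 * a1, tolerance = 1e-9)
  expect_equal(compute_alff(-3.7 * ts, tr), 3.7 * a1, tolerance = 1e-9)

  # bin assignment: closed intervals; the upper band starts half a bin
  # above the shared 0.05 Hz edge, so every bin lands in exactly one band
  df <- 1 / (100 * tr)
  lo <- compute_alff(ts, tr, band = c(0.01, 0.05))
  hi <- compute_alff(ts, tr, band = c(0.05 + df / 2, 0.1))
  expect_equal(lo + hi, compute_alff(ts, tr, band = c(0.01, 0.1)), tolerance = 1e-10)
})

test_that("Kendall's W matches brute-force evaluation and its invariants", {
  # identical series, no ties: perfect concordance
  x <- matrix(rep(c(3, 1, 4, 1.5, 5, 9, 2.6), 4), nrow = 4, byrow = TRUE)
  expect_equal(kendall_w(x), 1)

  # printed 3-series, 3-timepoint example: ranks (1,2,3),(1,2,3),(3,2,1)
  ex <- rbind(c(1, 2, 3), c(10, 20, 30), c(9, 5, 1))
  expect_equal(kendall_w(ex), brute_w(ex))
  expect_equal(kendall_w(ex), 1 / 9) # rank sums (5,6,7) by hand

  # ties handled with mid-ranks and the corrected denominator
  withr::with_seed(2L, {
    tied <- matrix(sample(1:4, 5 * 8, replace = TRUE), 5, 8)
    expect_equal(kendall_w(tied), brute_w(tied))
  })

  # invariant under strictly monotone transforms of each series
  withr::with_seed(3L, {
    z <- matrix(rnorm(6 * 30), 6, 30)
    expect_equal(kendall_w(exp(z)), kendall_w(z), tolerance = 1e-12)
  })

  # bounded in [0, 1] over random inputs
  withr::with_seed(4L, {
    for (i in 1:20) {
      w <- kendall_w(matrix(rnorm(4 * 10), 4, 10))
      expect_gte(w, 0)
      expect_lte(w, 1)
    }
  })
})

test_that("null mean of W over independent series matches a simulation oracle", {
  # 27 independent white-noise series, t = 200: compare the mean W across
  # voxels to the Monte-Carlo null mean of W for K = 27
  withr::with_seed(5L, {
    ts <- array(rnorm(5 * 5 * 5 * 200), dim = c(5, 5, 5, 200))
    rh <- compute_reho(ts, neighborhood = 27L)
    interior <- rh[2:4, 2:4, 2:4] # full 27-neighborhoods only
    null_w <- replicate(200, kendall_w(matrix(rnorm(27 * 200), 27, 200)))
    mc_se <- sd(null_w) / sqrt(length(null_w))
    expect_lt(abs(mean(interior) - mean(null_w)), mean(null_w) * 0.25 + 6 * mc_se)
  })
})

test_that("ReHo is 1 for identical series and validates its inputs", {
  base <- sin(seq_len(64))
  ts <- array(rep(base, each = 27), dim = c(3, 3, 3, 64))
  rh <- compute_reho(ts, neighborhood = 27L)
  expect_true(all(abs(rh - 1) < 1e-12))
  expect_error(compute_reho(array(0, c(2, 3, 3, 64))), ">= 3")
  expect_error(compute_reho(ts, neighborhood = 10L), "7, 19 or 27")

  # isolated in-mask voxel gets W = 0 with a message
  mask <- array(0, c(3, 3, 3))
  mask[1, 1, 1] <- 1
  expect_message(rh0 <- compute_reho(ts, mask = mask), "isolated")
  expect_equal(rh0[1, 1, 1], 0)
})

test_that("Gaussian smoothing matches the closed-form kernel and preserves constants", {
  g <- array(0, c(15, 15, 15))
  g[8, 8, 8] <- 1
  fwhm <- 6
  vox <- 2
  sm <- smooth_gaussian(g, fwhm, vox)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox # in voxels
  half <- ceiling(4 * sigma) # implementation truncates at 4 sigma
  k1 <- exp(-seq(-half, half)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k_full <- numeric(15)
  k_full[8 + seq(-half, half)] <- k1
  expected <- outer(outer(k_full, k_full), k_full)
  expect_equal(as.numeric(sm), as.numeric(expected), tolerance = 1e-6)

  const <- array(4.2, c(8, 8, 8))
  expect_equal(smooth_gaussian(const, 6, 3, mask = array(1, c(8, 8, 8))),
    const,
    tolerance = 1e-10
  )
  # fwhm -> 0 limit is the identity
  withr::with_seed(6L, {
    m <- array(rnorm(27), c(3, 3, 3))
    expect_identical(smooth_gaussian(m, 0, 3), m)
  })
  expect_error(smooth_gaussian(const, 6, 0), "positive")
})

test_that("the pipeline applies the modality-specific smoothing order", {
  # ALFF with fwhm -> 0 equals plain ALFF
  withr::with_seed(7L, {
    ts <- array(rnorm(4 * 4 * 4 * 64), dim = c(4, 4, 4, 64))
  })
  expect_equal(
    feature_pipeline(ts, "ALFF", tr = 2, fwhm_mm = 0),
    compute_alff(ts, tr = 2)
  )

  # ReHo order matters: smoothing before vs after differ on two-blob input
  two_blob <- array(0, c(5, 5, 5, 64))
  s1 <- sin(2 * pi * 0.05 * seq_len(64) * 2)
  s2 <- cos(2 * pi * 0.08 * seq_len(64) * 2)
  withr::with_seed(8L, {
    for (i in 1:5) {
      for (j in 1:5) {
        for (k in 1:5) {
          two_blob[i, j, k, ] <- (if (i <= 2) s1 else s2) + rnorm(64, 0, 0.3)
        }
      }
    }
  })
  after <- feature_pipeline(two_blob, "ReHo", fwhm_mm = 6, voxel_size_mm = 3)
  sm_first <- two_blob
  for (f in 1:64) sm_first[, , , f] <- smooth_gaussian(two_blob[, , , f], 6, 3)
  before <- compute_reho(sm_first)
  expect_gt(max(abs(after - before)), 0.01)

  # per-site ALFF ordering follows injected in-band amplitude ordering
  sim <- simulate_timeseries(c(3, 3, 3), 64,
    tr = 2,
    sites = tibble::tibble(
      site = c("lo", "mid", "hi"), n_subjects = c(2L, 2L, 2L),
      amp_scale = c(0.5, 1, 2)
    ),
    noise_sd = 0.05, seed = 4L
  )
  mean_alff <- sapply(sim$volumes, function(v) mean(compute_alff(v, tr = 2)))
  site_means <- tapply(mean_alff, sim$covariates$site, mean)
  expect_true(site_means["lo"] < site_means["mid"] &&
    site_means["mid"] < site_means["hi"])
})
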