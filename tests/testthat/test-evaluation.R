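test_that("partial F matches brute-force RSS evaluation on small designs", {
  withr::with_seed(61L, {
    for (i in 1:8) {
      n <- sample(8:12, 1)
      q <- sample(1:3, 1)
      X_red <- cbind(1, matrix(rnorm(n * q), n))
      X_full <- cbind(X_red, rnorm(n))
      y <- rnorm(n)
      mine <- harmodp:::partial_f(cbind(y), X_red, X_full)
      ref <- brute_partial_f(y, X_red, X_full)
      expect_equal(unname(mine$F[1]), ref$F, tolerance = 1e-9)
      expect_equal(unname(mine$p[1]), ref$p, tolerance = 1e-9)
    }
  })
})

test_that("site F equals the squared two-sample t on one balanced feature", {
  withr::with_seed(62L, {
    n <- 40L
    cov <- tibble::tibble(
      subject_id = as.character(1:n),
      site = factor(rep(c("A", "B"), each = n / 2)),
      diagnosis = rbinom(n, 1, 0.5), sex = rbinom(n, 1, 0.5),
      age = rnorm(n, 15, 5)
    )
    y <- rnorm(n) + as.numeric(cov$site == "B")
  })
  res <- site_effect_test(cbind(y, y), cov, covariates = character(0))
  tt <- t.test(y[cov$site == "A"], y[cov$site == "B"], var.equal = TRUE)
  expect_equal(res$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("null data give nominal raw rejection rates and Bonferroni behaves", {
  spec <- small_spec(n_per_site = 30L, n_sites = 3L, n_features = 500L, seed = 63L)
  sim <- simulate_features(spec)
  res <- site_effect_test(sim$features, sim$covariates)
  rate <- mean(res$p_value < 0.05)
  # binomial 99.7% CI half-width at 0.05 over 500 features ~ 0.03
  expect_lt(abs(rate - 0.05), 0.035)
  # Bonferroni: adjusted p = min(1, m p) exactly
  expect_equal(res$p_fwe, pmin(1, nrow(res) * res$p_value))
  expect_true(all(res$p_fwe >= res$p_value))
})

test_that("features carrying true site effects are detected", {
  nf <- 200L
  gamma <- matrix(0, 2, nf)
  gamma[2, seq_len(nf / 2)] <- 1.5
  spec <- synth_spec(
    n_sites = 2, subjects_per_site = c(60, 60), n_features = nf,
    site_additive = gamma, noise_sd = 0.3, seed = 64L
  )
  sim <- simulate_features(spec)
  res <- site_effect_test(sim$features, sim$covariates)
  affected <- seq_len(nf / 2)
  expect_gte(mean(res$significant[affected]), 0.95)
  expect_lte(mean(res$significant[-affected]), 0.05)
})

test_that("signal association tests report correct signs and respect permuted nulls", {
  nf <- 60L
  beta <- matrix(0, 3, nf, dimnames = list(c("diagnosis", "sex", "age"), NULL))
  beta["age", 1:20] <- -0.5
  beta["age", 21:40] <- 0.5
  spec <- synth_spec(
    n_sites = 2, subjects_per_site = c(60, 60), n_features = nf,
    signal_effects = beta, noise_sd = 0.5, seed = 65L
  )
  sim <- simulate_features(spec)
  res <- signal_association_test(sim$features, sim$covariates, "age",
    covariates = "sex"
  )
  expect_true(all(res$significant[1:40]))
  expect_true(all(res$direction[1:20] == "negative"))
  expect_true(all(res$direction[21:40] == "positive"))

  # flipping the age sign flips every direction
  cov_flip <- sim$covariates
  cov_flip$age <- -cov_flip$age
  res_flip <- signal_association_test(sim$features, cov_flip, "age",
    covariates = "sex"
  )
  expect_true(all(res_flip$direction[1:40] != res$direction[1:40]))

  # permuted labels: significant fraction near alpha, averaged over
  # permutations (features share structure, so a single permutation is
  # all-or-nothing; the null property is marginal over permutations)
  rates <- withr::with_seed(66L, {
    sapply(1:40, function(i) {
      cov_perm <- sim$covariates
      cov_perm$age <- sample(cov_perm$age)
      mean(signal_association_test(sim$features, cov_perm, "age",
        covariates = "sex"
      )$p_value < 0.05)
    })
  })
  expect_lt(abs(mean(rates) - 0.05), 0.06)

  # a factor duplicated as covariate is rejected
  expect_error(
    signal_association_test(sim$features, sim$covariates, "age",
      covariates = c("age", "sex")
    ),
    "both"
  )
})

test_that("hc_only restricts the age analysis to healthy controls", {
  spec <- small_spec(n_per_site = 40L, n_features = 10L, seed = 67L)
  sim <- simulate_features(spec)
  res <- signal_association_test(sim$features, sim$covariates, "age",
    covariates = "sex", hc_only = TRUE
  )
  n_hc <- sum(sim$covariates$diagnosis == 0)
  expect_equal(res$df2[1], n_hc - 3L)
})

test_that("permutation FWE agrees in spirit with Bonferroni on strong effects", {
  nf <- 40L
  gamma <- matrix(0, 2, nf)
  gamma[2, 1:10] <- 2
  spec <- synth_spec(
    n_sites = 2, subjects_per_site = c(30, 30), n_features = nf,
    site_additive = gamma, noise_sd = 0.5, seed = 68L
  )
  sim <- simulate_features(spec)
  res_b <- site_effect_test(sim$features, sim$covariates)
  res_p <- site_effect_test(sim$features, sim$covariates,
    fwe = "permutation", n_perm = 200L, seed = 1L
  )
  expect_true(all(res_p$significant[1:10]))
  expect_equal(res_b$significant[1:10], res_p$significant[1:10])
})

test_that("parcellation and median summaries behave on degenerate cases", {
  expect_error(make_parcellation(10, 20), "exceed")
  parc <- make_parcellation(10, 2)
  expect_equal(parc, rep(1:2, each = 5))

  cov <- tiny_cov(n_per_site = 5L, seed = 69L)
  # constant per subject: summary equals that constant exactly
  Y <- matrix(rep(seq_len(10), 8), 10, 8)
  mr <- median_roi_correlation(Y, make_parcellation(8, 4), cov)
  expect_equal(mr$summary$value, as.numeric(1:10))

  # single ROI equals the plain per-subject median
  withr::with_seed(70L, {
    Y2 <- matrix(rnorm(10 * 9), 10, 9)
  })
  one_roi <- median_roi_correlation(Y2, rep(1L, 9), cov)
  expect_equal(one_roi$summary$value, apply(Y2, 1, median))
  pooled <- median_roi_correlation(Y2, make_parcellation(9, 3), cov,
    summary_method = "pooled"
  )
  expect_equal(pooled$summary$value, apply(Y2, 1, median))
})

test_that("embeddings separate constructed site clusters and DP removes them", {
  withr::with_seed(71L, {
    n <- 90L
    site <- factor(rep(c("A", "B"), length.out = n))
    offset <- ifelse(site == "A", -8, 8)
    Y <- matrix(rnorm(n * 20), n, 20) + offset
    cov <- tibble::tibble(
      subject_id = as.character(1:n), site = site,
      diagnosis = rbinom(n, 1, 0.5), sex = rbinom(n, 1, 0.5),
      age = rnorm(n, 15, 5)
    )
  })
  emb <- embed_and_score(Y, cov, seed = 1L, perplexity = 10)
  expect_gte(emb$silhouette[["site"]], 0.5)

  # removing the site course kills the clustering
  site_course <- as.numeric(site == "B") - 0.5
  Yd <- dp_denoise(Y, cbind(site_course))
  emb_d <- embed_and_score(Yd, cov, seed = 1L, perplexity = 10)
  expect_lte(emb_d$silhouette[["site"]], 0.1)

  # silhouette is invariant under a relabeling permutation
  cov_relab <- cov
  cov_relab$site <- factor(ifelse(cov$site == "A", "Z", "Q"))
  emb_r <- embed_and_score(Y, cov_relab, seed = 1L, perplexity = 10)
  expect_equal(emb_r$silhouette[["site"]], emb$silhouette[["site"]])

  expect_error(
    embed_and_score(matrix(1, 40, 5), cov[1:40, ], perplexity = 5),
    "identical"
  )
})
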