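test_that("an empty removal basis is the identity", {
  withr::with_seed(51L, {
    Y <- matrix(rnorm(20 * 10), 20, 10)
  })
  none <- matrix(0, 20, 0)
  expect_equal(unclass(sp_denoise(Y, none)), Y, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(sp_denoise(Y, none, intercept = FALSE)), Y,
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("a rank-one matrix is annihilated by projecting on its own course", {
  withr::with_seed(52L, {
    a <- rnorm(30)
    s <- rnorm(40)
  })
  Y <- outer(a, s)
  out <- sp_denoise(Y, cbind(a), intercept = FALSE)
  expect_lt(max(abs(unclass(out))), 1e-8)
})

test_that("duplicated courses give the same projection (pseudo-inverse contract)", {
  withr::with_seed(53L, {
    Y <- matrix(rnorm(25 * 12), 25, 12)
    a <- rnorm(25)
  })
  one <- sp_denoise(Y, cbind(a))
  two <- sp_denoise(Y, cbind(a, a))
  expect_equal(unclass(one), unclass(two), tolerance = 1e-8)
})

test_that("residuals are orthogonal to the projection basis", {
  withr::with_seed(54L, {
    Y <- matrix(rnorm(50 * 30), 50, 30)
    B <- matrix(rnorm(50 * 4), 50, 4)
  })
  out <- unclass(sp_denoise(Y, B))
  # correlation with any basis course bounded by the projection contract
  cors <- abs(cor(out, B))
  expect_lt(max(cors), 1e-6)
})

test_that("purge_signal removes exactly the signal span", {
  cov <- tiny_cov(n_per_site = 20L, seed = 55L)
  X <- build_design(cov, c("diagnosis", "sex", "age"))
  # course equal to the age column: purged to (numerically) nothing
  out <- purge_signal(cbind(cov$age), X)
  expect_lt(max(abs(out)), 1e-10)
  # course orthogonal to the design: a fixed point
  withr::with_seed(56L, {
    z <- rnorm(nrow(cov))
  })
  z_orth <- z - X %*% (oracle_pinv(X) %*% z)
  expect_equal(purge_signal(cbind(z_orth), X), cbind(z_orth), tolerance = 1e-10)
  # zero mixed courses: valid empty result
  empty <- purge_signal(matrix(0, nrow(cov), 0), X)
  expect_equal(ncol(empty), 0L)
})

test_that("a site+age mixture purges to its site part", {
  withr::with_seed(57L, {
    n <- 200L
    site_course <- rep(c(-1, 1), each = n / 2)
    age <- rnorm(n, 15, 5)
    cov <- tibble::tibble(
      subject_id = as.character(1:n),
      site = factor(rep(c("A", "B"), each = n / 2)),
      diagnosis = rbinom(n, 1, 0.5), sex = rbinom(n, 1, 0.5), age = age
    )
  })
  X <- build_design(cov, c("diagnosis", "sex", "age"))
  mixed <- site_course + 0.5 * scale(cov$age)[, 1]
  purged <- purge_signal(cbind(mixed), X)
  expect_gt(abs(cor(purged[, 1], site_course)), 0.9)
  expect_lt(abs(cor(purged[, 1], cov$age)), 1e-6)
})

test_that("dual projection is idempotent and nests the single projection", {
  withr::with_seed(58L, {
    Y <- matrix(rnorm(60 * 25), 60, 25)
    A_sites <- matrix(rnorm(60 * 3), 60, 3)
    A_mixed <- matrix(rnorm(60 * 2), 60, 2)
    cov <- tiny_cov(n_per_site = 30L, seed = 58L)
  })
  X <- build_design(cov, c("diagnosis", "sex", "age"))
  proj <- projection_set(A_sites, A_mixed, X)

  # orthogonality invariant of the purged courses
  prime_n <- apply(proj$A_sites_prime, 2, function(v) v / sqrt(sum(v^2)))
  Xn <- apply(X, 2, function(v) v / sqrt(sum(v^2)))
  expect_lt(max(abs(crossprod(prime_n, Xn))), 1e-8)

  once <- dp_denoise(Y, proj)
  twice <- dp_denoise(once, proj)
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-10)

  # nesting: per-feature residual variance after DP <= after SP
  sp_out <- unclass(sp_denoise(Y, A_sites))
  dp_out <- unclass(once)
  v_sp <- apply(sp_out, 2, var)
  v_dp <- apply(dp_out, 2, var)
  expect_true(all(v_dp <= v_sp + 1e-12))

  # with no mixed components DP reduces exactly to SP
  proj_nomix <- projection_set(A_sites, matrix(0, 60, 0), X)
  expect_identical(
    unclass(dp_denoise(Y, proj_nomix)),
    unclass(sp_denoise(Y, A_sites))
  )
})

test_that("harmonize warns when site and signal variables are nearly collinear", {
  withr::with_seed(59L, {
    n <- 60L
    cov <- tibble::tibble(
      subject_id = as.character(1:n),
      site = factor(rep(c("A", "B"), each = n / 2)),
      diagnosis = rbinom(n, 1, 0.5),
      sex = rbinom(n, 1, 0.5),
      # age almost perfectly determined by site
      age = c(rnorm(n / 2, 10, 0.1), rnorm(n / 2, 40, 0.1))
    )
    Y <- matrix(rnorm(n * 30), n, 30)
  })
  expect_warning(
    harmonize(Y, cov, method = "combat"),
    "confounded"
  )
})

test_that("signal carried orthogonally to site courses survives dual projection", {
  # age effect lives on courses orthogonal to the site structure: DP must
  # preserve (or improve) the feature-age correlations relative to raw data
  medians <- replicate(10, NULL, simplify = FALSE)
  cors <- sapply(1:10, function(s) {
    spec <- abide_like_spec(s, n_features = 120L, confound_strength = 0.5)
    sim <- simulate_features(spec, seed = s)
    h <- suppressWarnings(harmonize(sim$features, sim$covariates,
      method = "ica-dp", n_components = 15L, seed = s
    ))
    aff <- which(sim$truth$beta["age", ] != 0)
    raw_r <- median(abs(cor(unclass(sim$features)[, aff], sim$covariates$age)))
    dp_r <- median(abs(cor(unclass(h$harmonized)[, aff], sim$covariates$age)))
    dp_r - raw_r
  })
  expect_gte(median(cors), 0)
})
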