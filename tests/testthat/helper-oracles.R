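# Shared fixtures and independent oracles used across the suite.

# Small covariate table: 2 sites, balanced, no confounding.
tiny_cov <- function(n_per_site = 10L, n_sites = 2L, seed = 1L) {
  withr::with_seed(seed, {
    n <- n_per_site * n_sites
    tibble::tibble(
      subject_id = sprintf("s%03d", seq_len(n)),
      site = factor(rep(paste0("site", seq_len(n_sites)), each = n_per_site)),
      diagnosis = rbinom(n, 1, 0.5),
      sex = rbinom(n, 1, 0.5),
      age = rnorm(n, 15, 5)
    )
  })
}

# Brute-force Kendall's W from explicit rank sums (independent of
# kendall_w's vectorized path).
brute_w <- function(X) {
  K <- nrow(X)
  t_len <- ncol(X)
  ranks <- t(apply(X, 1L, rank))
  Rj <- colSums(ranks)
  TT <- 0
  for (i in seq_len(K)) {
    for (tau in table(X[i, ])) TT <- TT + tau^3 - tau
  }
  12 * sum((Rj - mean(Rj))^2) / (K^2 * (t_len^3 - t_len) - K * TT)
}

# Brute-force partial F from explicit residual sums of squares via lm.
brute_partial_f <- function(y, X_red, X_full) {
  rss <- function(X) sum(residuals(lm.fit(X, y))^2)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- length(y) - ncol(X_full)
  F <- ((rss(X_red) - rss(X_full)) / df1) / (rss(X_full) / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Direct FFT amplitude-sum oracle for ALFF on a single series.
brute_alff <- function(x, tr, band) {
  nt <- length(x)
  tt <- seq_len(nt)
  fit <- lm.fit(cbind(1, tt), x)
  x <- residuals(fit)
  F <- fft(x)
  freqs <- (seq_len(nt) - 1L) / (nt * tr)
  keep <- freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12 &
    seq_len(nt) >= 2L & seq_len(nt) <= floor(nt / 2) + 1L
  sum(2 * Mod(F[keep]) / nt)
}

# Match rows of S_est to rows of S_true by greedy maximal |correlation|
# assignment (quotients out permutation and sign).
match_abs_cor <- function(S_est, S_true) {
  cc <- abs(cor(t(S_est), t(S_true)))
  k <- nrow(cc)
  out <- numeric(k)
  for (i in seq_len(k)) {
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    out[i] <- cc[best[1], best[2]]
    cc[best[1], ] <- -1
    cc[, best[2]] <- -1
  }
  out
}

# Plain SVD pseudo-inverse, independent of the package's internals.
oracle_pinv <- function(X) {
  s <- svd(X)
  s$v %*% ((1 / s$d) * t(s$u))
}

# A small multi-site spec with explicit effect matrices for truth tests.
small_spec <- function(n_per_site = 20L, n_sites = 3L, n_features = 40L,
                       gamma_scale = 0, delta = 1, noise_sd = 1,
                       beta = NULL, seed = 1L) {
  gamma <- withr::with_seed(seed + 500L, {
    matrix(rnorm(n_sites * n_features, 0, gamma_scale), n_sites, n_features)
  })
  if (is.null(beta)) {
    beta <- matrix(0, 3, n_features,
      dimnames = list(c("diagnosis", "sex", "age"), NULL)
    )
  }
  synth_spec(
    n_sites = n_sites,
    subjects_per_site = rep(n_per_site, n_sites),
    n_features = n_features,
    signal_effects = beta,
    site_additive = gamma,
    site_multiplicative = matrix(delta, n_sites, n_features),
    noise_sd = noise_sd,
    seed = seed
  )
}
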