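#' Specify a synthetic multi-site dataset
#'
#' A `synth_spec` fixes every parameter of the generative model
#' `Y[i,v] = alpha[v] + X[i,] %*% beta[,v] + gamma[site(i),v] +
#' delta[site(i),v] * eps[i,v]`, the additive/multiplicative site-effect
#' model that both ComBat and the projection denoisers target. Covariates
#' (diagnosis, sex, age) are drawn per site from site-specific
#' distributions interpolated toward the pooled distribution by
#' `1 - confound_strength`, so `confound_strength = 0` gives
#' site-independent covariates and values near 1 reproduce the strong
#' site-covariate confounding seen in real multi-site cohorts.
#'
#' @param n_sites Number of sites.
#' @param subjects_per_site Integer vector of per-site subject counts.
#' @param n_features Number of features (voxels).
#' @param alpha Per-feature baseline (length `n_features`).
#' @param signal_effects Numeric matrix of effects, rows named
#'   `diagnosis`, `sex`, `age`, columns = features.
#' @param site_additive `n_sites x n_features` additive site offsets
#'   (gamma).
#' @param site_multiplicative `n_sites x n_features` positive
#'   multiplicative site factors (delta).
#' @param noise_sd Residual standard deviation (> 0).
#' @param confound_strength Site-covariate association strength in
#'   `[0, 1)`.
#' @param site_age_mean,site_age_sd,site_p_male,site_p_asd Per-site
#'   covariate distribution parameters (length `n_sites`); defaults give
#'   identical distributions at every site.
#' @param site_names Optional site labels.
#' @param seed Integer seed used by [simulate_features()].
#'
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_sites, subjects_per_site, n_features,
                       alpha = rep(0, n_features),
                       signal_effects = matrix(0, 3, n_features,
                         dimnames = list(c("diagnosis", "sex", "age"), NULL)
                       ),
                       site_additive = matrix(0, n_sites, n_features),
                       site_multiplicative = matrix(1, n_sites, n_features),
                       noise_sd = 1,
                       confound_strength = 0,
                       site_age_mean = rep(15, n_sites),
                       site_age_sd = rep(6, n_sites),
                       site_p_male = rep(0.5, n_sites),
                       site_p_asd = rep(0.5, n_sites),
                       site_names = paste0("site_", seq_len(n_sites)),
                       seed = 1L) {
  subjects_per_site <- as.integer(subjects_per_site)
  if (length(subjects_per_site) != n_sites) {
    abort("subjects_per_site must have one entry per site.")
  }
  if (sum(subjects_per_site) < 4L) abort("Need at least 4 subjects in total.")
  if (!identical(dim(site_additive), c(as.integer(n_sites), as.integer(n_features))) &&
      !identical(dim(site_additive), c(n_sites, n_features))) {
    if (!all(dim(site_additive) == c(n_sites, n_features))) {
      abort("site_additive must be n_sites x n_features.")
    }
  }
  if (!all(dim(site_multiplicative) == c(n_sites, n_features))) {
    abort("site_multiplicative must be n_sites x n_features.")
  }
  if (any(site_multiplicative <= 0)) abort("site_multiplicative must be positive everywhere.")
  if (noise_sd <= 0) abort("noise_sd must be positive.")
  if (confound_strength < 0 || confound_strength >= 1) {
    abort("confound_strength must lie in [0, 1).")
  }
  if (length(alpha) != n_features) abort("alpha must have length n_features.")
  if (!all(rownames(signal_effects) == c("diagnosis", "sex", "age")) ||
      ncol(signal_effects) != n_features) {
    abort("signal_effects must be a 3 x n_features matrix with rows diagnosis, sex, age.")
  }
  structure(list(
    n_sites = as.integer(n_sites),
    subjects_per_site = subjects_per_site,
    n_features = as.integer(n_features),
    alpha = as.numeric(alpha),
    signal_effects = signal_effects,
    site_additive = site_additive,
    site_multiplicative = site_multiplicative,
    noise_sd = noise_sd,
    confound_strength = confound_strength,
    site_age_mean = site_age_mean,
    site_age_sd = site_age_sd,
    site_p_male = site_p_male,
    site_p_asd = site_p_asd,
    site_names = site_names,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> %d sites, %d subjects, %d features, confound_strength %.2f, seed %d\n",
    x$n_sites, sum(x$subjects_per_site), x$n_features, x$confound_strength, x$seed
  ))
  invisible(x)
}

# Truncated-normal draw via inverse CDF (lower truncation only);
# deterministic given the RNG state.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  plo <- pnorm(lower, mean, sd)
  u <- runif(n, plo, 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

#' Multi-site spec calibrated to the 16-site autism cohort
#'
#' Builds a [synth_spec()] emulating the packaged cohort demographics
#' ([abide_demographics()]): 16 sites with the real per-site subject
#' counts (795 in total), per-site age distributions Normal(mean, sd)
#' truncated at 5 years, and per-site sex/diagnosis proportions from the
#' observed counts — reproducing the cohort's strong site-age/sex/
#' diagnosis confounding. Site effects and signal effects are drawn once
#' from `base_seed`: each site gets a global amplitude shift plus
#' feature-wise additive offsets and a mild multiplicative factor; age
#' carries a negative effect over a contiguous half of the features, and
#' sex/diagnosis carry smaller effects on 10% blobs.
#'
#' @param base_seed Integer seed fixing the realized effect maps (and the
#'   default simulation seed).
#' @param n_features Number of features (default 500).
#' @param confound_strength Site-covariate association (default 0.9,
#'   near-cohort-level confounding).
#' @param noise_sd Residual sd (default 1).
#' @param site_sd Site effect scale: both the sd of the per-site global
#'   shift and of the feature-wise offsets (default 0.5).
#' @param beta_age Age effect per year on the affected features
#'   (default -0.03).
#' @return A [synth_spec()].
#' @export
abide_like_spec <- function(base_seed = 1L, n_features = 500L,
                            confound_strength = 0.9, noise_sd = 1,
                            site_sd = 0.5, beta_age = -0.03) {
  demo <- abide_demographics()
  n_sites <- nrow(demo)
  n_per_site <- demo$n_asd + demo$n_hc
  nf <- as.integer(n_features)
  with_seed(derive_seed(base_seed, 101L), {
    alpha <- rnorm(nf, mean = 10, sd = 2)
    g_global <- rnorm(n_sites, 0, site_sd)
    gamma <- matrix(rnorm(n_sites * nf, 0, site_sd), n_sites, nf) + g_global
    delta <- matrix(exp(rnorm(n_sites * nf, 0, 0.1)), n_sites, nf)
  })
  beta <- matrix(0, 3, nf, dimnames = list(c("diagnosis", "sex", "age"), NULL))
  # age: contiguous blob over the first half; sex/diagnosis: 10% blobs.
  beta["age", seq_len(floor(nf / 2))] <- beta_age
  sex_blob <- seq.int(floor(nf * 0.55) + 1L, floor(nf * 0.65))
  dx_blob <- seq.int(floor(nf * 0.70) + 1L, floor(nf * 0.80))
  beta["sex", sex_blob] <- 0.15
  beta["diagnosis", dx_blob] <- -0.15
  synth_spec(
    n_sites = n_sites,
    subjects_per_site = n_per_site,
    n_features = nf,
    alpha = alpha,
    signal_effects = beta,
    site_additive = gamma,
    site_multiplicative = delta,
    noise_sd = noise_sd,
    confound_strength = confound_strength,
    site_age_mean = demo$age_mean,
    site_age_sd = demo$age_sd,
    site_p_male = demo$n_male / n_per_site,
    site_p_asd = demo$n_asd / n_per_site,
    site_names = demo$site,
    seed = as.integer(base_seed)
  )
}

#' Generate a multi-site feature matrix with known ground truth
#'
#' Draws covariates, then `Y = alpha + X beta + gamma[site,] +
#' delta[site,] * eps` with `eps` iid standard normal scaled by
#' `noise_sd`. Fully reproducible from the seed.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A list with elements `features` (a [feature_matrix()]),
#'   `covariates` (tibble) and `truth` (a `synthetic_truth` list holding
#'   the realized `alpha`, `beta`, `gamma`, `delta`, the covariates and
#'   boolean feature masks `signal_features` / `site_features`).
#' @export
simulate_features <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- sum(spec$subjects_per_site)
  nf <- spec$n_features
  cs <- spec$confound_strength
  # pooled covariate parameters (subject-weighted)
  w <- spec$subjects_per_site / n
  pool_age_mean <- sum(w * spec$site_age_mean)
  pool_age_sd <- sqrt(sum(w * (spec$site_age_sd^2 +
    (spec$site_age_mean - pool_age_mean)^2)))
  pool_p_male <- sum(w * spec$site_p_male)
  pool_p_asd <- sum(w * spec$site_p_asd)
  site_f <- factor(rep(spec$site_names, spec$subjects_per_site),
    levels = spec$site_names
  )
  cov <- with_seed(derive_seed(seed, 1L), {
    age <- sex <- dx <- numeric(n)
    for (s in seq_len(spec$n_sites)) {
      i <- which(as.integer(site_f) == s)
      m <- (1 - cs) * pool_age_mean + cs * spec$site_age_mean[s]
      sdev <- (1 - cs) * pool_age_sd + cs * spec$site_age_sd[s]
      age[i] <- rtruncnorm_lower(length(i), m, sdev, lower = 5)
      sex[i] <- rbinom(length(i), 1L, (1 - cs) * pool_p_male + cs * spec$site_p_male[s])
      dx[i] <- rbinom(length(i), 1L, (1 - cs) * pool_p_asd + cs * spec$site_p_asd[s])
    }
    tibble::tibble(
      subject_id = sprintf("sub_%04d", seq_len(n)),
      site = site_f, diagnosis = dx, sex = sex, age = age
    )
  })
  X <- cbind(diagnosis = cov$diagnosis, sex = cov$sex, age = cov$age)
  eps <- with_seed(
    derive_seed(seed, 2L),
    matrix(rnorm(n * nf, 0, spec$noise_sd), n, nf)
  )
  site_idx <- as.integer(cov$site)
  Y <- matrix(spec$alpha, n, nf, byrow = TRUE) +
    X %*% spec$signal_effects +
    spec$site_additive[site_idx, , drop = FALSE] +
    spec$site_multiplicative[site_idx, , drop = FALSE] * eps
  fm <- feature_matrix(Y, subject_ids = cov$subject_id, modality = "synthetic")
  truth <- structure(list(
    alpha = spec$alpha,
    beta = spec$signal_effects,
    gamma = spec$site_additive,
    delta = spec$site_multiplicative,
    covariates = cov,
    signal_features = colSums(abs(spec$signal_effects)) > 0,
    site_features = apply(spec$site_additive, 2, function(g) any(g != 0)) |
      apply(spec$site_multiplicative, 2, function(d) any(d != 1))
  ), class = "synthetic_truth")
  list(features = fm, covariates = cov, truth = truth)
}

#' Generate small multi-site 4-D time series with known spectra
#'
#' Each voxel's series is a sum of sinusoids at the stated frequencies
#' and amplitudes plus white noise; the site modulates the sinusoid
#' amplitude through `amp_scale`. Deterministic components depend only on
#' the spec, noise only on the seed. Intended as a ground-truth fixture
#' for the ALFF/ReHo feature extractors.
#'
#' @param grid Integer 3-vector of spatial dimensions (each >= 3).
#' @param n_timepoints Number of timepoints (>= 64).
#' @param tr Repetition time in seconds.
#' @param sites Tibble/data frame with columns `site`, `n_subjects`,
#'   `amp_scale`.
#' @param freqs,amplitudes Sinusoid frequencies (Hz) and base amplitudes.
#' @param noise_sd White-noise sd added to every voxel series.
#' @param seed Integer seed.
#' @return List with `volumes` (list of 4-D arrays, one per subject),
#'   `covariates` (tibble with site labels and placeholder signal
#'   covariates), and `tr`.
#' @export
simulate_timeseries <- function(grid, n_timepoints, tr,
                                sites = tibble::tibble(
                                  site = c("A", "B"), n_subjects = c(2L, 2L),
                                  amp_scale = c(1, 1.5)
                                ),
                                freqs = 0.05, amplitudes = 1,
                                noise_sd = 0.1, seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 3L)) {
    abort("grid must be a 3-vector with every dimension >= 3 (27-voxel neighborhoods).")
  }
  if (n_timepoints < 64L) abort("n_timepoints must be at least 64.")
  if (length(freqs) != length(amplitudes)) {
    abort("freqs and amplitudes must have equal length.")
  }
  tp <- seq_len(n_timepoints) * tr
  base <- rowSums(vapply(
    seq_along(freqs),
    function(j) amplitudes[j] * sin(2 * pi * freqs[j] * tp),
    numeric(n_timepoints)
  ))
  n <- sum(sites$n_subjects)
  site_f <- factor(rep(sites$site, sites$n_subjects), levels = sites$site)
  nvox <- prod(grid)
  volumes <- with_seed(derive_seed(seed, 3L), {
    lapply(seq_len(n), function(i) {
      scale_i <- sites$amp_scale[as.integer(site_f)[i]]
      noise <- matrix(rnorm(nvox * n_timepoints, 0, noise_sd), nvox, n_timepoints)
      arr <- array(0, dim = c(grid, n_timepoints))
      arr[] <- t(matrix(scale_i * base, n_timepoints, nvox) + t(noise))
      arr
    })
  })
  cov <- tibble::tibble(
    subject_id = sprintf("sub_%03d", seq_len(n)),
    site = site_f,
    diagnosis = rep_len(c(0, 1), n),
    sex = rep_len(c(0, 1), n),
    age = seq(10, 30, length.out = n)
  )
  list(volumes = volumes, covariates = cov, tr = tr)
}
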