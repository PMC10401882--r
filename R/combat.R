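#' Fit the empirical-Bayes ComBat site-effect model
#'
#' Per feature, fits `Y = alpha + X_signal beta + gamma_site +
#' delta_site * eps` by least squares with the weighted
#' site-sum-to-zero constraint (`sum_s n_s gamma_s = 0`), standardizes
#' residual data by the pooled variance, and shrinks the naive per-site
#' location/scale estimates with a parametric empirical-Bayes step:
#' normal prior for the additive effects, inverse-gamma for the
#' multiplicative ones, hyperparameters by method of moments across
#' features, iterated to convergence.
#'
#' @param Y A [feature_matrix()] or numeric matrix (subjects x features).
#' @param site Factor (or coercible) of site labels, one per subject;
#'   every level needs at least 2 subjects.
#' @param X_signal Signal design matrix from [build_design()] (an
#'   all-ones intercept column, if present, is absorbed into the
#'   standardization mean as in the reference formulation).
#' @param eb_tol Relative-change convergence tolerance of the EB
#'   iteration (default 1e-8).
#' @param eb_max_iter Maximum EB iterations per site (default 500).
#' @return A `combat_model` list with `alpha`, `beta_signal`,
#'   `gamma_hat`/`delta_hat`, `gamma_star`/`delta_star`, `prior_params`,
#'   `pooled_variance` and the fit bookkeeping.
#' @export
combat_fit <- function(Y, site, X_signal = NULL, eb_tol = 1e-8, eb_max_iter = 500L) {
  Ym <- fm_values(as_feature_values(Y))
  n <- nrow(Ym)
  site <- factor(site)
  if (length(site) != n) abort("site must have one label per subject.")
  nb <- nlevels(site)
  if (nb < 2L) abort("ComBat needs at least 2 sites; nothing to harmonize with one.")
  n_batches <- as.numeric(table(site))
  if (any(n_batches < 2L)) {
    abort(sprintf(
      "Every site needs >= 2 subjects (site variance undefined otherwise): %s.",
      paste(levels(site)[n_batches < 2L], collapse = ", ")
    ))
  }
  batchmod <- stats::model.matrix(~ 0 + site)
  colnames(batchmod) <- levels(site)
  mod <- NULL
  if (!is.null(X_signal)) {
    mod <- as.matrix(X_signal)
    ones <- apply(mod, 2L, function(x) all(x == 1))
    mod <- mod[, !ones, drop = FALSE]
    if (ncol(mod) == 0L) mod <- NULL
  }
  design <- cbind(batchmod, mod)
  if (matrix_rank(design) < ncol(design)) {
    abort(sprintf(
      "Confounded design: site indicators and signal covariates are collinear (%s).",
      paste(dependent_columns(design), collapse = ", ")
    ))
  }
  dat <- t(Ym) # features x subjects, reference orientation
  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(n_batches / n, B_hat[seq_len(nb), , drop = FALSE])
  var_pooled <- as.numeric(((dat - t(design %*% B_hat))^2) %*% rep(1 / n, n))
  if (any(var_pooled <= 0)) {
    abort("Zero pooled variance for at least one feature; cannot standardize.")
  }
  stand_mean <- t(grand_mean)[, rep(1L, n), drop = FALSE]
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)
  gamma_hat <- solve(crossprod(batchmod), t(batchmod) %*% t(s_data))
  delta_hat <- t(vapply(
    levels(site),
    function(l) apply(s_data[, site == l, drop = FALSE], 1L, var),
    numeric(nrow(s_data))
  ))
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, var)
  a_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2
  })
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iters <- integer(nb)
  for (b in seq_len(nb)) {
    sdat <- s_data[, site == levels(site)[b], drop = FALSE]
    nbk <- ncol(sdat)
    g_old <- gamma_hat[b, ]
    d_old <- delta_hat[b, ]
    count <- 0L
    repeat {
      count <- count + 1L
      g_new <- (t2[b] * nbk * gamma_hat[b, ] + d_old * gamma_bar[b]) /
        (t2[b] * nbk + d_old)
      sum2 <- rowSums((sdat - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (nbk / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old), abs(d_new - d_old) / abs(d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < eb_tol || count >= eb_max_iter) break
    }
    gamma_star[b, ] <- g_old
    delta_star[b, ] <- d_old
    iters[b] <- count
  }
  beta_signal <- if (!is.null(mod)) {
    B_hat[seq.int(nb + 1L, nrow(B_hat)), , drop = FALSE]
  } else {
    NULL
  }
  structure(list(
    alpha = as.numeric(grand_mean),
    beta_signal = beta_signal,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    prior_params = list(
      gamma_bar = gamma_bar, t2 = t2,
      a_prior = a_prior, b_prior = b_prior
    ),
    pooled_variance = var_pooled,
    site_levels = levels(site),
    n_per_site = stats::setNames(n_batches, levels(site)),
    signal_columns = if (!is.null(mod)) colnames(mod) else character(),
    eb_iterations = iters
  ), class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf(
    "<combat_model> %d sites x %d features; signal covariates: %s\n",
    length(x$site_levels), length(x$alpha),
    if (length(x$signal_columns)) paste(x$signal_columns, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' Standardizes the data with the fitted mean and pooled variance,
#' subtracts the shrunk additive site effects, divides by the square root
#' of the shrunk multiplicative effects, then restores the intercept and
#' signal-covariate effects.
#'
#' @param Y Data to harmonize (same features as the fit).
#' @param model A [combat_fit()] result.
#' @param site Site labels for the rows of `Y`; must be levels seen at
#'   fit time.
#' @param X_signal Signal design for the rows of `Y` (same columns as at
#'   fit time).
#' @return A [feature_matrix()] of the same dimensions as `Y`.
#' @export
combat_apply <- function(Y, model, site, X_signal = NULL) {
  stopifnot(inherits(model, "combat_model"))
  fm <- as_feature_values(Y)
  Ym <- fm_values(fm)
  n <- nrow(Ym)
  site <- as.character(site)
  unseen <- setdiff(unique(site), model$site_levels)
  if (length(unseen)) {
    abort(sprintf("Unseen site label(s): %s.", paste(unseen, collapse = ", ")))
  }
  b_idx <- match(site, model$site_levels)
  stand_mean <- matrix(model$alpha, n, length(model$alpha), byrow = TRUE)
  if (length(model$signal_columns)) {
    if (is.null(X_signal)) abort("X_signal required: the model was fitted with signal covariates.")
    mod <- as.matrix(X_signal)
    ones <- apply(mod, 2L, function(x) all(x == 1))
    mod <- mod[, !ones, drop = FALSE]
    if (!identical(colnames(mod), model$signal_columns)) {
      abort("X_signal columns do not match the fitted model.")
    }
    stand_mean <- stand_mean + mod %*% model$beta_signal
  }
  sd_pooled <- matrix(sqrt(model$pooled_variance), n, length(model$alpha), byrow = TRUE)
  z <- (Ym - stand_mean) / sd_pooled
  z <- (z - model$gamma_star[b_idx, , drop = FALSE]) /
    sqrt(model$delta_star[b_idx, , drop = FALSE])
  fm_like(z * sd_pooled + stand_mean, fm)
}
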