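#' Single-projection denoising: regress pure site components out
#'
#' Removes the least-squares projection of the data onto the pure
#' site-related mixing courses: `Y - B pinv(B) Y` with `B = A_Sites`. By
#' default the projection basis is augmented with the all-ones column and
#' the per-feature means are re-added afterwards, so the harmonized data
#' keeps its original grand mean (comparable to the ComBat restore step);
#' `intercept = FALSE` reproduces the literal projection equation.
#'
#' @param Y A [feature_matrix()] or numeric matrix (subjects x features).
#' @param A_sites Matrix of pure-noise mixing courses (subjects x k);
#'   0 columns is valid (identity under the default intercept handling).
#' @param intercept Augment the basis with an intercept and restore the
#'   feature means (default `TRUE`).
#' @return A harmonized [feature_matrix()].
#' @export
sp_denoise <- function(Y, A_sites, intercept = TRUE) {
  fm <- as_feature_values(Y)
  Ym <- fm_values(fm)
  A_sites <- as.matrix(A_sites)
  if (length(A_sites) && nrow(A_sites) != nrow(Ym)) {
    abort("A_sites rows must align with the subjects of Y.")
  }
  fm_like(project_residual(Ym, A_sites, intercept), fm)
}

project_residual <- function(Ym, basis, intercept) {
  n <- nrow(Ym)
  if (intercept) {
    B <- cbind(rep(1, n), basis)
    mu <- colMeans(Ym)
    Ym - project_onto(Ym, B) + matrix(mu, n, ncol(Ym), byrow = TRUE)
  } else {
    if (is.null(basis) || ncol(as.matrix(basis)) == 0L) {
      return(Ym)
    }
    Ym - project_onto(Ym, as.matrix(basis))
  }
}

#' Purge signal variance from mixed components
#'
#' Replaces each mixed mixing course by its residual after least-squares
#' regression on the signal design: `A' = A_Mixed - X pinv(X) A_Mixed`.
#' The result carries only the site-related part of each mixed component
#' and is orthogonal to every signal-design column.
#'
#' @param A_mixed Matrix of mixed mixing courses (subjects x m); 0
#'   columns is valid and yields an empty result.
#' @param var_signal Signal design matrix (subjects x q), full rank; an
#'   intercept column is included automatically if absent so course means
#'   do not leak into the purged residuals.
#' @return Matrix of signal-purged courses, same shape as `A_mixed`.
#' @export
purge_signal <- function(A_mixed, var_signal) {
  A_mixed <- as.matrix(A_mixed)
  if (ncol(A_mixed) == 0L) {
    return(A_mixed)
  }
  X <- as.matrix(var_signal)
  if (nrow(X) != nrow(A_mixed)) abort("var_signal rows must align with A_mixed.")
  if (!any(apply(X, 2L, function(x) all(x == x[1L]) && x[1L] != 0))) {
    X <- cbind(1, X)
  }
  if (matrix_rank(X) < ncol(X)) abort("var_signal must be full rank.")
  A_mixed - project_onto(A_mixed, X)
}

#' Bundle the dual-projection removal basis
#'
#' Builds `A'_Sites` by purging the signal design from the mixed courses
#' ([purge_signal()]) and stores the combined removal basis
#' `[A_Sites, A'_Sites]` used by [dp_denoise()].
#'
#' @param A_sites Pure-noise mixing courses (subjects x k).
#' @param A_mixed Mixed mixing courses (subjects x m).
#' @param var_signal Signal design matrix.
#' @return A `projection_set` list: `A_sites`, `A_mixed`,
#'   `A_sites_prime`, `basis`.
#' @export
projection_set <- function(A_sites, A_mixed, var_signal) {
  A_sites <- as.matrix(A_sites)
  A_mixed <- as.matrix(A_mixed)
  A_prime <- purge_signal(A_mixed, var_signal)
  structure(list(
    A_sites = A_sites, A_mixed = A_mixed,
    A_sites_prime = A_prime,
    basis = cbind(A_sites, A_prime)
  ), class = "projection_set")
}

#' Dual-projection denoising: regress site and purged-mixed components out
#'
#' Removes the projection of the data onto the combined basis
#' `[A_Sites, A'_Sites]` — the pure site courses plus the site-related
#' part of the mixed courses. With no mixed components this reduces
#' exactly to [sp_denoise()]. Intercept handling as in [sp_denoise()].
#'
#' @param Y A [feature_matrix()] or numeric matrix.
#' @param proj A [projection_set()] built from the same ICA run, or a
#'   plain basis matrix.
#' @param intercept See [sp_denoise()].
#' @return A harmonized [feature_matrix()].
#' @export
dp_denoise <- function(Y, proj, intercept = TRUE) {
  basis <- if (inherits(proj, "projection_set")) proj$basis else as.matrix(proj)
  fm <- as_feature_values(Y)
  Ym <- fm_values(fm)
  if (length(basis) && nrow(basis) != nrow(Ym)) {
    abort("Projection basis rows must align with the subjects of Y.")
  }
  fm_like(project_residual(Ym, basis, intercept), fm)
}

#' Harmonize a multi-site feature matrix
#'
#' One-call interface to the three denoisers. For the ICA methods it runs
#' the spatial ICA, classifies the components against site and signal
#' variables, and removes the pure-noise courses (`"ica-sp"`) or the
#' pure-noise plus signal-purged mixed courses (`"ica-dp"`). For
#' `"combat"` it fits and applies the empirical-Bayes location/scale
#' model. When the site labels are nearly collinear with the signal
#' design (first canonical correlation above `confound_warn`), a warning
#' is issued: effects shared between site and signal cannot be separated
#' by any of the methods.
#'
#' @param Y A [feature_matrix()] or numeric matrix (subjects x features).
#' @param cov Covariate tibble aligned with the rows of `Y`.
#' @param method `"ica-dp"`, `"ica-sp"` or `"combat"`.
#' @param signal_vars Signal variable names (default diagnosis, age, sex).
#' @param n_components ICA model order (ICA methods).
#' @param seed Integer seed for the ICA initialization.
#' @param alpha Family-wise level for component classification.
#' @param intercept Intercept handling of the projections (see
#'   [sp_denoise()]).
#' @param confound_warn Canonical-correlation threshold for the
#'   site/signal confounding warning (default 0.95).
#' @param ... Further arguments passed to [run_ica()] or [combat_fit()].
#' @return A `harmonization_result` list: `harmonized` (a
#'   [feature_matrix()]), `method`, and the fitted `model` (plus
#'   `labels` and `projection` for the ICA methods).
#' @export
harmonize <- function(Y, cov, method = c("ica-dp", "ica-sp", "combat"),
                      signal_vars = c("diagnosis", "age", "sex"),
                      n_components = 20L, seed = 1L, alpha = 0.05,
                      intercept = TRUE, confound_warn = 0.95, ...) {
  method <- match.arg(method)
  fm <- as_feature_values(Y)
  if (nrow(cov) != nrow(fm)) abort("Covariates must align with the rows of Y.")
  X_signal <- build_design(cov, signal_vars, include_intercept = TRUE)
  check_confounding(cov$site, X_signal, confound_warn)
  if (method == "combat") {
    model <- combat_fit(fm, cov$site, X_signal, ...)
    out <- combat_apply(fm, model, cov$site, X_signal)
    return(structure(list(harmonized = out, method = method, model = model),
      class = "harmonization_result"
    ))
  }
  model <- run_ica(fm, n_components = n_components, seed = seed, ...)
  labels <- classify_components(model, cov, signal_vars = signal_vars, alpha = alpha)
  A_sites <- select_courses(model, labels, "noise")
  if (method == "ica-sp") {
    out <- sp_denoise(fm, A_sites, intercept = intercept)
    proj <- NULL
  } else {
    A_mixed <- select_courses(model, labels, "mixed")
    proj <- projection_set(A_sites, A_mixed, X_signal)
    out <- dp_denoise(fm, proj, intercept = intercept)
  }
  structure(list(
    harmonized = out, method = method, model = model,
    labels = labels, projection = proj
  ), class = "harmonization_result")
}

# First canonical correlation between site indicators and the signal
# design; a value near 1 means site and signal effects are inseparable.
check_confounding <- function(site, X_signal, threshold = 0.95) {
  site <- factor(site)
  D <- stats::model.matrix(~ 0 + site)
  D <- sweep(D, 2L, colMeans(D))
  X <- as.matrix(X_signal)
  X <- X[, apply(X, 2L, function(x) !all(x == x[1L])), drop = FALSE]
  if (ncol(X) == 0L) return(invisible(0))
  X <- sweep(X, 2L, colMeans(X))
  cc <- tryCatch(stats::cancor(D, X)$cor[1L], error = function(e) NA_real_)
  if (isTRUE(cc > threshold)) {
    warn(sprintf(
      "Site labels and signal covariates are strongly confounded (canonical correlation %.3f); effects shared between them cannot be removed or preserved reliably.",
      cc
    ))
  }
  invisible(cc)
}

#' @export
print.harmonization_result <- function(x, ...) {
  cat(sprintf("<harmonization_result> method %s: %d subjects x %d features\n",
              x$method, nrow(x$harmonized), ncol(x$harmonized)))
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels$label,
      levels = c("signal", "noise", "mixed", "unclassified")))
    cat("  components:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
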