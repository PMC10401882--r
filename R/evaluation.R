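#' @keywords internal
# Vectorized per-feature partial F-test: full model [reduced | tested]
# vs reduced, via extra sum of squares. Returns F, dfs, p per feature.
partial_f <- function(Ym, X_reduced, X_full) {
  n <- nrow(Ym)
  q_full <- qr(X_full)
  q_red <- qr(X_reduced)
  if (q_full$rank < ncol(X_full)) {
    abort(sprintf(
      "Rank-deficient test design; confounded columns: %s.",
      paste(dependent_columns(X_full), collapse = ", ")
    ))
  }
  rss_full <- colSums(qr.resid(q_full, Ym)^2)
  rss_red <- colSums(qr.resid(q_red, Ym)^2)
  df1 <- ncol(X_full) - ncol(X_reduced)
  df2 <- n - ncol(X_full)
  F <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

finalize_mass_univariate <- function(stats_list, factor_name, covariates, alpha,
                                     fwe, direction = NULL) {
  m <- length(stats_list$F)
  p_fwe <- pmin(1, m * stats_list$p)
  out <- tibble::tibble(
    feature = seq_len(m),
    statistic = unname(stats_list$F),
    df1 = stats_list$df1,
    df2 = stats_list$df2,
    p_value = unname(stats_list$p),
    p_fwe = p_fwe,
    significant = p_fwe < alpha
  )
  if (!is.null(direction)) out$direction <- direction
  attr(out, "factor") <- factor_name
  attr(out, "covariates") <- covariates
  attr(out, "alpha") <- alpha
  attr(out, "fwe") <- fwe
  attr(out, "n_significant") <- sum(out$significant)
  class(out) <- c("mass_univariate_result", class(out))
  out
}

#' Voxelwise test for residual site effects
#'
#' Per feature, the partial F-test of the site factor in a linear model
#' adjusting for the signal covariates (one-way ANOVA on site, GLM
#' implementation), with family-wise error control across features.
#'
#' @param Y A [feature_matrix()] or numeric matrix.
#' @param cov Covariate tibble aligned with `Y`.
#' @param covariates Adjustment covariates (default diagnosis, age, sex).
#' @param alpha Family-wise significance level.
#' @param fwe `"bonferroni"` (adjusted p = min(1, m p)) or
#'   `"permutation"` (max-F null distribution over label permutations).
#' @param n_perm Number of permutations for `fwe = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return A `mass_univariate_result` tibble: per-feature `statistic`,
#'   `df1`, `df2`, `p_value`, `p_fwe`, `significant`.
#' @export
site_effect_test <- function(Y, cov, covariates = c("diagnosis", "age", "sex"),
                             alpha = 0.05, fwe = c("bonferroni", "permutation"),
                             n_perm = 1000L, seed = 1L) {
  fwe <- match.arg(fwe)
  Ym <- fm_values(as_feature_values(Y))
  if (nrow(cov) != nrow(Ym)) abort("Covariates must align with the rows of Y.")
  X_red <- build_design(cov, covariates, include_intercept = TRUE)
  site <- factor(cov$site)
  D <- stats::model.matrix(~site)[, -1L, drop = FALSE]
  X_full <- cbind(X_red, D)
  res <- partial_f(Ym, X_red, X_full)
  out <- finalize_mass_univariate(res, "site", covariates, alpha, fwe)
  if (fwe == "permutation") {
    out <- permutation_fwe(out, Ym, X_red, function(perm) {
      cbind(X_red, D[perm, , drop = FALSE])
    }, n_perm, seed, alpha)
  }
  out
}

#' Voxelwise test for a signal variable's association
#'
#' Per feature, the partial F-test of one signal variable (diagnosis, sex
#' or age — continuous age enters as a linear term with 1 numerator df)
#' adjusting for the requested covariates, with the association direction
#' taken from the coefficient sign so positive/negative effect maps can
#' be reported.
#'
#' @param Y A [feature_matrix()] or numeric matrix.
#' @param cov Covariate tibble aligned with `Y`.
#' @param factor_var The tested variable: `"age"`, `"sex"` or
#'   `"diagnosis"`.
#' @param covariates Adjustment covariates.
#' @param hc_only Restrict the analysis to healthy controls
#'   (`diagnosis == 0`), as appropriate for age effects.
#' @param alpha,fwe,n_perm,seed See [site_effect_test()].
#' @return A `mass_univariate_result` tibble with a `direction` column
#'   (`"positive"`/`"negative"`).
#' @export
signal_association_test <- function(Y, cov, factor_var = c("age", "sex", "diagnosis"),
                                    covariates = NULL, hc_only = FALSE,
                                    alpha = 0.05,
                                    fwe = c("bonferroni", "permutation"),
                                    n_perm = 1000L, seed = 1L) {
  factor_var <- match.arg(factor_var)
  fwe <- match.arg(fwe)
  if (is.null(covariates)) {
    covariates <- switch(factor_var,
      age = "sex",
      sex = c("age", "diagnosis"),
      diagnosis = c("age", "sex")
    )
  }
  if (factor_var %in% covariates) {
    abort(sprintf("'%s' cannot be both the tested factor and a covariate.", factor_var))
  }
  Ym <- fm_values(as_feature_values(Y))
  if (nrow(cov) != nrow(Ym)) abort("Covariates must align with the rows of Y.")
  if (hc_only) {
    keep <- cov$diagnosis == 0
    Ym <- Ym[keep, , drop = FALSE]
    cov <- cov[keep, , drop = FALSE]
  }
  X_red <- build_design(cov, covariates, include_intercept = TRUE)
  x <- as.numeric(cov[[factor_var]])
  X_full <- cbind(X_red, x)
  colnames(X_full)[ncol(X_full)] <- factor_var
  res <- partial_f(Ym, X_red, X_full)
  coefs <- qr.coef(qr(X_full), Ym)[ncol(X_full), ]
  direction <- unname(ifelse(coefs >= 0, "positive", "negative"))
  out <- finalize_mass_univariate(res, factor_var, covariates, alpha, fwe, direction)
  if (fwe == "permutation") {
    out <- permutation_fwe(out, Ym, X_red, function(perm) {
      Xp <- cbind(X_red, x[perm])
      colnames(Xp)[ncol(Xp)] <- factor_var
      Xp
    }, n_perm, seed, alpha)
  }
  out
}

# Max-statistic permutation FWE: permute the tested term's rows, record
# the maximum F across features, and compare the observed F to that null.
permutation_fwe <- function(out, Ym, X_red, full_builder, n_perm, seed, alpha) {
  n <- nrow(Ym)
  max_f <- with_seed(derive_seed(seed, 11L), {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(n)
      max(partial_f(Ym, X_red, full_builder(perm))$F)
    }, numeric(1))
  })
  out$p_fwe <- vapply(out$statistic, function(f) {
    (1 + sum(max_f >= f)) / (n_perm + 1)
  }, numeric(1))
  out$significant <- out$p_fwe < alpha
  attr(out, "n_significant") <- sum(out$significant)
  out
}

#' Partition features into contiguous equal-size regions of interest
#'
#' A synthetic parcellation assigning each feature to one of `n_roi`
#' contiguous, (near-)equal-size blocks over the feature index.
#'
#' @param n_features Number of features.
#' @param n_roi Number of regions (default 100).
#' @return Integer vector of ROI assignments, length `n_features`.
#' @export
make_parcellation <- function(n_features, n_roi = 100L) {
  if (n_roi > n_features) abort("n_roi cannot exceed n_features.")
  sort(rep_len(seq_len(n_roi), n_features))
}

#' Whole-brain median summary and its correlation with age
#'
#' Per subject: the median of the features within each region of
#' interest, then the median across the regional values (optionally the
#' median over all pooled in-ROI features via
#' `summary_method = "pooled"`). The resulting one-number-per-subject
#' summary is correlated with age — the quantity used to judge whether
#' harmonization preserved (or unmasked) the age effect.
#'
#' @param Y A [feature_matrix()] or numeric matrix.
#' @param parcellation Integer ROI assignment per feature (see
#'   [make_parcellation()]); every ROI must contain at least one feature.
#' @param cov Covariate tibble aligned with `Y` (needs `age`).
#' @param summary_method `"roi_median"` (median of ROI medians, default)
#'   or `"pooled"` (plain median across features).
#' @return A list with `summary` (tibble: subject_id, value, age),
#'   `r` (Pearson correlation with age) and `p_value`.
#' @export
median_roi_correlation <- function(Y, parcellation, cov,
                                   summary_method = c("roi_median", "pooled")) {
  summary_method <- match.arg(summary_method)
  Ym <- fm_values(as_feature_values(Y))
  parcellation <- as.integer(parcellation)
  if (length(parcellation) != ncol(Ym)) {
    abort("parcellation must assign every feature to a ROI.")
  }
  rois <- sort(unique(parcellation))
  counts <- table(parcellation)
  if (any(counts == 0)) abort("Every ROI must contain at least one feature.")
  values <- if (summary_method == "pooled") {
    unname(apply(Ym, 1L, median))
  } else {
    roi_medians <- vapply(
      rois,
      function(r) apply(Ym[, parcellation == r, drop = FALSE], 1L, median),
      numeric(nrow(Ym))
    )
    unname(apply(roi_medians, 1L, median))
  }
  ct <- cor.test(values, cov$age, method = "pearson")
  list(
    summary = tibble::tibble(
      subject_id = rownames(Ym) %||% as.character(seq_len(nrow(Ym))),
      value = values, age = cov$age, site = cov$site
    ),
    r = unname(ct$estimate),
    p_value = ct$p.value
  )
}
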