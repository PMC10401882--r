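#' Spatial ICA of a subjects-by-features matrix
#'
#' Decomposes the feature-wise centered matrix as `Y - mean = A %*% S`,
#' where the rows of `S` are spatial maps sought to be statistically
#' independent and non-Gaussian across features, and the columns of `A`
#' are the corresponding per-subject mixing courses — the objects later
#' tested against site and signal covariates. The algorithm is fixed-point
#' ICA on PCA-whitened data: logcosh contrast, symmetric decorrelation,
#' seed-controlled random orthogonal initialization. Components are
#' ordered by explained variance (descending) with the sign fixed so each
#' map's largest-magnitude value is positive.
#'
#' @param Y A [feature_matrix()] or numeric matrix (subjects x features).
#' @param n_components Number of components `C`, `2 <= C <= rank(Y)`.
#' @param seed Integer seed for the initial rotation.
#' @param max_iter Maximum fixed-point iterations (default 1000).
#' @param tol Convergence tolerance on the rotation update (default 1e-6).
#' @return An `ica_model` list: `A` (subjects x C), `S` (C x features),
#'   `center` (per-feature means), `explained_variance`, `converged`,
#'   `iterations`, `seed`.
#' @export
run_ica <- function(Y, n_components, seed = 1L, max_iter = 1000L, tol = 1e-6) {
  Ym <- fm_values(as_feature_values(Y))
  n <- nrow(Ym)
  p <- ncol(Ym)
  C <- as.integer(n_components)
  if (C < 2L) abort("n_components must be at least 2.")
  if (C > min(n, p)) {
    abort(sprintf("n_components (%d) exceeds min(n_subjects, n_features) = %d.", C, min(n, p)))
  }
  center <- colMeans(Ym)
  Xc <- sweep(Ym, 2L, center)
  sv <- svd(Xc, nu = C, nv = C)
  r <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10)
  if (C > r) {
    abort(sprintf("n_components (%d) exceeds the rank of the centered data; at most %d achievable.", C, r))
  }
  # Whitened spatial sources: rows of Z have unit mean square across features.
  Z <- sqrt(p) * t(sv$v[, seq_len(C), drop = FALSE]) # C x p
  W <- with_seed(derive_seed(seed, 7L), {
    qr.Q(qr(matrix(rnorm(C * C), C, C)))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), C) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  delta <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / p - diag(rowMeans(Gp), C) %*% W
    W_new <- sym_decorrelate(W_new)
    # convergence: rotations per component close to +/-1
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "ICA did not converge within %d iterations (last update %.2e > tol %.0e); result flagged.",
      max_iter, delta, tol
    ))
  }
  S <- W %*% Z # C x p, rows ~ unit mean square
  # A = Xc pinv(S); with S = sqrt(p) W V_C' and S S' = p I this is
  # Xc V_C W' / sqrt(p)
  A <- (Xc %*% sv$v[, seq_len(C), drop = FALSE]) %*% t(W) / sqrt(p)
  # order by explained variance ||A_c||^2 ||S_c||^2
  ev <- colSums(A^2) * rowSums(S^2)
  ord <- order(ev, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  ev <- ev[ord]
  # sign convention: largest-magnitude map value positive
  for (c in seq_len(C)) {
    s <- sign(S[c, which.max(abs(S[c, ]))])
    if (s < 0) {
      S[c, ] <- -S[c, ]
      A[, c] <- -A[, c]
    }
  }
  colnames(A) <- rownames(S) <- paste0("IC", seq_len(C))
  rownames(A) <- rownames(Ym)
  resid <- norm(Xc - A %*% S, "F") / max(norm(Xc, "F"), .Machine$double.eps)
  structure(list(
    A = A, S = S, center = center, n_components = C,
    explained_variance = ev, residual = resid,
    converged = converged, iterations = it, seed = as.integer(seed)
  ), class = "ica_model")
}

as_feature_values <- function(Y) {
  if (inherits(Y, "feature_matrix")) {
    return(Y)
  }
  feature_matrix(as.matrix(Y))
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf(
    "<ica_model> %d components over %d subjects x %d features; %sconverged in %d iterations (residual %.2e)\n",
    x$n_components, nrow(x$A), ncol(x$S),
    if (x$converged) "" else "NOT ", x$iterations, x$residual
  ))
  invisible(x)
}

#' Classify independent components as signal, noise, mixed or unclassified
#'
#' Tests every mixing course (column of `A`) against each signal variable
#' with a Pearson correlation test (point-biserial for the binary ones)
#' and against the site label with a one-way ANOVA F-test, then applies a
#' Bonferroni correction over the whole family (components x tested
#' variables). A component significant only for signal variables is
#' `signal`; only for site, `noise`; for both, `mixed`; for neither,
#' `unclassified`. Unclassified components are retained by both denoisers
#' (they are never part of the removal basis).
#'
#' @param model An [run_ica()] model.
#' @param cov Covariate tibble aligned row-wise with the data the model
#'   was fitted on.
#' @param signal_vars Signal variable names (default diagnosis, sex, age).
#' @param alpha Family-wise significance level (default 0.05).
#' @param correction Multiplicity correction; only `"bonferroni"`.
#' @return A `component_labels` tibble: one row per component with raw
#'   p-values per variable, the site p-value, and `label`. Attributes
#'   record the correction method, family size and alpha.
#' @export
classify_components <- function(model, cov, signal_vars = c("diagnosis", "sex", "age"),
                                alpha = 0.05, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  stopifnot(inherits(model, "ica_model"))
  if (nrow(cov) != nrow(model$A)) {
    abort("Covariate rows must align with the subjects the ICA was run on.")
  }
  C <- model$n_components
  m_family <- C * (length(signal_vars) + 1L)
  site <- factor(cov$site)
  rows <- purrr::map(seq_len(C), function(c) {
    a <- model$A[, c]
    if (sd(a) < .Machine$double.eps^0.5) {
      warn(sprintf("Component %d has a constant course; labeled unclassified.", c))
      p_sig <- stats::setNames(rep(NA_real_, length(signal_vars)), signal_vars)
      return(c(list(component = c), as.list(p_sig), list(p_site = NA_real_, label = "unclassified")))
    }
    p_sig <- vapply(signal_vars, function(v) {
      x <- as.numeric(cov[[v]])
      if (sd(x) < .Machine$double.eps^0.5) {
        return(NA_real_)
      }
      cor.test(a, x, method = "pearson")$p.value
    }, numeric(1))
    p_site <- anova(lm(a ~ site))[["Pr(>F)"]][1L]
    sig_signal <- any(p_sig * m_family < alpha, na.rm = TRUE)
    sig_site <- isTRUE(p_site * m_family < alpha)
    label <- if (sig_signal && sig_site) {
      "mixed"
    } else if (sig_signal) {
      "signal"
    } else if (sig_site) {
      "noise"
    } else {
      "unclassified"
    }
    c(list(component = c), as.list(p_sig), list(p_site = p_site, label = label))
  })
  out <- dplyr::bind_rows(purrr::map(rows, tibble::as_tibble))
  attr(out, "correction") <- correction
  attr(out, "family_size") <- m_family
  attr(out, "alpha") <- alpha
  class(out) <- c("component_labels", class(out))
  out
}

#' Extract course submatrices by component label
#'
#' Returns the columns of `A` whose label is in `which`, in original
#' component order. An empty selection yields a valid 0-column matrix.
#'
#' @param model An [run_ica()] model.
#' @param labels A [classify_components()] result aligned with the model.
#' @param which Character subset of
#'   `c("signal", "noise", "mixed", "unclassified")`.
#' @return A subjects-by-k matrix of mixing courses.
#' @export
select_courses <- function(model, labels, which = "noise") {
  stopifnot(inherits(model, "ica_model"))
  if (nrow(labels) != model$n_components) {
    abort("labels must have one row per component.")
  }
  which <- match.arg(which, c("signal", "noise", "mixed", "unclassified"),
    several.ok = TRUE
  )
  keep <- labels$component[labels$label %in% which]
  model$A[, keep, drop = FALSE]
}
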