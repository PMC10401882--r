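#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ICA model into one row per component
#'
#' @param x An [run_ica()] model.
#' @param ... Unused.
#' @return Tibble with `component`, `explained_variance`,
#'   `variance_fraction`, `course_sd`.
#' @export
tidy.ica_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    explained_variance = x$explained_variance,
    variance_fraction = x$explained_variance / sum(x$explained_variance),
    course_sd = apply(x$A, 2L, sd)
  )
}

#' @export
glance.ica_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n_subjects = nrow(x$A),
    n_features = ncol(x$S),
    converged = x$converged,
    iterations = x$iterations,
    residual = x$residual
  )
}

#' Tidy a ComBat model into one row per site and feature
#'
#' @param x A [combat_fit()] model.
#' @param ... Unused.
#' @return Tibble with `site`, `feature`, naive and shrunk additive
#'   (`gamma_hat`, `gamma_star`) and multiplicative (`delta_hat`,
#'   `delta_star`) site effects.
#' @export
tidy.combat_model <- function(x, ...) {
  nf <- length(x$alpha)
  tibble::tibble(
    site = rep(x$site_levels, each = nf),
    feature = rep(seq_len(nf), times = length(x$site_levels)),
    gamma_hat = as.numeric(t(x$gamma_hat)),
    gamma_star = as.numeric(t(x$gamma_star)),
    delta_hat = as.numeric(t(x$delta_hat)),
    delta_star = as.numeric(t(x$delta_star))
  )
}

#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$site_levels),
    n_features = length(x$alpha),
    n_signal_covariates = length(x$signal_columns),
    max_eb_iterations = max(x$eb_iterations),
    mean_abs_gamma_star = mean(abs(x$gamma_star)),
    mean_delta_star = mean(x$delta_star)
  )
}

#' @export
tidy.component_labels <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.mass_univariate_result <- function(x, ...) {
  tibble::tibble(
    factor = attr(x, "factor"),
    fwe = attr(x, "fwe"),
    alpha = attr(x, "alpha"),
    n_features = nrow(x),
    n_significant = sum(x$significant),
    fraction_significant = mean(x$significant),
    min_p_fwe = min(x$p_fwe)
  )
}

#' @export
glance.harmonization_result <- function(x, ...) {
  out <- tibble::tibble(
    method = x$method,
    n_subjects = nrow(x$harmonized),
    n_features = ncol(x$harmonized)
  )
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels$label,
      levels = c("signal", "noise", "mixed", "unclassified")
    ))
    out <- dplyr::bind_cols(out, tibble::as_tibble(t(as.matrix(tab))))
  }
  out
}
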