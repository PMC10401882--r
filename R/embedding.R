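#' Low-dimensional embedding with per-labeling silhouette scores
#'
#' Embeds the subjects in 2-D with t-SNE (deterministic given the seed)
#' and quantifies how strongly the embedding clusters by site, sex and
#' diagnosis via the mean silhouette width of each labeling, plus the
#' canonical correlation of the coordinates with age. Site silhouettes
#' near or above 0.5 indicate scanner-driven clustering; values near 0
#' after harmonization indicate the site structure is gone.
#'
#' @param Y A [feature_matrix()] or numeric matrix.
#' @param cov Covariate tibble aligned with `Y`.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (default 30; requires
#'   `n_subjects >= 3 * perplexity + 1`).
#' @param max_iter t-SNE iterations (default 1000).
#' @return An `embedding_result` list: `coordinates` tibble
#'   (`dim1`, `dim2`, plus the covariates), `silhouette` named vector
#'   (site, sex, diagnosis), `age_correlation`, `seed`, `perplexity`.
#' @export
embed_and_score <- function(Y, cov, seed = 1L, perplexity = 30, max_iter = 1000L) {
  Ym <- fm_values(as_feature_values(Y))
  if (nrow(cov) != nrow(Ym)) abort("Covariates must align with the rows of Y.")
  if (nrow(Ym) < 3 * perplexity + 1) {
    abort(sprintf(
      "Need at least %d subjects for perplexity %g.", ceiling(3 * perplexity) + 1, perplexity
    ))
  }
  if (all(apply(Ym, 2L, function(x) sd(x) < .Machine$double.eps^0.5))) {
    abort("Degenerate input: all subjects identical.")
  }
  coords <- with_seed(derive_seed(seed, 13L), {
    Rtsne::Rtsne(Ym,
      dims = 2L, perplexity = perplexity, max_iter = max_iter,
      check_duplicates = FALSE, pca = TRUE, verbose = FALSE
    )$Y
  })
  d <- stats::dist(coords)
  sil_for <- function(labels) {
    labels <- as.integer(factor(labels))
    if (length(unique(labels)) < 2L) {
      return(NA_real_)
    }
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  }
  sil <- c(
    site = sil_for(cov$site),
    sex = sil_for(cov$sex),
    diagnosis = sil_for(cov$diagnosis)
  )
  age_cor <- max(abs(cor(coords, cov$age)))
  out <- structure(list(
    coordinates = tibble::tibble(
      subject_id = cov$subject_id, dim1 = coords[, 1L], dim2 = coords[, 2L],
      site = cov$site, sex = cov$sex, diagnosis = cov$diagnosis, age = cov$age
    ),
    silhouette = sil,
    age_correlation = age_cor,
    seed = as.integer(seed),
    perplexity = perplexity
  ), class = "embedding_result")
  out
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf(
    "<embedding_result> %d subjects; silhouette: site %.3f, sex %.3f, diagnosis %.3f; |cor(coords, age)| %.3f\n",
    nrow(x$coordinates), x$silhouette["site"], x$silhouette["sex"],
    x$silhouette["diagnosis"], x$age_correlation
  ))
  invisible(x)
}
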