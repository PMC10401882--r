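#' Per-site demographics of the multi-site autism cohort
#'
#' Scanner parameters and demographic composition of the 16-site resting
#' state cohort (ABIDE II after quality control) whose structure the
#' synthetic generator emulates: per-site scanner model, TR/TE, flip
#' angle, voxel size, ASD and healthy-control counts, male/female counts
#' and age mean/sd.
#'
#' @return A tibble with one row per site.
#' @export
abide_demographics <- function() {
  path <- system.file("extdata", "abide2_demographics.csv",
    package = "harmodp", mustWork = TRUE
  )
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_demographics(df)
  tibble::as_tibble(df)
}

validate_demographics <- function(d) {
  needed <- c("site", "n_asd", "n_hc", "n_male", "n_female", "age_mean", "age_sd")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    abort(sprintf("Demographics table missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in c("n_asd", "n_hc", "n_male", "n_female")) {
    x <- d[[col]]
    if (any(x < 0) || any(x != round(x))) {
      abort(sprintf("Demographics column '%s' must hold non-negative integers.", col))
    }
  }
  invisible(d)
}

#' Summarize a demographics table into cohort totals
#'
#' @param d A demographics tibble (see [abide_demographics()]).
#' @return A one-row tibble with `n_sites`, `n_asd`, `n_hc`, `n_total`.
#' @export
summarize_demographics <- function(d) {
  if (nrow(d) == 0L) {
    return(tibble::tibble(n_sites = 0L, n_asd = 0L, n_hc = 0L, n_total = 0L))
  }
  validate_demographics(d)
  tibble::tibble(
    n_sites = nrow(d),
    n_asd = as.integer(sum(d$n_asd)),
    n_hc = as.integer(sum(d$n_hc)),
    n_total = as.integer(sum(d$n_asd) + sum(d$n_hc))
  )
}
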