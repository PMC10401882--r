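#' Validate a per-subject covariate table
#'
#' The harmonization model distinguishes the site label (the noise
#' variable: which scanner the subject was measured on) from the signal
#' variables of biological interest: diagnosis (ASD vs. healthy control),
#' sex and age. This validator coerces a data frame to the canonical
#' column types and enforces the invariants every downstream routine
#' relies on.
#'
#' @param df Data frame with columns `subject_id`, `site`, `diagnosis`,
#'   `sex`, `age` (extra columns are kept).
#' @return A tibble with `subject_id` character, `site` a factor with
#'   levels in first-appearance order, `diagnosis` and `sex` coded 0/1
#'   numeric, `age` numeric.
#' @export
covariate_table <- function(df) {
  required <- c("subject_id", "site", "diagnosis", "sex", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Missing covariate column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)
  out$subject_id <- as.character(out$subject_id)
  if (anyDuplicated(out$subject_id)) abort("subject_id values must be unique.")
  out$site <- factor(as.character(out$site), levels = unique(as.character(out$site)))
  out$diagnosis <- coerce_binary(out$diagnosis, "diagnosis", one = c("ASD", "asd", "1", "TRUE"))
  out$sex <- coerce_binary(out$sex, "sex", one = c("M", "male", "Male", "1", "TRUE"))
  if (!is.numeric(out$age)) {
    age_num <- suppressWarnings(as.numeric(as.character(out$age)))
    if (anyNA(age_num) && !anyNA(out$age)) {
      abort(sprintf("Non-numeric age at row %d.", which(is.na(age_num))[1L]))
    }
    out$age <- age_num
  }
  for (col in required) {
    if (anyNA(out[[col]])) {
      abort(sprintf("Missing values in covariate column '%s' (row %d).",
                    col, which(is.na(out[[col]]))[1L]))
    }
  }
  counts <- table(out$site)
  if (length(counts) < 2L) abort("Covariates must contain at least 2 sites.")
  if (any(counts < 2L)) {
    abort(sprintf(
      "Every site needs at least 2 subjects; site(s) with fewer: %s.",
      paste(names(counts)[counts < 2L], collapse = ", ")
    ))
  }
  out
}

coerce_binary <- function(x, name, one) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x))) {
      abort(sprintf("Column '%s' must be binary 0/1.", name))
    }
    return(as.numeric(x))
  }
  x <- as.character(x)
  lv <- unique(x[!is.na(x)])
  if (length(lv) > 2L) abort(sprintf("Column '%s' has more than 2 levels.", name))
  as.numeric(x %in% one)
}

#' Read a covariate table from a delimited file
#'
#' Reads a comma-separated file with a header row and maps its columns to
#' the canonical covariate names, then validates with [covariate_table()].
#' Unused extra columns are kept and noted with a message.
#'
#' @param path CSV file path.
#' @param column_spec Named character vector mapping canonical names
#'   (`subject_id`, `site`, `diagnosis`, `sex`, `age`) to the file's
#'   column names. Defaults to the identity mapping.
#' @return A validated covariate tibble.
#' @export
load_covariates <- function(path, column_spec = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  canonical <- c("subject_id", "site", "diagnosis", "sex", "age")
  spec <- stats::setNames(canonical, canonical)
  if (!is.null(column_spec)) spec[names(column_spec)] <- column_spec
  missing_cols <- spec[!spec %in% names(df)]
  if (length(missing_cols)) {
    abort(sprintf(
      "Covariate file '%s' is missing column(s): %s.",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  extra <- setdiff(names(df), spec)
  if (length(extra)) {
    inform(sprintf("Ignoring extra covariate column(s): %s.", paste(extra, collapse = ", ")))
  }
  out <- df[, spec, drop = FALSE]
  names(out) <- canonical
  covariate_table(cbind(out, df[, extra, drop = FALSE]))
}

#' Build a design matrix from covariates
#'
#' Codes the requested variables into a full-rank numeric design matrix:
#' binary variables as a single 0/1 column, categorical variables as L-1
#' treatment-coded indicators against the first-appearance reference
#' level, continuous variables as-is. This is the `X_signal` regressed in
#' the ComBat model and the `Var_Signal` basis that the dual-projection
#' step purges from mixed components.
#'
#' @param cov A covariate tibble (see [covariate_table()]).
#' @param variables Ordered character vector of column names to include;
#'   may be empty.
#' @param include_intercept Prepend a column of ones (default `TRUE`).
#' @return A numeric matrix with named columns and a `coding` attribute
#'   recording how each categorical was coded.
#' @export
build_design <- function(cov, variables = c("diagnosis", "age", "sex"),
                         include_intercept = TRUE) {
  missing_vars <- setdiff(variables, names(cov))
  if (length(missing_vars)) {
    abort(sprintf("Unknown design variable(s): %s.", paste(missing_vars, collapse = ", ")))
  }
  n <- nrow(cov)
  cols <- list()
  col_names <- character()
  coding <- list()
  add_col <- function(name, values) {
    cols[[length(cols) + 1L]] <<- values
    col_names[length(col_names) + 1L] <<- name
  }
  if (include_intercept) add_col("(Intercept)", rep(1, n))
  for (v in variables) {
    x <- cov[[v]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(as.character(x), levels = unique(as.character(x)))
      lv <- levels(x)
      coding[[v]] <- list(type = "treatment", reference = lv[1L], levels = lv)
      for (l in lv[-1L]) add_col(paste0(v, l), as.numeric(x == l))
    } else {
      coding[[v]] <- list(type = "numeric")
      add_col(v, as.numeric(x))
    }
  }
  if (!length(cols)) abort("Design matrix would have zero columns.")
  X <- do.call(cbind, cols)
  colnames(X) <- col_names
  rownames(X) <- cov$subject_id
  r <- matrix_rank(X)
  if (r < ncol(X)) {
    dep <- dependent_columns(X)
    abort(sprintf(
      "Design matrix is rank deficient (rank %d < %d columns); dependent column set: %s.",
      r, ncol(X), paste(dep, collapse = ", ")
    ))
  }
  attr(X, "coding") <- coding
  X
}

# Name a set of linearly dependent columns for the rank-deficiency error.
dependent_columns <- function(X, tol = 1e-8) {
  qrX <- qr(X, tol = tol)
  if (qrX$rank == ncol(X)) return(character())
  colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
}
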