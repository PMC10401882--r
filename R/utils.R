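#' @importFrom rlang abort warn inform %||%
#' @importFrom stats coef cor cor.test lm median pf pnorm pt qnorm rbinom rnorm
#'   runif sd var fft anova as.formula
NULL

# Moore-Penrose pseudo-inverse with a relative singular-value cutoff.
# rtol is relative to the largest singular value.
pinv <- function(X, rtol = 1e-10) {
  if (length(X) == 0L || ncol(X) == 0L) {
    return(matrix(0, nrow = ncol(X), ncol = nrow(X)))
  }
  s <- svd(X)
  keep <- s$d > rtol * s$d[1L]
  if (!any(keep)) {
    return(matrix(0, nrow = ncol(X), ncol = nrow(X)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Orthogonal projection of the columns of Y onto the column space of B,
# realized as minimum-norm least squares (rank deficiency allowed).
project_onto <- function(Y, B, rtol = 1e-10) {
  if (is.null(B) || ncol(B) == 0L) {
    return(matrix(0, nrow = nrow(Y), ncol = ncol(Y)))
  }
  B %*% (pinv(B, rtol = rtol) %*% Y)
}

# Numerical column rank via QR with a tolerance; used by design validation.
matrix_rank <- function(X, tol = 1e-8) {
  if (length(X) == 0L) return(0L)
  qr(X, tol = tol)$rank
}

# Derive a stream-specific 32-bit seed from a base seed, so independent
# stages (covariates, effects, noise) use decoupled streams.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
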