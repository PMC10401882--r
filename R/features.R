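#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' For every in-mask voxel: linearly detrend the series, take the real
#' FFT, convert to one-sided amplitudes `2|F_k|/t`, and sum the
#' amplitudes over the frequency bins falling inside the band (closed
#' interval on both edges; the DC bin is always excluded, even when
#' `band[1] == 0`).
#'
#' @param ts 4-D numeric array (x, y, z, t) or a voxels-by-time matrix.
#' @param tr Repetition time in seconds.
#' @param band Frequency band in Hz, `c(low, high)` with
#'   `0 <= low < high <= 1/(2*tr)`.
#' @param mask Optional binary 3-D array; out-of-mask voxels get 0.
#' @param stat Spectral statistic: `"sum_amplitude"` (default),
#'   `"mean_amplitude"` or `"sum_power"` (sum of squared amplitudes).
#' @param detrend Remove a linear trend before the FFT (default `TRUE`).
#' @return A 3-D map (array input) or a vector (matrix input).
#' @export
compute_alff <- function(ts, tr, band = c(0.01, 0.1), mask = NULL,
                         stat = c("sum_amplitude", "mean_amplitude", "sum_power"),
                         detrend = TRUE) {
  stat <- match.arg(stat)
  nyquist <- 1 / (2 * tr)
  if (band[1] < 0 || band[1] >= band[2] || band[2] > nyquist + 1e-12) {
    abort(sprintf(
      "Band [%g, %g] Hz invalid for TR %g s (Nyquist %g Hz).",
      band[1], band[2], tr, nyquist
    ))
  }
  is_vol <- length(dim(ts)) == 4L
  if (is_vol) {
    shape <- dim(ts)[1:3]
    nt <- dim(ts)[4L]
    X <- matrix(ts, nrow = prod(shape), ncol = nt)
  } else {
    X <- as.matrix(ts)
    nt <- ncol(X)
  }
  if (detrend) X <- detrend_linear(X)
  # real FFT over time: mvfft works column-wise, so transpose.
  F <- stats::mvfft(t(X))
  freqs <- (seq_len(nt) - 1L) / (nt * tr)
  kmax <- floor(nt / 2) + 1L
  in_band <- freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12 &
    seq_len(nt) >= 2L & seq_len(nt) <= kmax
  amp <- 2 * Mod(F[in_band, , drop = FALSE]) / nt
  vals <- switch(stat,
    sum_amplitude = colSums(amp),
    mean_amplitude = colMeans(amp),
    sum_power = colSums(amp^2)
  )
  if (!is_vol) {
    return(vals)
  }
  out <- array(vals, dim = shape)
  if (!is.null(mask)) out[!(as.array(mask) > 0)] <- 0
  out
}

detrend_linear <- function(X) {
  nt <- ncol(X)
  tt <- seq_len(nt)
  B <- cbind(1, tt - mean(tt))
  X - t(B %*% qr.coef(qr(B), t(X)))
}

#' Kendall's coefficient of concordance for a set of series
#'
#' The rank-based concordance `W` of `K` series over `t` timepoints:
#' each series is ranked over time (mid-ranks for ties), `R_j` is the
#' rank sum across series at timepoint `j`, and
#' `W = 12 * sum((R_j - mean(R))^2) / (K^2 (t^3 - t) - K * TT)` with the
#' tie correction `TT = sum over series of sum(tau^3 - tau)` over tie
#' groups of size `tau`. `W = 1` means identical rankings.
#'
#' @param X Numeric matrix, one series per row (`K x t`).
#' @return `W` in `[0, 1]`.
#' @export
kendall_w <- function(X) {
  X <- as.matrix(X)
  K <- nrow(X)
  t_len <- ncol(X)
  if (K < 2L) abort("kendall_w needs at least 2 series.")
  R <- apply(X, 1L, rank) # t x K, mid-ranks for ties
  Rj <- rowSums(R)
  TT <- sum(apply(X, 1L, function(x) {
    tau <- table(x)
    sum(tau^3 - tau)
  }))
  denom <- K^2 * (t_len^3 - t_len) - K * TT
  if (denom <= 0) {
    return(0)
  }
  12 * sum((Rj - mean(Rj))^2) / denom
}

#' Regional homogeneity (ReHo) map
#'
#' Per in-mask voxel, Kendall's coefficient of concordance ([kendall_w()])
#' between the voxel's time series and its nearest in-mask neighbors
#' (itself included). Voxels whose available neighborhood contains only
#' themselves get `W = 0` (counted and reported via a message).
#'
#' @param ts 4-D numeric array (x, y, z, t).
#' @param neighborhood Neighborhood size: 7 (faces), 19 (faces+edges) or
#'   27 (full cube).
#' @param mask Optional binary 3-D array.
#' @return A 3-D map of `W` values (0 outside the mask).
#' @export
compute_reho <- function(ts, neighborhood = 27L, mask = NULL) {
  shape <- dim(ts)[1:3]
  if (any(shape < 3L)) abort("Every spatial dimension must be >= 3 for ReHo.")
  if (!neighborhood %in% c(7L, 19L, 27L)) abort("neighborhood must be 7, 19 or 27.")
  nt <- dim(ts)[4L]
  mask_arr <- if (is.null(mask)) array(TRUE, shape) else as.array(mask) > 0
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist2 <- rowSums(offs^2)
  offs <- offs[switch(as.character(neighborhood),
    "7" = dist2 <= 1, "19" = dist2 <= 2, "27" = dist2 <= 3
  ), , drop = FALSE]
  Xall <- matrix(ts, nrow = prod(shape), ncol = nt)
  out <- array(0, dim = shape)
  idx <- which(mask_arr, arr.ind = TRUE)
  isolated <- 0L
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    nb <- sweep(offs, 2L, v, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * shape[1] + (nb[, 3] - 1L) * shape[1] * shape[2]
    lin <- lin[mask_arr[lin]]
    if (length(lin) < 2L) {
      isolated <- isolated + 1L
      next
    }
    out[v[1], v[2], v[3]] <- kendall_w(Xall[lin, , drop = FALSE])
  }
  if (isolated > 0L) {
    inform(sprintf("%d isolated in-mask voxel(s) had no neighbors; W set to 0.", isolated))
  }
  out
}

#' Gaussian spatial smoothing of a 3-D map
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis, in voxel units derived from `voxel_size_mm`. With a mask, the
#' map and mask are smoothed separately and divided (mask-aware
#' renormalization), so in-mask values are unbiased near the boundary.
#'
#' @param map 3-D numeric array.
#' @param fwhm_mm Full width at half maximum in mm (> 0; values below
#'   numerical resolution return the map unchanged).
#' @param voxel_size_mm Voxel edge lengths in mm (scalar or 3-vector).
#' @param mask Optional binary 3-D array.
#' @return Smoothed 3-D map (0 outside the mask when given).
#' @export
smooth_gaussian <- function(map, fwhm_mm, voxel_size_mm = 1, mask = NULL) {
  if (any(voxel_size_mm <= 0)) abort("voxel_size_mm must be positive.")
  if (fwhm_mm < 0) abort("fwhm_mm must be non-negative.")
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size_mm
  if (all(sigma_vox < 1e-6)) {
    return(map)
  }
  shape <- dim(map)
  smooth_arr <- function(arr) {
    for (ax in 1:3) {
      s <- sigma_vox[ax]
      if (s < 1e-6) next
      half <- max(1L, ceiling(4 * s))
      k <- exp(-(seq(-half, half))^2 / (2 * s^2))
      k <- k / sum(k)
      arr <- conv_axis(arr, k, ax)
    }
    arr
  }
  if (is.null(mask)) {
    return(smooth_arr(map))
  }
  m <- as.array(mask) > 0
  num <- smooth_arr(map * m)
  den <- smooth_arr(m * 1)
  out <- array(0, dim = shape)
  ok <- m & den > 1e-12
  out[ok] <- num[ok] / den[ok]
  out
}

# 1-D convolution of a 3-D array along one axis with zero padding,
# implemented as a banded matrix product on the unfolded array.
conv_axis <- function(arr, kernel, axis) {
  shape <- dim(arr)
  n <- shape[axis]
  half <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - half - 1L
    i <- seq_len(n)
    tgt <- i + off
    ok <- tgt >= 1L & tgt <= n
    K[cbind(i[ok], tgt[ok])] <- K[cbind(i[ok], tgt[ok])] + kernel[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  a <- K %*% matrix(a, nrow = n)
  dim(a) <- d
  aperm(a, order(perm))
}

#' Feature-map pipeline with the modality-specific smoothing order
#'
#' ALFF: smooth every 3-D frame of the 4-D series first (FWHM 6 mm by
#' default), then compute the spectral amplitude. ReHo: compute the
#' concordance map on the unsmoothed series, then smooth the map.
#'
#' @param ts 4-D numeric array (x, y, z, t).
#' @param modality `"ALFF"` or `"ReHo"`.
#' @param tr Repetition time in seconds (ALFF only).
#' @param fwhm_mm Smoothing FWHM in mm (default 6).
#' @param voxel_size_mm Voxel size in mm.
#' @param band ALFF band in Hz.
#' @param neighborhood ReHo neighborhood (7/19/27).
#' @param mask Optional binary 3-D array.
#' @return A 3-D feature map.
#' @export
feature_pipeline <- function(ts, modality = c("ALFF", "ReHo"), tr = NULL,
                             fwhm_mm = 6, voxel_size_mm = 3,
                             band = c(0.01, 0.1), neighborhood = 27L,
                             mask = NULL) {
  modality <- match.arg(modality)
  if (modality == "ALFF") {
    if (is.null(tr)) abort("tr is required for ALFF.")
    sm <- ts
    if (fwhm_mm > 0) {
      for (f in seq_len(dim(ts)[4L])) {
        sm[, , , f] <- smooth_gaussian(ts[, , , f], fwhm_mm, voxel_size_mm, mask)
      }
    }
    compute_alff(sm, tr = tr, band = band, mask = mask)
  } else {
    rh <- compute_reho(ts, neighborhood = neighborhood, mask = mask)
    smooth_gaussian(rh, fwhm_mm, voxel_size_mm, mask)
  }
}
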