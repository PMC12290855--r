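# internal: zero-phase frequency-domain band-pass of each column of x.
# Keeps Fourier bins whose frequency lies in [lo, hi] (inclusive, both
# mirrored halves); the DC bin is always removed.
bandpass_columns <- function(x, tr_seconds, band_hz) {
  n <- nrow(x)
  f <- (seq_len(n) - 1) / (n * tr_seconds)
  f <- pmin(f, 1 / tr_seconds - f)           # fold to [0, Nyquist]
  eps <- 1e-12
  keep <- f >= band_hz[1] - eps & f <= band_hz[2] + eps
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Confound removal with orthogonal band-pass filtering
#'
#' Removes a nuisance design from every voxel series by projection on the
#' orthogonal complement of the design's column space, applied orthogonally
#' to a band-pass temporal filter: both the data and the regressors are
#' band-passed with the same zero-phase frequency-domain mask before the
#' projection, so filtering cannot reintroduce removed confounds. With
#' `apply_bandpass = FALSE` only the projection is performed (the
#' deconvolution path uses the full-spectrum signal). Output voxel series
#' are demeaned, and standardized to unit temporal variance when
#' `standardize = TRUE`.
#'
#' @param img a [bold_image].
#' @param design a [nuisance_design()] or `NULL` (filtering / demeaning
#'   only). Rank-deficient designs have their dependent columns dropped
#'   with a warning.
#' @param band_hz inclusive pass band in Hz (default `c(0.01, 0.17)`).
#' @param standardize scale each voxel series to unit variance.
#' @param apply_bandpass apply the band-pass (and filter the regressors).
#' @return a denoised [bold_image]; attribute `dropped_columns` lists any
#'   design columns removed for rank deficiency.
#' @export
denoise <- function(img, design = NULL, band_hz = c(0.01, 0.17),
                    standardize = TRUE, apply_bandpass = TRUE) {
  stopifnot(inherits(img, "bold_image"))
  d <- dim(img$data)
  T <- d[4]
  Y <- t(matrix(img$data, nrow = prod(d[1:3]), ncol = T))   # T x V
  Y <- sweep(Y, 2, colMeans(Y))
  dropped <- character(0)
  X <- NULL
  if (!is.null(design)) {
    if (nrow(design) != T)
      stop("design has ", nrow(design), " rows for ", T, " volumes",
           call. = FALSE)
    X <- sweep(unclass(design), 2, colMeans(design))
    X <- X[, apply(X, 2, function(v) any(v != 0)), drop = FALSE]
    xlabs <- colnames(X)
  }
  if (apply_bandpass) {
    Y <- bandpass_columns(Y, img$tr_seconds, band_hz)
    if (!is.null(X) && ncol(X))
      X <- bandpass_columns(X, img$tr_seconds, band_hz)
  }
  if (!is.null(X) && ncol(X)) {
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      keep <- qrx$pivot[seq_len(qrx$rank)]
      dropped <- xlabs[setdiff(seq_len(ncol(X)), keep)]
      warning("rank-deficient design: dropping ",
              paste(dropped, collapse = ", "))
      qrx <- qr(X[, keep, drop = FALSE])
    }
    Y <- qr.resid(qrx, Y)
  }
  Y <- sweep(Y, 2, colMeans(Y))
  if (standardize) {
    sdev <- sqrt(colMeans(Y^2))
    pos <- sdev > 0
    Y[, pos] <- sweep(Y[, pos, drop = FALSE], 2, sdev[pos], "/")
  }
  out <- img
  out$data <- array(t(Y), d)
  attr(out, "dropped_columns") <- dropped
  out
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths every volume with a separable Gaussian whose FWHM is given in mm
#' per axis; voxel sizes are taken from the affine. `fwhm = 0` on an axis is
#' the identity on that axis. Kernels are truncated at 3.5 sigma and
#' normalized to unit sum, with zero padding at the boundary, so total
#' signal is conserved for interior-supported structure.
#'
#' @param img a [bold_image].
#' @param fwhm_mm numeric length 3, full width at half maximum per axis
#'   (mm, >= 0).
#' @return a smoothed [bold_image].
#' @export
smooth_bold <- function(img, fwhm_mm) {
  stopifnot(inherits(img, "bold_image"))
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  if (any(fwhm_mm < 0)) stop("fwhm must be >= 0", call. = FALSE)
  if (all(fwhm_mm == 0)) return(img)
  vs <- voxel_sizes(img$affine)
  d <- dim(img$data)
  kernels <- lapply(1:3, function(ax) {
    if (fwhm_mm[ax] == 0) return(NULL)
    sigma <- fwhm_mm[ax] / (2 * sqrt(2 * log(2))) / vs[ax]
    r <- max(1L, ceiling(3.5 * sigma))
    w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    w / sum(w)
  })
  # band matrix per axis: zero-padded truncated-kernel convolution
  ops <- lapply(1:3, function(ax) {
    w <- kernels[[ax]]
    if (is.null(w)) return(NULL)
    n <- d[ax]; r <- (length(w) - 1L) / 2L
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- w[ok]
    }
    K
  })
  out <- img$data
  for (t in seq_len(d[4])) {
    v <- out[, , , t]
    if (!is.null(ops[[1]]))
      v <- array(ops[[1]] %*% matrix(v, d[1]), d[1:3])
    if (!is.null(ops[[2]])) {
      v <- aperm(v, c(2, 1, 3))
      v <- array(ops[[2]] %*% matrix(v, d[2]), d[c(2, 1, 3)])
      v <- aperm(v, c(2, 1, 3))
    }
    if (!is.null(ops[[3]])) {
      v <- aperm(v, c(3, 1, 2))
      v <- array(ops[[3]] %*% matrix(v, d[3]), d[c(3, 1, 2)])
      v <- aperm(v, c(2, 3, 1))
    }
    out[, , , t] <- v
  }
  img$data <- out
  img
}
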