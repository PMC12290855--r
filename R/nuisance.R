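#' Nuisance design matrix
#'
#' Time-by-regressor matrix with labelled columns and a provenance tag per
#' column (`retroicor`, `compcor`, `dct` or `motion`), so a combined design
#' can always be traced back to its sources.
#'
#' @param x numeric matrix (n_volumes x p), finite, no all-zero column.
#' @param provenance character vector of length p.
#' @param labels optional column labels (defaults to existing colnames).
#' @return object of class `nuisance_design` (a matrix with attributes
#'   `provenance` and possibly `degenerate`, `explained_variance`).
#' @export
nuisance_design <- function(x, provenance, labels = colnames(x)) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("design contains non-finite values", call. = FALSE)
  if (any(colSums(x != 0) == 0L))
    stop("design contains an all-zero column", call. = FALSE)
  provenance <- rep_len(provenance, ncol(x))
  bad <- setdiff(unique(provenance), c("retroicor", "compcor", "dct", "motion"))
  if (length(bad))
    stop("unknown provenance tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(labels)) labels <- paste0(provenance, seq_len(ncol(x)))
  colnames(x) <- labels
  structure(x, provenance = provenance, class = c("nuisance_design", "matrix"))
}

#' @export
print.nuisance_design <- function(x, ...) {
  tab <- table(attr(x, "provenance"))
  cat(sprintf("<nuisance_design> %d volumes x %d regressors (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Column-bind nuisance designs
#'
#' @param ... `nuisance_design` objects with equal row counts.
#' @return a combined `nuisance_design`.
#' @export
combine_designs <- function(...) {
  ds <- list(...)
  ds <- ds[!vapply(ds, is.null, logical(1))]
  stopifnot(length(ds) >= 1L)
  if (length(unique(vapply(ds, nrow, integer(1)))) != 1L)
    stop("designs have different numbers of volumes", call. = FALSE)
  nuisance_design(do.call(cbind, lapply(ds, unclass)),
                  provenance = unlist(lapply(ds, attr, "provenance")),
                  labels = unlist(lapply(ds, colnames)))
}

#' Cardiac and respiratory phases at volume times
#'
#' Cardiac phase is linear in time between consecutive pulse peaks, wrapped
#' to `[0, 2*pi)` (a volume exactly on a peak has phase 0); volumes outside
#' the detected peaks extrapolate the nearest inter-peak interval.
#' Respiratory phase follows the Glover histogram-equalized transfer: the
#' empirical CDF of the belt amplitude, scaled to `(0, pi]` and signed by
#' the derivative of the belt trace, giving a phase in `(-pi, pi]`.
#'
#' @param cardiac,resp [physio_trace()] objects. Cardiac peaks are taken
#'   from `peak_times_seconds` when present, otherwise detected as local
#'   maxima above the trace mean.
#' @param volume_times acquisition times of the volumes (s).
#' @return list with numeric vectors `phi_c` (in `[0, 2*pi)`) and `phi_r`
#'   (in `(-pi, pi]`), one entry per volume.
#' @export
retroicor_phases <- function(cardiac, resp, volume_times) {
  stopifnot(inherits(cardiac, "physio_trace"), inherits(resp, "physio_trace"))
  pk <- cardiac$peak_times_seconds
  if (is.null(pk)) {
    x <- cardiac$samples
    thr <- mean(x) + 0.25 * stats::sd(x)
    i <- which(x[-c(1, length(x))] > x[-c(length(x) - 1, length(x))] &
                 x[-c(1, length(x))] >= x[-(1:2)] &
                 x[-c(1, length(x))] > thr) + 1L
    pk <- (i - 1) / cardiac$sampling_rate_hz
  }
  if (length(pk) < 2L)
    stop("fewer than 2 cardiac peaks: cannot assign cardiac phases",
         call. = FALSE)
  phi_c <- vapply(volume_times, function(t) {
    k <- findInterval(t, pk)
    if (k == 0L) { lo <- pk[1]; hi <- pk[2] }
    else if (k >= length(pk)) { lo <- pk[length(pk) - 1]; hi <- pk[length(pk)] }
    else { lo <- pk[k]; hi <- pk[k + 1] }
    (2 * pi * (t - lo) / (hi - lo)) %% (2 * pi)
  }, numeric(1))

  rt <- (seq_along(resp$samples) - 1) / resp$sampling_rate_hz
  b <- stats::approx(rt, resp$samples, xout = volume_times, rule = 2)$y
  db <- stats::approx(rt[-1] - 0.5 / resp$sampling_rate_hz,
                      diff(resp$samples), xout = volume_times, rule = 2)$y
  s <- sign(db); s[s == 0] <- 1
  transfer <- stats::ecdf(resp$samples)(b)     # in (0, 1]
  phi_r <- pi * transfer * s
  phi_r[phi_r <= -pi] <- pi                    # keep in (-pi, pi]
  list(phi_c = phi_c, phi_r = phi_r)
}

#' RETROICOR Fourier expansion
#'
#' Builds the physiological-noise design from per-volume cardiac and
#' respiratory phases: `{sin, cos}` of the first `n_cardiac` cardiac
#' harmonics, the first `n_resp` respiratory harmonics, and `n_interaction`
#' multiplicative orders expanded as `{sin, cos}` of both the phase sum and
#' difference. Defaults (3 cardiac, 4 respiratory, 1 interaction) give
#' 6 + 8 + 4 = 18 regressors.
#'
#' @param phi_c,phi_r per-volume phases (see [retroicor_phases()]).
#' @param n_cardiac,n_resp,n_interaction harmonic counts (>= 0).
#' @return a [nuisance_design()] with provenance `"retroicor"`; columns that
#'   came out constant (degenerate phases) are listed in attribute
#'   `degenerate`.
#' @export
retroicor_design <- function(phi_c, phi_r, n_cardiac = 3L, n_resp = 4L,
                             n_interaction = 1L) {
  if (n_cardiac < 0 || n_resp < 0 || n_interaction < 0)
    stop("harmonic counts must be >= 0", call. = FALSE)
  stopifnot(length(phi_c) == length(phi_r))
  cols <- list(); labs <- character(0)
  add <- function(v, l) { cols[[length(cols) + 1L]] <<- v; labs <<- c(labs, l) }
  for (m in seq_len(n_cardiac)) {
    add(sin(m * phi_c), sprintf("cardiac_sin%d", m))
    add(cos(m * phi_c), sprintf("cardiac_cos%d", m))
  }
  for (m in seq_len(n_resp)) {
    add(sin(m * phi_r), sprintf("resp_sin%d", m))
    add(cos(m * phi_r), sprintf("resp_cos%d", m))
  }
  for (m in seq_len(n_interaction)) {
    add(sin(m * (phi_c + phi_r)), sprintf("interaction_sum_sin%d", m))
    add(cos(m * (phi_c + phi_r)), sprintf("interaction_sum_cos%d", m))
    add(sin(m * (phi_c - phi_r)), sprintf("interaction_diff_sin%d", m))
    add(cos(m * (phi_c - phi_r)), sprintf("interaction_diff_cos%d", m))
  }
  if (!length(cols)) stop("no regressors requested", call. = FALSE)
  X <- do.call(cbind, cols)
  degen <- labs[apply(X, 2, function(v) stats::sd(v) == 0)]
  zero <- colSums(X != 0) == 0L   # e.g. sin columns of an all-zero phase
  if (any(zero)) {
    degen <- union(degen, labs[zero])
    X <- X[, !zero, drop = FALSE]
    labs <- labs[!zero]
  }
  d <- nuisance_design(X, "retroicor", labs)
  attr(d, "degenerate") <- degen
  attr(d, "n_columns_requested") <- 2L * (n_cardiac + n_resp) +
    4L * n_interaction
  d
}

#' CompCor: principal components of a noise compartment
#'
#' Extracts the leading principal components over time of the (unsmoothed)
#' CSF voxel series: each voxel series is demeaned and variance-normalized,
#' the temporal components are returned unit-norm in decreasing
#' explained-variance order, with a deterministic sign convention (the
#' largest-magnitude voxel loading of each component is positive).
#'
#' @param img a [bold_image] (unsmoothed).
#' @param csf_mask logical 3D array; must contain at least `n_components`
#'   voxels with temporal variance.
#' @param n_components number of components (>= 1).
#' @return a [nuisance_design()] with provenance `"compcor"` and attribute
#'   `explained_variance` (the eigenvalues of the normalized voxel
#'   covariance, all of them, decreasing).
#' @export
compcor <- function(img, csf_mask, n_components) {
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  Y <- mask_series(img, csf_mask)
  Y <- sweep(Y, 2, colMeans(Y))
  sdev <- sqrt(colSums(Y^2) / (nrow(Y) - 1))
  keep <- sdev > 0
  Y <- sweep(Y[, keep, drop = FALSE], 2, sdev[keep], "/")
  if (ncol(Y) < n_components)
    stop(sprintf("only %d usable CSF voxels for %d components",
                 ncol(Y), n_components), call. = FALSE)
  sv <- svd(Y, nu = n_components, nv = n_components)
  U <- sv$u
  for (j in seq_len(n_components)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) U[, j] <- -U[, j]
  }
  d <- nuisance_design(U, "compcor", sprintf("compcor%d", seq_len(n_components)))
  attr(d, "explained_variance") <- sv$d^2 / (nrow(Y) - 1)
  d
}

#' Discrete cosine detrending basis
#'
#' The `n_functions` lowest-frequency non-constant DCT-II basis vectors,
#' unit-norm and mutually orthogonal; the classic slow-drift model.
#'
#' @param n_volumes number of time points.
#' @param n_functions number of basis functions (< `n_volumes`).
#' @return a [nuisance_design()] with provenance `"dct"`.
#' @export
dct_basis <- function(n_volumes, n_functions = 5L) {
  if (n_functions >= n_volumes)
    stop("n_functions must be < n_volumes", call. = FALSE)
  if (n_functions < 1L) stop("n_functions must be >= 1", call. = FALSE)
  t <- seq_len(n_volumes)
  X <- vapply(seq_len(n_functions), function(j)
    sqrt(2 / n_volumes) * cos(pi * (2 * t - 1) * j / (2 * n_volumes)),
    numeric(n_volumes))
  nuisance_design(X, "dct", sprintf("dct%d", seq_len(n_functions)))
}

#' Motion regressors as a nuisance design
#'
#' @param motion realignment table (n_volumes x p).
#' @return a [nuisance_design()] with provenance `"motion"`.
#' @export
motion_design <- function(motion) {
  m <- as.matrix(motion)
  labs <- colnames(m)
  if (is.null(labs)) labs <- sprintf("motion%d", seq_len(ncol(m)))
  nuisance_design(m, "motion", labs)
}
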