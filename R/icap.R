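# internal: lower-triangular Toeplitz convolution operator for kernel h
hrf_operator <- function(h, n) {
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    len <- min(length(h), n - j + 1L)
    H[j:(j + len - 1L), j] <- h[seq_len(len)]
  }
  H
}

#' Regularized hemodynamic deconvolution
#'
#' Recovers activity-inducing signals from (unfiltered, denoised) BOLD by
#' solving, per voxel, `min 0.5 ||y - H a||^2 + lambda TV(a)` where `H` is
#' convolution with the HRF and `TV` the total variation of `a` (an L1
#' penalty on its temporal increments, promoting piecewise-constant
#' activity whose jumps are the innovations). The solver is a monotone
#' accelerated proximal-gradient scheme: gradient steps on the quadratic
#' data term with an exact 1-D total-variation proximal map (Condat's
#' direct algorithm, compiled), keeping each voxel's penalized objective
#' non-increasing by construction. Iteration stops when the relative
#' change falls below `tol` or at `max_iter`.
#'
#' The default per-voxel `lambda` comes from a robust noise estimate (median
#' absolute deviation of the first differences of the series) scaled by the
#' universal threshold `sqrt(2 log T)` and a global multiplier.
#'
#' @param img a denoised, *not* band-passed [bold_image] (the deconvolution
#'   uses the full-spectrum signal).
#' @param mask logical 3D array selecting the voxels to deconvolve.
#' @param lambda optional global regularization weight (scalar) overriding
#'   the per-voxel estimate.
#' @param hrf HRF kernel; defaults to [hrf_kernel()] at the image TR.
#' @param lambda_mult global multiplier on the per-voxel lambda.
#' @param max_iter,tol iteration budget and relative-change tolerance.
#' @return object of class `activity_signals`: `activity` (voxels x time),
#'   `innovations` (voxels x time-1, the temporal derivative), `mask`,
#'   `converged`, `n_iter`, `objective_path` (iterations x voxels) and the
#'   settings used.
#' @export
deconvolve <- function(img, mask, lambda = NULL, hrf = NULL,
                       lambda_mult = 0.5, max_iter = 2500L, tol = 1e-6) {
  stopifnot(inherits(img, "bold_image"))
  if (is.null(hrf)) hrf <- hrf_kernel(img$tr_seconds)
  if (!is.null(lambda) && lambda <= 0)
    stop("lambda must be > 0", call. = FALSE)
  Y <- mask_series(img, mask)                       # T x V
  T <- nrow(Y); V <- ncol(Y)
  Y <- sweep(Y, 2, colMeans(Y))
  H <- hrf_operator(hrf, T)
  # absorb a free per-voxel baseline: project the constant out of the data
  # and of the operator's columns, so the causal onset transient is not
  # forced to fit the demeaned baseline
  H <- sweep(H, 2, colMeans(H))
  L <- (svd(H, nu = 0, nv = 0)$d[1])^2
  if (is.null(lambda)) {
    sigma <- apply(Y, 2, function(y) stats::mad(diff(y)) / sqrt(2))
    sigma[sigma == 0] <- 1e-12
    lam <- lambda_mult * sigma * sqrt(2 * log(T))
  } else {
    lam <- rep(lambda, V)
  }
  objective <- function(A) {
    R <- H %*% A - Y
    0.5 * colSums(R^2) + lam * colSums(abs(diff(A)))
  }
  Xb <- matrix(0, T, V); Xprev <- Xb; Z <- Xb; Wprev <- Xb
  tk <- 1
  Fb <- objective(Xb)
  obj_path <- matrix(NA_real_, max_iter, V)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    G <- crossprod(H, H %*% Z - Y)
    Wz <- .tv1d_prox_mat(Z - G / L, lam / L)
    Fz <- objective(Wz)
    better <- Fz <= Fb
    Xnew <- Xb
    Xnew[, better] <- Wz[, better]
    Fb <- pmin(Fz, Fb)
    obj_path[it, ] <- Fb
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Xnew + (tk / tnew) * (Wz - Xnew) + ((tk - 1) / tnew) * (Xnew - Xprev)
    # both the monotone iterate and the raw prox iterate must stabilize
    # (the safeguard can hold Xb fixed while the momentum point explores)
    delta_x <- max(sqrt(colSums((Xnew - Xb)^2)) /
                     pmax(sqrt(colSums(Xb^2)), 1e-12))
    delta_w <- max(sqrt(colSums((Wz - Wprev)^2)) /
                     pmax(sqrt(colSums(Wprev^2)), 1e-12))
    Xprev <- Xb <- Xnew
    Wprev <- Wz
    tk <- tnew
    if (max(delta_x, delta_w) < tol) { converged <- TRUE; break }
  }
  structure(list(activity = t(Xb), innovations = t(diff(Xb)),
                 mask = mask, converged = converged, n_iter = it,
                 objective_path = obj_path[seq_len(it), , drop = FALSE],
                 settings = list(lambda = lam, lambda_mult = lambda_mult,
                                 hrf = hrf, tol = tol, max_iter = max_iter)),
            class = "activity_signals")
}

# internal: phase-randomized surrogates of one series; returns n x n_surr
phase_randomized <- function(x, n_surr) {
  n <- length(x)
  X <- stats::fft(x)
  m <- floor((n - 1) / 2)
  amp <- Mod(X)
  out <- matrix(0i, n, n_surr)
  out[1, ] <- X[1]
  if (m >= 1) {
    th <- matrix(stats::runif(m * n_surr, 0, 2 * pi), m, n_surr)
    out[2:(m + 1), ] <- amp[2:(m + 1)] * exp(1i * th)
    out[n:(n - m + 1), ] <- Conj(out[2:(m + 1), , drop = FALSE])
  }
  if (n %% 2 == 0) {
    sgn <- matrix(sample(c(-1, 1), n_surr, replace = TRUE), 1)
    out[n / 2 + 1, ] <- amp[n / 2 + 1] * sgn
  }
  Re(stats::mvfft(out, inverse = TRUE)) / n
}

#' Select significant innovation frames
#'
#' Thresholds each voxel's innovation series against phase-randomized
#' surrogates of itself: the per-voxel two-sided threshold is the
#' `1 - alpha` quantile of the surrogate amplitudes, and a frame is retained
#' when the fraction of suprathreshold voxels reaches
#' `min_active_fraction`.
#'
#' @param inn an `activity_signals` object or a plain voxels x (time-1)
#'   innovation matrix.
#' @param alpha two-sided significance level.
#' @param n_surrogates surrogates per voxel (>= 20).
#' @param min_active_fraction minimum suprathreshold voxel fraction for a
#'   frame to be retained.
#' @param seed RNG seed (surrogates are the only randomness).
#' @return object of class `innovation_frames`: `innovations`, `selected`
#'   (frame indices), `thresholds` (per voxel), `active_fraction` per frame
#'   and the selection settings.
#' @export
select_significant_frames <- function(inn, alpha = 0.05, n_surrogates = 100L,
                                      min_active_fraction = 0.05, seed = 1L) {
  if (inherits(inn, "activity_signals")) inn <- inn$innovations
  inn <- as.matrix(inn)
  if (n_surrogates < 20L) stop("n_surrogates must be >= 20", call. = FALSE)
  set.seed(seed)
  V <- nrow(inn)
  thr <- numeric(V)
  for (v in seq_len(V)) {
    surr <- phase_randomized(inn[v, ], n_surrogates)
    thr[v] <- stats::quantile(abs(surr), 1 - alpha, names = FALSE)
  }
  active <- abs(inn) > thr
  frac <- colMeans(active)
  selected <- which(frac >= min_active_fraction)
  if (!length(selected))
    stop(sprintf(paste0("no frame reaches min_active_fraction = %g ",
                        "(max active fraction observed: %.3f)"),
                 min_active_fraction, max(frac)), call. = FALSE)
  structure(list(innovations = inn, selected = selected, thresholds = thr,
                 active_fraction = frac,
                 settings = list(alpha = alpha, n_surrogates = n_surrogates,
                                 min_active_fraction = min_active_fraction,
                                 seed = seed)),
            class = "innovation_frames")
}

# internal: frames-by-voxels matrix from an innovation_frames object (or a
# plain voxels x frames matrix). For selected innovation frames, voxels
# below their significance threshold are zeroed and each frame is rectified
# to its dominant transition polarity (a frame records one event's rise or
# fall; the opposite-sign voxels belong to other events' concurrent
# transitions and would contaminate the spatial pattern). Frames left
# all-zero are dropped.
frames_matrix <- function(frames, threshold = TRUE) {
  if (inherits(frames, "innovation_frames")) {
    X <- frames$innovations[, frames$selected, drop = FALSE]
    if (threshold) {
      X <- X * (abs(X) > frames$thresholds)
      pos <- colSums(X * (X > 0))
      neg <- -colSums(X * (X < 0))
      dom_neg <- pos < neg
      Xr <- pmax(X, 0)
      Xr[, dom_neg] <- -pmin(X[, dom_neg, drop = FALSE], 0)
      X <- Xr
    }
    keep <- colSums(X != 0) > 0
    list(X = t(X[, keep, drop = FALSE]), index = frames$selected[keep])
  } else {
    X <- as.matrix(frames)
    list(X = t(X), index = seq_len(ncol(X)))
  }
}

# internal: spherical K-means with polarity folding (a frame and its
# negation are equivalent). X: frames x voxels. Returns assignment, signs,
# unit centroids and total dispersion sum(1 - |cos|).
fold_kmeans_once <- function(X, K, max_iter = 100L, max_repairs = 10L) {
  F <- nrow(X)
  nrm <- sqrt(rowSums(X^2)); nrm[nrm == 0] <- 1
  Xn <- X / nrm
  # kmeans++-style seeding on the folded cosine distance
  first <- sample.int(F, 1L)
  centers <- first
  d2 <- (1 - abs(Xn %*% Xn[first, ]))^2
  while (length(centers) < K) {
    d2[centers] <- 0
    nxt <- if (sum(d2) > 0) sample.int(F, 1L, prob = d2) else
      sample.int(F, 1L)
    centers <- c(centers, nxt)
    d2 <- pmin(d2, (1 - abs(Xn %*% Xn[nxt, ]))^2)
  }
  Cn <- Xn[centers, , drop = FALSE]
  assign_prev <- rep(0L, F)
  repairs <- 0L
  for (iter in seq_len(max_iter)) {
    sim <- Xn %*% t(Cn)                   # F x K cosines
    a <- max.col(abs(sim), ties.method = "first")
    s <- sign(sim[cbind(seq_len(F), a)]); s[s == 0] <- 1
    for (k in seq_len(K)) {
      mem <- which(a == k)
      if (!length(mem)) {
        if (repairs >= max_repairs) next
        repairs <- repairs + 1L
        worst <- which.min(abs(sim[cbind(seq_len(F), a)]))
        Cn[k, ] <- Xn[worst, ]
        next
      }
      ck <- colSums(Xn[mem, , drop = FALSE] * s[mem])
      n2 <- sqrt(sum(ck^2))
      if (n2 > 0) Cn[k, ] <- ck / n2
    }
    if (identical(a, assign_prev)) break
    assign_prev <- a
  }
  sim <- Xn %*% t(Cn)
  a <- max.col(abs(sim), ties.method = "first")
  s <- sign(sim[cbind(seq_len(F), a)]); s[s == 0] <- 1
  disp <- sum(1 - abs(sim[cbind(seq_len(F), a)]))
  list(assignment = a, signs = s, centroids = Cn, dispersion = disp,
       repairs = repairs)
}

#' Temporal K-means of significant innovation frames
#'
#' Clusters the selected innovation frames with cosine distance on
#' polarity-folded frames (a frame and its negation belong together), best
#' of `n_restarts` by within-cluster dispersion. Each cluster's spatial map
#' is the z-scored mean of its member frames after sign alignment.
#'
#' @param frames an `innovation_frames` object (selected frames, voxels
#'   below their significance threshold zeroed), or a voxels x frames
#'   matrix (all columns used as-is).
#' @param K number of clusters (<= number of frames).
#' @param n_restarts K-means restarts.
#' @param seed RNG seed.
#' @param distance `"cosine"` (folded, default) or `"euclidean"`
#'   (plain [stats::kmeans()] on raw frames).
#' @return object of class `icap_set`: `maps` (voxels x K, z-scored),
#'   `assignment` and `signs` per frame, `K`, `dispersion`, `frame_index`.
#' @export
cluster_frames <- function(frames, K, n_restarts = 20L, seed = 1L,
                           distance = c("cosine", "euclidean")) {
  distance <- match.arg(distance)
  fm <- frames_matrix(frames)
  X <- fm$X
  frame_index <- fm$index
  F <- nrow(X)
  if (F < K) stop("fewer selected frames than clusters", call. = FALSE)
  set.seed(seed)
  if (distance == "euclidean") {
    km <- stats::kmeans(X, centers = K, nstart = n_restarts, iter.max = 100)
    a <- km$cluster; s <- rep(1, F); disp <- km$tot.withinss
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- fold_kmeans_once(X, K)
      if (is.null(best) || fit$dispersion < best$dispersion) best <- fit
    }
    a <- best$assignment; s <- best$signs; disp <- best$dispersion
  }
  maps <- vapply(seq_len(K), function(k) {
    mem <- which(a == k)
    if (!length(mem)) return(rep(NA_real_, ncol(X)))
    m <- colSums(X[mem, , drop = FALSE] * s[mem]) / length(mem)
    (m - mean(m)) / stats::sd(m)
  }, numeric(ncol(X)))
  structure(list(maps = maps, assignment = a, signs = s, K = K,
                 dispersion = disp, frame_index = frame_index,
                 distance = distance),
            class = "icap_set")
}

#' @export
print.icap_set <- function(x, ...) {
  cat(sprintf("<icap_set> K = %d, %d frames, %s distance, dispersion %.3f\n",
              x$K, length(x$assignment), x$distance, x$dispersion))
  invisible(x)
}

#' Consensus clustering stability of the frame clusters
#'
#' Monti-style consensus: recluster random frame subsamples, accumulate the
#' co-assignment frequency of every frame pair among the subsamples
#' containing both, and score each final cluster by the mean consensus of
#' its within-cluster pairs.
#'
#' @inheritParams cluster_frames
#' @param n_subsamples number of random subsamples; with fewer than 2 the
#'   scores are trivially 1 and flagged uninformative.
#' @param subsample_fraction fraction of frames per subsample.
#' @param n_restarts restarts per subsample clustering.
#' @return list with `scores` (per final cluster, in `[0, 1]`),
#'   `mean_consensus`, `consensus_matrix`, `assignment` (the full-data
#'   clustering) and `uninformative`.
#' @export
consensus_cluster <- function(frames, K, n_subsamples = 50L,
                              subsample_fraction = 0.8, seed = 1L,
                              n_restarts = 5L) {
  full <- cluster_frames(frames, K, n_restarts = max(n_restarts, 10L),
                         seed = seed)
  a <- full$assignment
  F <- length(a)
  if (n_subsamples < 2L) {
    return(list(scores = rep(1, K), mean_consensus = 1,
                consensus_matrix = NULL, assignment = a,
                uninformative = TRUE))
  }
  X <- frames_matrix(frames)$X
  set.seed(seed + 1L)
  co <- matrix(0, F, F); npair <- matrix(0, F, F)
  m <- max(K, round(subsample_fraction * F))
  for (b in seq_len(n_subsamples)) {
    idx <- sort(sample.int(F, m))
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- fold_kmeans_once(X[idx, , drop = FALSE], K)
      if (is.null(best) || fit$dispersion < best$dispersion) best <- fit
    }
    same <- outer(best$assignment, best$assignment, "==") * 1
    co[idx, idx] <- co[idx, idx] + same
    npair[idx, idx] <- npair[idx, idx] + 1
  }
  cons <- ifelse(npair > 0, co / pmax(npair, 1), 0)
  scores <- vapply(seq_len(K), function(k) {
    mem <- which(a == k)
    if (length(mem) < 2L) return(1)
    sub <- cons[mem, mem]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  list(scores = scores, mean_consensus = mean(scores),
       consensus_matrix = cons, assignment = a, uninformative = FALSE)
}
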