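# small controlled deconvolution fixture: a few voxels driven by known
# activity through the HRF operator
deconv_fixture <- function(T = 120, tr = 1.55, noise = 0.01, seed = 1) {
  h <- hrf_kernel(tr)
  H <- cordmap:::hrf_operator(h, T)
  set.seed(seed)
  a_step <- c(rep(0, 49), rep(1, T - 49))
  y <- cbind(H %*% a_step + rnorm(T, 0, noise),
             rep(3, T) + rnorm(T, 0, noise))    # constant measured series
  img <- bold_image(array(t(y), c(2, 1, 1, T)), tr)
  list(img = img, mask = array(TRUE, c(2, 1, 1)), H = H, t0 = 50)
}

test_that("TV proximal map satisfies its optimality conditions", {
  # oracle: KKT for min 0.5||x - y||^2 + lambda TV(x): the running sum of
  # (y - x) stays within [-lambda, lambda], ends at 0, and touches the
  # bound exactly at jumps
  set.seed(42)
  for (lam in c(0.5, 2.5, 10)) {
    y <- cumsum(rnorm(80))
    x <- cordmap:::.tv1d_prox_mat(matrix(y), lam)[, 1]
    u <- cumsum(y - x)
    expect_lte(max(abs(u)), lam + 1e-8)
    expect_lt(abs(u[length(u)]), 1e-8)
    jumps <- which(abs(diff(x)) > 1e-10)
    if (length(jumps))
      expect_true(all(abs(abs(u[jumps]) - lam) < 1e-8))
  }
})

test_that("deconvolution recovers a planted onset within one volume", {
  fx <- deconv_fixture(noise = 0)
  act <- deconvolve(fx$img, fx$mask, lambda = 0.1)
  expect_true(act$converged)
  inn <- act$innovations
  expect_lte(abs(which.max(abs(inn[1, ])) - (fx$t0 - 1)), 1)
})

test_that("constant input yields constant activity, no innovations", {
  fx <- deconv_fixture(noise = 0)
  act <- deconvolve(fx$img, fx$mask, lambda = 0.5)
  expect_lt(max(abs(act$innovations[2, ])), 1e-8)
})

test_that("infinite regularization flattens the activity", {
  fx <- deconv_fixture()
  act <- deconvolve(fx$img, fx$mask, lambda = 1e6)
  expect_lt(max(abs(act$innovations)), 1e-8)
})

test_that("the penalized objective is non-increasing along iterations", {
  set.seed(9)
  T <- 100
  h <- hrf_kernel(1.55)
  H <- cordmap:::hrf_operator(h, T)
  A <- matrix(0, T, 20)
  for (v in 1:20) A[sample(T, 3), v] <- runif(3, 0.5, 2)
  Y <- H %*% apply(A, 2, cumsum) / 10 + matrix(rnorm(T * 20, 0, 0.1), T)
  img <- bold_image(array(t(Y), c(20, 1, 1, T)), 1.55)
  act <- deconvolve(img, array(TRUE, c(20, 1, 1)))
  expect_true(all(apply(act$objective_path, 2,
                        function(o) all(diff(o) <= 1e-10))))
})

test_that("frame selection is calibrated on white-noise innovations", {
  frac <- vapply(1:10, function(seed) {
    set.seed(seed)
    inn <- matrix(rnorm(200 * 99), 200, 99)
    n_sel <- tryCatch(
      length(select_significant_frames(inn, min_active_fraction = 0.1,
                                       seed = seed)$selected),
      error = function(e) 0L)                  # empty selection errors out
    n_sel / ncol(inn)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("alpha = 1 retains every frame", {
  set.seed(3)
  inn <- matrix(rnorm(30 * 50), 30, 50)
  sel <- select_significant_frames(inn, alpha = 1, seed = 1)
  expect_equal(sel$selected, seq_len(50))
})

test_that("selection is deterministic given the seed and errors when empty", {
  set.seed(4)
  inn <- matrix(rnorm(40 * 60), 40, 60)
  a <- select_significant_frames(inn, seed = 7)
  b <- select_significant_frames(inn, seed = 7)
  expect_identical(a$selected, b$selected)
  expect_identical(a$thresholds, b$thresholds)
  expect_error(select_significant_frames(inn, min_active_fraction = 1.1,
                                         seed = 1),
               "min_active_fraction")
  expect_error(select_significant_frames(inn, n_surrogates = 5, seed = 1),
               ">= 20")
})

test_that("planted orthogonal templates are recovered bijectively", {
  set.seed(11)
  V <- 120; K <- 4
  templates <- matrix(0, V, K)
  for (k in seq_len(K)) templates[((k - 1) * 30 + 1):(k * 30), k] <- 1
  frames <- templates[, rep(seq_len(K), each = 12)]
  frames <- frames * rep(runif(K * 12, 0.8, 1.2), each = V)
  frames <- frames + matrix(rnorm(V * K * 12, 0, 0.02), V)
  set <- cluster_frames(frames, K, seed = 2)
  cc <- abs(cor(set$maps, templates))
  best <- apply(cc, 1, which.max)
  expect_setequal(best, seq_len(K))
  expect_true(all(cc[cbind(seq_len(K), best)] >= 0.99))
})

test_that("K = 1 reduces to the z-scored mean of folded frames", {
  set.seed(12)
  frames <- matrix(rnorm(50 * 8), 50, 8)
  base <- abs(rnorm(50)) + 0.5
  frames <- base %o% runif(8, 0.5, 2) * sample(c(-1, 1), 8, TRUE)[col(frames)]
  set <- cluster_frames(frames, 1, seed = 1)
  expect_equal(dim(set$maps), c(50L, 1L))
  expect_gt(abs(cor(set$maps[, 1], base)), 0.999)
})

test_that("duplicating frames and flipping polarity leave maps unchanged", {
  set.seed(13)
  V <- 60
  templates <- cbind(c(rep(1, 30), rep(0, 30)), c(rep(0, 30), rep(1, 30)))
  frames <- templates[, rep(1:2, each = 8)] +
    matrix(rnorm(V * 16, 0, 0.05), V)
  base <- cluster_frames(frames, 2, seed = 5)
  dup <- cluster_frames(cbind(frames, frames), 2, seed = 5)
  flip <- frames; flip[, 3] <- -flip[, 3]
  flp <- cluster_frames(flip, 2, seed = 5)
  align <- function(a, b) {
    cc <- abs(cor(a, b))
    mean(cc[cbind(seq_len(ncol(a)), apply(cc, 1, which.max))])
  }
  expect_gt(align(base$maps, dup$maps), 0.999)
  expect_gt(align(base$maps, flp$maps), 0.999)
})

test_that("consensus is 1 for separated clusters, lower for a single cloud", {
  set.seed(14)
  V <- 60
  templates <- cbind(c(rep(1, 30), rep(0, 30)), c(rep(0, 30), rep(1, 30)))
  frames <- templates[, rep(1:2, each = 10)] +
    matrix(rnorm(V * 20, 0, 0.02), V)
  cc <- consensus_cluster(frames, 2, n_subsamples = 30, seed = 3)
  expect_equal(cc$scores, c(1, 1))
  # isotropic cloud: ambiguous clustering
  null_mean <- vapply(1:10, function(seed) {
    set.seed(seed)
    cloud <- matrix(rnorm(40 * 30), 40, 30)
    consensus_cluster(cloud, 2, n_subsamples = 20,
                      seed = seed)$mean_consensus
  }, numeric(1))
  expect_lt(mean(null_mean), 0.9)
  # single resample is uninformative
  one <- consensus_cluster(frames, 2, n_subsamples = 1, seed = 1)
  expect_true(one$uninformative)
  expect_equal(one$scores, c(1, 1))
})

test_that("phantom events and segments are recovered by the iCAP chain", {
  ph <- default_phantom()
  des <- truth_design(ph, "cord")
  dn <- denoise(ph$cord, des, apply_bandpass = FALSE)
  sm <- smooth_bold(dn, c(3, 3, 6))
  act <- deconvolve(sm, ph$truth$gm_masks$cord)
  expect_true(act$converged)
  fr <- select_significant_frames(act, seed = 1)
  ev_frames <- which(colSums(ph$truth$event_trains) > 0)
  recall <- mean(vapply(ev_frames, function(t)
    any(abs(fr$selected - (t - 1)) <= 1), logical(1)))
  expect_gte(recall, 0.9)
  set <- cluster_frames(fr, 7, seed = 1)
  arr <- array(0L, dim(ph$truth$cord_labels$data))
  arr[which(ph$truth$gm_masks$cord)] <- max.col(set$maps,
                                                ties.method = "first")
  m <- match_labels_max_weight(label_map(arr), ph$truth$cord_labels)
  expect_gte(m$mean_dice, 0.75)
})
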