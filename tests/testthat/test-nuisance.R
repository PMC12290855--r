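test_that("cardiac phase interpolates linearly between peaks", {
  card <- physio_trace(rep(0, 10), 100, "cardiac",
                       peak_times_seconds = c(0, 1, 2))
  resp <- physio_trace(sin(2 * pi * 0.3 * seq(0, 2, by = 0.01)), 100,
                       "respiratory")
  ph <- retroicor_phases(card, resp, c(0, 0.5, 1))
  expect_equal(ph$phi_c, c(0, pi, 0))          # peak -> 0 boundary convention
  expect_error(
    retroicor_phases(physio_trace(rep(0, 10), 100, "cardiac",
                                  peak_times_seconds = 1),
                     resp, 0.5),
    "2 cardiac peaks")
})

test_that("respiratory phase advances monotonically within half-cycles", {
  # analytic sinusoidal belt: one full cycle of 10 s
  t_hi <- seq(0, 20, by = 0.01)
  resp <- physio_trace(sin(2 * pi * 0.1 * t_hi), 100, "respiratory")
  card <- physio_trace(rep(0, 10), 100, "cardiac",
                       peak_times_seconds = c(0, 1))
  # inhalation: t in (0, 2.4); exhalation: t in (2.6, 7.4)
  vt_up <- seq(0.1, 2.3, by = 0.2)
  vt_dn <- seq(2.7, 7.3, by = 0.2)
  up <- retroicor_phases(card, resp, vt_up)$phi_r
  dn <- retroicor_phases(card, resp, vt_dn)$phi_r
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) > 0))               # -pi side rises back to 0
  expect_true(all(up >= 0 & up <= pi))
  expect_true(all(dn >= -pi & dn <= 0))
})

test_that("RETROICOR expansion yields the printed 18 regressors", {
  phi <- stats::runif(50, 0, 2 * pi)
  d <- retroicor_design(phi, stats::runif(50, -pi, pi))
  expect_equal(ncol(d), 18L)
  expect_equal(attr(d, "n_columns_requested"), 18L)
  expect_setequal(unique(attr(d, "provenance")), "retroicor")
  # reduced harmonic counts
  d4 <- retroicor_design(phi, stats::runif(50, -pi, pi),
                         n_cardiac = 1, n_resp = 1, n_interaction = 0)
  expect_equal(ncol(d4), 4L)
  expect_error(retroicor_design(phi, phi, n_cardiac = -1), ">= 0")
})

test_that("degenerate all-zero phases are flagged, cosines kept", {
  phi_r <- stats::runif(30, -pi, pi)
  d <- retroicor_design(rep(0, 30), phi_r)
  # cardiac sines are identically zero -> dropped and reported
  expect_true(all(sprintf("cardiac_sin%d", 1:3) %in% attr(d, "degenerate")))
  expect_false(any(sprintf("cardiac_sin%d", 1:3) %in% colnames(d)))
  # cardiac cosines are constant 1 -> kept but flagged degenerate
  expect_true(all(sprintf("cardiac_cos%d", 1:3) %in% attr(d, "degenerate")))
  expect_true(all(d[, "cardiac_cos1"] == 1))
})

test_that("compcor recovers rank-1 structure and is orthonormal", {
  set.seed(5)
  T <- 60
  base <- sin(seq_len(T) / 3)
  arr <- array(0, c(10, 1, 1, T))
  w <- runif(10, 0.5, 2)
  for (v in 1:10) arr[v, 1, 1, ] <- w[v] * base
  img <- bold_image(arr, 1.55)
  mask <- array(TRUE, c(10, 1, 1))
  d <- compcor(img, mask, 1)
  expect_equal(abs(cor(d[, 1], base)), 1, tolerance = 1e-10)
  # orthogonality on a noisy instance
  set.seed(6)
  arr2 <- array(rnorm(30 * 80), c(30, 1, 1, 80))
  d2 <- compcor(bold_image(arr2, 1), array(TRUE, c(30, 1, 1)), 5)
  g <- crossprod(unclass(d2))
  expect_lt(max(abs(g - diag(5))), 1e-10)
  expect_error(compcor(img, mask, 11), "11 components")
})

test_that("compcor variances equal a brute-force eigendecomposition", {
  set.seed(7)
  arr <- array(rnorm(30 * 50), c(30, 1, 1, 50))
  img <- bold_image(arr, 1)
  mask <- array(TRUE, c(30, 1, 1))
  d <- compcor(img, mask, 3)
  # oracle: full eigendecomposition of the normalized voxel covariance
  Y <- scale(t(matrix(arr, 30, 50)))           # T x V, demeaned, unit sd
  ev <- eigen(crossprod(Y) / (nrow(Y) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  got <- attr(d, "explained_variance")
  expect_equal(got[seq_along(ev)], ev, tolerance = 1e-8)
})

test_that("DCT basis is orthonormal with low-frequency structure", {
  d <- dct_basis(230, 5)
  g <- crossprod(unclass(d))
  expect_lt(max(abs(g - diag(5))), 1e-10)
  # lowest-frequency cosine crosses zero exactly once
  expect_equal(sum(diff(sign(d[, 1])) != 0), 1)
  # a linear ramp is almost entirely inside the 5-function span
  ramp <- seq_len(230); ramp <- ramp - mean(ramp)
  res <- lm.fit(unclass(d), ramp)$residuals
  expect_lt(sum(res^2) / sum(ramp^2), 0.01)
  expect_error(dct_basis(10, 10), "n_functions")
})

test_that("design containers validate inputs and combine cleanly", {
  expect_error(nuisance_design(matrix(0, 5, 1), "dct"), "all-zero")
  expect_error(nuisance_design(matrix(1, 5, 1), "banana"), "provenance")
  a <- dct_basis(40, 2)
  b <- motion_design(matrix(rnorm(40 * 2), 40,
                            dimnames = list(NULL, c("tx", "ty"))))
  ab <- combine_designs(a, b)
  expect_equal(ncol(ab), 4L)
  expect_equal(attr(ab, "provenance"), c("dct", "dct", "motion", "motion"))
  expect_error(combine_designs(a, dct_basis(39, 2)), "different numbers")
})
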