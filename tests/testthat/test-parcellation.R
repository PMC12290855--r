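rand_label_arrays <- function(n, K, Katlas = K, seed = 1) {
  set.seed(seed)
  list(cl = array(sample.int(K, n, replace = TRUE), c(n, 1, 1)),
       at = array(sample.int(Katlas, n, replace = TRUE), c(n, 1, 1)))
}

# exhaustive maximum-weight assignment oracle (permutations of the larger
# side restricted to injective maps rows -> cols)
brute_match <- function(W) {
  nr <- nrow(W); nc <- ncol(W)
  stopifnot(nr <= nc)
  best <- -Inf; best_perm <- NULL
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(nc))) {
    w <- sum(W[cbind(seq_len(nr), p[seq_len(nr)])])
    if (w > best) { best <- w; best_perm <- p[seq_len(nr)] }
  }
  list(weight = best, assignment = best_perm)
}

test_that("feature matrix is the clamped Fisher-z cross-correlation", {
  set.seed(1)
  T <- 60
  cord <- array(rnorm(4 * T), c(4, 1, 1, T))
  brain <- array(rnorm(3 * T), c(3, 1, 1, T))
  brain[1, 1, 1, ] <- cord[2, 1, 1, ]          # identical pair
  ci <- bold_image(cord, 1); bi <- bold_image(brain, 1)
  cm <- array(TRUE, c(4, 1, 1)); bm <- array(TRUE, c(3, 1, 1))
  Z <- fc_feature_matrix(ci, bi, cm, bm)
  expect_equal(dim(Z), c(4L, 3L))
  expect_equal(Z[2, 1], atanh(1 - 1e-7))       # clamp ceiling
  # against plain cor + atanh
  R <- cor(t(matrix(cord, 4, T)), t(matrix(brain, 3, T)))
  expect_equal(unclass(Z)[-c(2)], atanh(R)[-c(2)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("null feature entries center on zero", {
  set.seed(2)
  T <- 230
  ci <- bold_image(array(rnorm(20 * T), c(20, 1, 1, T)), 1.55)
  bi <- bold_image(array(rnorm(100 * T), c(100, 1, 1, T)), 1.55)
  Z <- fc_feature_matrix(ci, bi, array(TRUE, c(20, 1, 1)),
                         array(TRUE, c(100, 1, 1)))
  expect_lt(abs(mean(Z)), 0.02)
})

test_that("similarity equals a naive double-loop Pearson oracle", {
  set.seed(3)
  Z <- matrix(rnorm(60), 10, 6)
  S <- similarity_from_features(Z)
  for (i in 1:10) for (k in 1:10) {
    expect_equal(S[i, k], if (i == k) 1 else cor(Z[i, ], Z[k, ]),
                 tolerance = 1e-12)
  }
  # self and anti-similarity
  Z2 <- rbind(Z[1, ], Z[1, ], -Z[1, ])
  S2 <- similarity_from_features(Z2)
  expect_equal(S2[1, 2], 1, tolerance = 1e-12)
  expect_equal(S2[1, 3], -1, tolerance = 1e-12)
  # invariant under common affine rescaling of the columns of Z
  S3 <- similarity_from_features(2.5 * Z + 7)
  expect_equal(unclass(S3), unclass(S), tolerance = 1e-12)
})

test_that("group-mean similarity preserves structure", {
  set.seed(4)
  mk <- function() similarity_from_features(matrix(rnorm(40), 8, 5))
  s1 <- mk(); s2 <- mk()
  g <- group_mean_similarity(list(s1, s2))
  expect_equal(unclass(g), t(unclass(g)))
  expect_equal(diag(g), rep(1, 8))
  expect_true(all(g >= -1 & g <= 1))
  expect_equal(unclass(group_mean_similarity(list(s1))), unclass(s1),
               ignore_attr = TRUE)
  expect_equal(unclass(group_mean_similarity(list(s2, s1))), unclass(g),
               ignore_attr = TRUE)
  expect_error(group_mean_similarity(list(s1, similarity_from_features(
    matrix(rnorm(35), 7, 5)))), "different sizes")
})

test_that("hierarchical clustering recovers planted blocks and degenerate cuts", {
  n <- 12
  S <- matrix(0.1, n, n)
  S[1:6, 1:6] <- 0.9; S[7:12, 7:12] <- 0.9
  diag(S) <- 1
  sol <- hierarchical_cluster(structure(S, class = c("similarity_matrix",
                                                     "matrix")), c(2, n))
  lab <- sol$labels[, "2"]
  expect_equal(length(unique(lab[1:6])), 1L)
  expect_equal(length(unique(lab[7:12])), 1L)
  expect_false(lab[1] == lab[7])
  expect_equal(sort(unique(sol$labels[, as.character(n)])), 1:n)
  expect_error(hierarchical_cluster(S, n + 1), "k values")
})

test_that("average-linkage merges match a naive O(n^3) oracle", {
  # oracle: direct UPGMA agglomeration of D = 1 - S
  naive_upgma_heights <- function(D) {
    n <- nrow(D)
    active <- as.list(seq_len(n))
    heights <- numeric(0)
    Dm <- D
    repeat {
      m <- length(active)
      if (m == 1) break
      best <- c(Inf, 0, 0)
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        d <- mean(D[active[[i]], active[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
      heights <- c(heights, best[1])
      i <- best[2]; j <- best[3]
      active[[i]] <- c(active[[i]], active[[j]])
      active[[j]] <- NULL
    }
    heights
  }
  for (seed in 1:10) {
    set.seed(seed)
    Z <- matrix(rnorm(8 * 6), 8, 6)
    S <- similarity_from_features(Z)
    sol <- hierarchical_cluster(S, 2)
    expect_equal(sol$hclust$height, naive_upgma_heights(1 - unclass(S)),
                 tolerance = 1e-12)
  }
})

test_that("dice matches hand arithmetic and its edge conventions", {
  g <- c(4, 1, 1)
  a <- array(c(TRUE, TRUE, TRUE, TRUE), g)
  b <- array(c(TRUE, TRUE, TRUE, FALSE), g)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, array(FALSE, g)), 0)
  # |a| = 4, |b| = 3, overlap 3 -> 6/7
  expect_equal(dice(a, b), 6 / 7)
  ab <- array(c(TRUE, TRUE, FALSE, FALSE), g)
  bb <- array(c(TRUE, FALSE, TRUE, FALSE), g)
  expect_equal(dice(ab, bb), 2 * 1 / (2 + 2))
  expect_equal(dice(ab, bb), dice(bb, ab))               # symmetry
  e <- array(FALSE, g)
  expect_equal(as.numeric(dice(e, e)), 0)
  expect_true(attr(dice(e, e), "both_empty"))
  expect_error(dice(a, array(TRUE, c(2, 1, 1))), "same grid")
})

test_that("label matching equals the exhaustive 7! oracle", {
  for (seed in 1:20) {
    fx <- rand_label_arrays(300, 7, seed = seed)
    got <- match_labels_max_weight(fx$cl, fx$at)
    W <- matrix(0, 7, 7)
    for (i in 1:7) for (j in 1:7)
      W[i, j] <- dice(fx$cl == i, fx$at == j)
    oracle <- brute_match(W)
    expect_equal(got$total_weight, oracle$weight, tolerance = 1e-10)
    # optimality lower bound: at least the identity assignment
    expect_gte(got$total_weight, sum(diag(W)) - 1e-12)
  }
})

test_that("matching recovers identity and permutations exactly", {
  fx <- rand_label_arrays(200, 6, seed = 99)
  ident <- match_labels_max_weight(fx$cl, fx$cl)
  expect_equal(ident$pairs$cluster, ident$pairs$atlas)
  expect_equal(ident$mean_dice, 1)
  expect_equal(ident$sd_dice, 0)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  permuted <- array(perm[fx$cl], dim(fx$cl))
  m <- match_labels_max_weight(fx$cl, permuted)
  expect_equal(m$pairs$atlas[order(m$pairs$cluster)], perm)
  expect_equal(m$mean_dice, 1)
})

test_that("inter-subject profile stability behaves at both extremes", {
  set.seed(5)
  S <- similarity_from_features(matrix(rnorm(80), 16, 5))
  same <- intersubject_profile_stability(list(S, S, S))
  expect_equal(same$stability, rep(1, 16), tolerance = 1e-12)
  expect_equal(same$grand_mean, 1, tolerance = 1e-12)
  # independent subjects: grand mean near zero
  nulls <- lapply(1:6, function(i)
    similarity_from_features(matrix(rnorm(40 * 30), 40, 30)))
  ns <- intersubject_profile_stability(nulls)
  expect_lt(abs(ns$grand_mean), 0.1)
  # two subjects: symmetric in order
  two_ab <- intersubject_profile_stability(nulls[1:2])
  two_ba <- intersubject_profile_stability(nulls[2:1])
  expect_equal(two_ab$stability, two_ba$stability)
  expect_error(intersubject_profile_stability(nulls[1]), "2 subjects")
})

test_that("individual-to-group alignment matches a brute-force oracle", {
  set.seed(6)
  g <- sample.int(5, 400, replace = TRUE)
  # identity: alignment is the identity, heatmaps count every subject
  al <- subject_group_alignment(list(g, g), g)
  expect_equal(al$assignment[[1]], 1:5)
  expect_equal(al$aligned[[2]], g)
  for (k in 1:5) expect_true(all(al$heatmaps[g == k, k] == 2L))
  # permuted labels: permutation recovered
  perm <- c(4L, 5L, 1L, 3L, 2L)
  al2 <- subject_group_alignment(list(perm[g]), g)
  expect_equal(al2$assignment[[1]][perm], 1:5)
  expect_equal(al2$aligned[[1]], g)
  # random contingencies against the exhaustive oracle
  for (seed in 1:20) {
    set.seed(seed)
    il <- sample.int(5, 400, replace = TRUE)
    al3 <- subject_group_alignment(list(il), g)
    ct <- al3$contingency[[1]]                  # group x individual
    oracle <- brute_match(t(ct))
    got_w <- sum(ct[cbind(al3$assignment[[1]], 1:5)])
    expect_equal(got_w, oracle$weight, tolerance = 1e-10)
  }
})

test_that("fingerprints average member-voxel maps and are equivariant", {
  set.seed(7)
  Z1 <- matrix(rnorm(60), 10, 6)
  Z2 <- matrix(rnorm(60), 10, 6)
  labels <- rep(1:2, each = 5)
  fp <- cluster_fingerprints(labels, list(Z1, Z2))
  expect_equal(fp$fingerprints[1, ],
               (colMeans(Z1[1:5, ]) + colMeans(Z2[1:5, ])) / 2)
  # K = 1: whole-cord mean map
  fp1 <- cluster_fingerprints(rep(1L, 10), list(Z1))
  expect_equal(fp1$fingerprints[1, ], colMeans(Z1))
  # permuting cluster indices permutes fingerprints identically
  fp_sw <- cluster_fingerprints(3L - labels, list(Z1, Z2))
  expect_equal(fp_sw$fingerprints[2, ], fp$fingerprints[1, ])
  expect_warning(cluster_fingerprints(c(rep(1L, 9), 3L), list(Z1)),
                 "empty cluster")
})
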