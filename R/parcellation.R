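#' Cord-voxel x cortical-voxel Fisher-z feature matrix
#'
#' `Z[i, j] = atanh(r)` for the Pearson correlation between cord voxel `i`
#' and cortical voxel `j` (r clamped to `+/- (1 - 1e-7)`), i.e. every cord
#' voxel's FC profile with the sensorimotor cortex. Constant voxels get 0
#' entries and are counted as degenerate.
#'
#' @param cord_img,brain_img [bold_image]s of equal temporal length.
#' @param cord_mask,smc_mask non-empty logical 3D masks on the respective
#'   grids.
#' @return numeric matrix `|cord_mask|` x `|smc_mask|` of class
#'   `fc_feature_matrix`, with attributes `cord_idx`, `smc_idx` (voxel
#'   registries), `n_degenerate`.
#' @export
fc_feature_matrix <- function(cord_img, brain_img, cord_mask, smc_mask) {
  X <- mask_series(cord_img, cord_mask)
  Y <- mask_series(brain_img, smc_mask)
  if (nrow(X) != nrow(Y))
    stop("cord and brain runs have different temporal length", call. = FALSE)
  xs <- unit_columns(X); ys <- unit_columns(Y)
  R <- crossprod(xs$x, ys$x)
  R[xs$degenerate, ] <- 0
  R[, ys$degenerate] <- 0
  Z <- atanh(pmin(pmax(R, -(1 - 1e-7)), 1 - 1e-7))
  structure(Z, class = c("fc_feature_matrix", "matrix"),
            cord_idx = which(cord_mask), smc_idx = which(smc_mask),
            n_degenerate = sum(xs$degenerate) + sum(ys$degenerate))
}

# internal: center columns and scale to unit norm; flags zero-variance cols
unit_columns <- function(M) {
  M <- sweep(M, 2, colMeans(M))
  nrm <- sqrt(colSums(M^2))
  deg <- nrm == 0
  nrm[deg] <- 1
  list(x = sweep(M, 2, nrm, "/"), degenerate = deg)
}

#' Functional similarity matrix from FC profiles
#'
#' Row-wise Pearson correlation of the feature matrix: each cord voxel's
#' cortical profile is centered and scaled across cortical voxels, and
#' `S[i, k]` is the correlation of profiles `i` and `k`. The diagonal is
#' forced to 1; zero-variance profiles get similarity 0 and are flagged.
#'
#' @param Z an [fc_feature_matrix()] (or plain matrix) with >= 2 columns.
#' @return symmetric matrix of class `similarity_matrix`, unit diagonal,
#'   entries in `[-1, 1]`; attribute `n_degenerate`.
#' @export
similarity_from_features <- function(Z) {
  Z <- unclass(as.matrix(Z))
  if (ncol(Z) < 2L)
    stop("need at least 2 cortical voxels to correlate profiles",
         call. = FALSE)
  rs <- unit_columns(t(Z))          # rows of Z as unit columns
  S <- crossprod(rs$x)
  S[rs$degenerate, ] <- 0
  S[, rs$degenerate] <- 0
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  structure(S, class = c("similarity_matrix", "matrix"),
            n_degenerate = sum(rs$degenerate), provenance = "subject")
}

#' Group-mean similarity matrix
#'
#' @param s_list list of equally sized `similarity_matrix` objects.
#' @return their elementwise mean (symmetric, unit diagonal).
#' @export
group_mean_similarity <- function(s_list) {
  stopifnot(length(s_list) >= 1L)
  n <- unique(vapply(s_list, nrow, integer(1)))
  if (length(n) != 1L)
    stop("similarity matrices have different sizes", call. = FALSE)
  S <- Reduce(`+`, lapply(s_list, unclass)) / length(s_list)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  structure(S, class = c("similarity_matrix", "matrix"),
            provenance = "group-mean")
}

#' Average-linkage hierarchical clustering of the similarity matrix
#'
#' Agglomerates voxels on the dissimilarity `D = 1 - S` with average
#' linkage (UPGMA) and cuts the tree at each requested K.
#'
#' @param S a `similarity_matrix`.
#' @param k_values integer cluster counts, each in `[1, n]`.
#' @return object of class `cluster_solution`: `labels` (n x
#'   `length(k_values)` matrix, columns named by K), `hclust` (the merge
#'   tree), `k_values`.
#' @export
hierarchical_cluster <- function(S, k_values) {
  S <- unclass(as.matrix(S))
  n <- nrow(S)
  k_values <- as.integer(k_values)
  if (any(k_values < 1L | k_values > n))
    stop("k values must lie in [1, n]", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  labels <- vapply(k_values, function(k) stats::cutree(hc, k = k),
                   integer(n))
  colnames(labels) <- as.character(k_values)
  structure(list(labels = labels, hclust = hc, k_values = k_values),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d voxels, K = {%s}\n",
              nrow(x$labels), paste(x$k_values, collapse = ", ")))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2 |a & b| / (|a| + |b|)`; two empty masks give 0 (flagged via attribute
#' `both_empty`).
#'
#' @param a,b logical arrays on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("masks are not on the same grid", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0)
    return(structure(0, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

# internal: maximum-weight injective assignment between the rows and
# columns of a non-negative weight matrix; returns row -> column map (NA
# for unmatched rows)
max_weight_assignment <- function(W) {
  W <- as.matrix(W)
  nr <- nrow(W); nc <- ncol(W)
  Wpos <- pmax(W, 0)
  dimnames(Wpos) <- NULL          # keep igraph's matching as integer ids
  if (all(Wpos == 0)) return(rep(NA_integer_, nr))
  g <- igraph::graph_from_biadjacency_matrix(Wpos, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  out <- m$matching[seq_len(nr)]
  out <- ifelse(is.na(out), NA_integer_, as.integer(out) - nr)
  out
}

#' Match cluster labels to atlas levels by maximum-weight matching
#'
#' Builds the pairwise weight matrix (Dice by default, raw voxel overlap
#' optionally) between every cluster label and every atlas level and solves
#' the maximum-weight bipartite matching, so each cluster is paired with at
#' most one atlas level and vice versa.
#'
#' @param clusters,atlas [label_map]s (or integer arrays) on the same grid;
#'   label 0 is background.
#' @param weight `"dice"` or `"overlap"` (intersection voxel count).
#' @return object of class `match_report`: data.frame `pairs` (columns
#'   `cluster`, `atlas`, `weight`, `dice`), `mean_dice`, `sd_dice`,
#'   `total_weight`.
#' @export
match_labels_max_weight <- function(clusters, atlas,
                                    weight = c("dice", "overlap")) {
  weight <- match.arg(weight)
  ca <- if (inherits(clusters, "label_map")) clusters$data else clusters
  aa <- if (inherits(atlas, "label_map")) atlas$data else atlas
  if (!all(dim(ca) == dim(aa)))
    stop("cluster and atlas maps are not on the same grid", call. = FALSE)
  cl <- sort(unique(ca[ca > 0])); al <- sort(unique(aa[aa > 0]))
  if (!length(cl) || !length(al))
    stop("empty cluster or atlas map", call. = FALSE)
  Wd <- matrix(0, length(cl), length(al))
  Wo <- matrix(0, length(cl), length(al))
  for (i in seq_along(cl)) for (j in seq_along(al)) {
    mi <- ca == cl[i]; mj <- aa == al[j]
    Wo[i, j] <- sum(mi & mj)
    Wd[i, j] <- dice(mi, mj)
  }
  W <- if (weight == "dice") Wd else Wo
  asg <- max_weight_assignment(W)
  keep <- which(!is.na(asg))
  pairs <- data.frame(cluster = cl[keep], atlas = al[asg[keep]],
                      weight = W[cbind(keep, asg[keep])],
                      dice = Wd[cbind(keep, asg[keep])])
  structure(list(pairs = pairs, mean_dice = mean(pairs$dice),
                 sd_dice = stats::sd(pairs$dice),
                 total_weight = sum(pairs$weight), weight = weight),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d pair(s), mean Dice %.3f +/- %.3f\n",
              nrow(x$pairs), x$mean_dice,
              if (is.na(x$sd_dice)) 0 else x$sd_dice))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Inter-subject stability of similarity profiles
#'
#' For each voxel, the mean over subject pairs of the Pearson correlation
#' between that voxel's similarity profile (its matrix row, own diagonal
#' entry excluded) in the two subjects.
#'
#' @param s_list list of >= 2 equally sized per-subject
#'   `similarity_matrix` objects.
#' @return list with `stability` (per-voxel mean correlation),
#'   `grand_mean`, `n_pairs`.
#' @export
intersubject_profile_stability <- function(s_list) {
  if (length(s_list) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  n <- nrow(s_list[[1]])
  drop_diag <- function(S) {
    v <- as.vector(t(unclass(S)))
    matrix(v[-(seq_len(n) + (seq_len(n) - 1) * n)], n, n - 1, byrow = TRUE)
  }
  rows <- lapply(s_list, function(S) {
    M <- drop_diag(S)
    M <- M - rowMeans(M)
    nrm <- sqrt(rowSums(M^2)); nrm[nrm == 0] <- 1
    M / nrm
  })
  pairs <- utils::combn(length(s_list), 2)
  acc <- numeric(n)
  for (p in seq_len(ncol(pairs))) {
    acc <- acc + rowSums(rows[[pairs[1, p]]] * rows[[pairs[2, p]]])
  }
  stab <- acc / ncol(pairs)
  list(stability = stab, grand_mean = mean(stab), n_pairs = ncol(pairs))
}

#' Align individual cluster labels to the group solution
#'
#' Builds, per subject, the contingency matrix between individual and group
#' labels, normalizes each entry by the group-cluster size, and assigns
#' individual labels to group labels by maximum-weight injective matching;
#' unmatched individual labels become 0 ("unassigned"). Heatmaps count, per
#' group label and voxel, the subjects whose aligned label covers the
#' voxel.
#'
#' @param indiv_labels list of per-subject integer label vectors (one entry
#'   per cord voxel, labels `1..K`).
#' @param group_labels integer label vector of the group solution at the
#'   same K.
#' @return list with `aligned` (per-subject relabeled vectors),
#'   `contingency` (per-subject normalized matrices, group x individual),
#'   `assignment` (per-subject individual -> group label maps), `heatmaps`
#'   (voxels x K subject counts).
#' @export
subject_group_alignment <- function(indiv_labels, group_labels) {
  K <- max(group_labels)
  n <- length(group_labels)
  gsize <- tabulate(group_labels, nbins = K)
  out_al <- list(); out_ct <- list(); out_as <- list()
  heat <- matrix(0L, n, K)
  for (s in seq_along(indiv_labels)) {
    il <- indiv_labels[[s]]
    if (length(il) != n)
      stop("subject ", s, " labels are not on the group grid", call. = FALSE)
    Ki <- max(il)
    ct <- table(factor(group_labels, levels = seq_len(K)),
                factor(il, levels = seq_len(Ki)))
    ct <- unclass(ct) / gsize                     # normalized by group size
    asg <- max_weight_assignment(t(ct))           # individual -> group
    al <- rep(0L, n)
    for (k in seq_len(Ki)) if (!is.na(asg[k])) al[il == k] <- asg[k]
    heat <- heat + outer(al, seq_len(K), "==")
    out_al[[s]] <- al; out_ct[[s]] <- ct; out_as[[s]] <- asg
  }
  list(aligned = out_al, contingency = out_ct, assignment = out_as,
       heatmaps = heat)
}

#' Brain fingerprints of the cord clusters
#'
#' Per subject and cluster, the mean over member cord voxels of their
#' voxelwise brain FC maps (the rows of the subject's feature matrix), then
#' averaged across subjects; a winner-take-all over the K group fingerprints
#' labels every cortical voxel.
#'
#' @param labels integer vector of cluster labels (one per cord voxel, the
#'   row order of the feature matrices).
#' @param z_list list of per-subject [fc_feature_matrix()] objects (cord
#'   voxels x cortical voxels, Fisher z).
#' @return list with `fingerprints` (K x n_cortical group means), `wta`
#'   (winning cluster per cortical voxel), `skipped` (empty clusters).
#' @export
cluster_fingerprints <- function(labels, z_list) {
  K <- max(labels)
  nb <- ncol(z_list[[1]])
  acc <- matrix(0, K, nb)
  skipped <- integer(0)
  for (Z in z_list) {
    Z <- unclass(as.matrix(Z))
    if (nrow(Z) != length(labels))
      stop("feature matrix rows do not match the label vector", call. = FALSE)
    for (k in seq_len(K)) {
      mem <- which(labels == k)
      if (!length(mem)) { skipped <- union(skipped, k); next }
      acc[k, ] <- acc[k, ] + colMeans(Z[mem, , drop = FALSE])
    }
  }
  fp <- acc / length(z_list)
  if (length(skipped))
    warning("empty cluster(s) skipped: ", paste(skipped, collapse = ", "))
  wta <- max.col(t(fp), ties.method = "first")
  list(fingerprints = fp, wta = wta, skipped = skipped)
}
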