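#' Mean time series per seed
#'
#' Unweighted mean over member voxels of each seed, per volume. Seeds are
#' the labels of a [label_map] (e.g. the gray matter of the cord segments);
#' the unsmoothed denoised series is the conventional input.
#'
#' @param img a [bold_image].
#' @param seeds a [label_map] on the same grid, labels `1..S`, all
#'   non-empty.
#' @return numeric matrix, `n_volumes` x S, columns named after the labels.
#' @export
extract_seed_series <- function(img, seeds) {
  stopifnot(inherits(img, "bold_image"), inherits(seeds, "label_map"))
  if (!all(dim(seeds$data) == dim(img$data)[1:3]))
    stop("seed map is not on the image grid", call. = FALSE)
  S <- max(seeds$data)
  if (S < 1L) stop("seed map has no labels", call. = FALSE)
  d <- dim(img$data)
  m <- matrix(img$data, prod(d[1:3]), d[4])
  out <- vapply(seq_len(S), function(s) {
    idx <- which(seeds$data == s)
    if (!length(idx)) stop("seed ", s, " is empty", call. = FALSE)
    colMeans(m[idx, , drop = FALSE])
  }, numeric(d[4]))
  colnames(out) <- sprintf("C%d", seq_len(S))
  out
}

#' Seed-to-voxel Pearson correlation map
#'
#' @param seed_series numeric vector, one value per volume.
#' @param img a [bold_image] of equal temporal length.
#' @param target_mask logical 3D array (non-empty) restricting the map.
#' @return an `fc_map`: list with `data` (3D array, `NA` outside the mask,
#'   Pearson r inside), `mask`, `type = "r"`, `n_degenerate` (constant
#'   voxels, reported as r = 0), `seed`, `subject`.
#' @export
seed_to_voxel_fc <- function(seed_series, img, target_mask, seed = NA,
                             subject = NA) {
  stopifnot(inherits(img, "bold_image"))
  if (length(seed_series) != dim(img$data)[4])
    stop("seed series length does not match the number of volumes",
         call. = FALSE)
  Y <- mask_series(img, target_mask)
  x <- seed_series - mean(seed_series)
  sx <- sqrt(sum(x^2))
  Yc <- sweep(Y, 2, colMeans(Y))
  sy <- sqrt(colSums(Yc^2))
  deg <- sy == 0 | sx == 0
  r <- numeric(ncol(Y))
  if (sx > 0)
    r[!deg] <- as.vector(crossprod(x, Yc[, !deg, drop = FALSE])) /
      (sx * sy[!deg])
  arr <- array(NA_real_, dim(img$data)[1:3])
  arr[which(target_mask)] <- r
  structure(list(data = arr, mask = target_mask, type = "r",
                 n_degenerate = sum(deg), seed = seed, subject = subject),
            class = "fc_map")
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)` with `r` clamped to `+/- (1 - 1e-7)`; strictly increasing
#' and odd. Accepts numerics or an `fc_map` (returned with `type = "z"`).
#'
#' @param r correlation values in `[-1, 1]` or an `fc_map` of them.
#' @return transformed object of the same shape.
#' @export
fisher_z <- function(r) {
  if (inherits(r, "fc_map")) {
    r$data <- fisher_z(r$data)
    r$type <- "z"
    return(r)
  }
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| > 1: not a correlation", call. = FALSE)
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Voxelwise group average of FC maps
#'
#' @param maps list of `fc_map`s on an identical grid and mask (one per
#'   subject, typically Fisher-z maps).
#' @return an `fc_map` with `subject = "group"`.
#' @export
group_average <- function(maps) {
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!all(dim(m$data) == dim(ref$data)) || !identical(m$mask, ref$mask))
      stop("FC maps are not on a common grid/mask", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(maps, `[[`, "data")) / length(maps)
  out <- ref
  out$data <- acc
  out$subject <- "group"
  out
}

#' Winner-take-all somatotopic labeling
#'
#' Assigns every in-mask voxel the seed with the strongest connectivity
#' (argmax over the S maps). Exact ties go to the lowest seed index and are
#' counted. With `positive_only = TRUE`, voxels whose maximum is <= 0 are
#' left unassigned (label 0).
#'
#' @param maps list of S >= 2 `fc_map`s on a common mask, or a numeric
#'   matrix `n_in_mask_voxels` x S.
#' @param mask logical 3D array (required when `maps` is a matrix;
#'   otherwise taken from the maps).
#' @param positive_only mask out non-positive winners.
#' @return a `wta_map`: list with `labels` ([label_map]), `counts` per seed
#'   label, `n_ties`, `S`.
#' @export
winner_take_all <- function(maps, mask = NULL, positive_only = FALSE) {
  if (is.list(maps) && inherits(maps[[1]], "fc_map")) {
    if (is.null(mask)) mask <- maps[[1]]$mask
    vals <- vapply(maps, function(m) m$data[which(mask)],
                   numeric(sum(mask)))
    dims <- dim(maps[[1]]$data)
  } else {
    vals <- as.matrix(maps)
    if (is.null(mask)) stop("`mask` is required with a matrix input",
                            call. = FALSE)
    dims <- dim(mask)
  }
  S <- ncol(vals)
  if (S < 2L) stop("winner-take-all needs at least 2 seed maps", call. = FALSE)
  if (any(is.na(vals)))
    stop("NaN/NA inside the mask: refusing to assign winners", call. = FALSE)
  lab <- max.col(vals, ties.method = "first")
  mx <- vals[cbind(seq_len(nrow(vals)), lab)]
  n_ties <- sum(rowSums(vals == mx) > 1L)
  if (positive_only) lab[mx <= 0] <- 0L
  arr <- array(0L, dims)
  arr[which(mask)] <- lab
  counts <- tabulate(lab, nbins = S)
  names(counts) <- sprintf("C%d", seq_len(S))
  structure(list(labels = label_map(arr), counts = counts,
                 n_ties = n_ties, S = S, mask = mask),
            class = "wta_map")
}

#' @export
print.wta_map <- function(x, ...) {
  cat(sprintf("<wta_map> %d seeds, %d voxels labeled, %d tie(s)\n",
              x$S, sum(x$counts), x$n_ties))
  print(x$counts)
  invisible(x)
}

#' Per-subject voxel counts inside the group winner masks
#'
#' For each group-level winner mask (one per seed label) and each subject,
#' counts how many of the mask's voxels the subject assigned to each label —
#' the reproducibility table a mixed model consumes downstream.
#'
#' @param subject_wtas list of per-subject `wta_map`s.
#' @param group_wta the group-level `wta_map` on the same grid.
#' @return data.frame with columns `group_mask_label`, `subject`,
#'   `assigned_label`, `n_voxels`; per group mask and subject the counts sum
#'   to the mask size.
#' @export
wta_subject_counts <- function(subject_wtas, group_wta) {
  S <- group_wta$S
  glab <- group_wta$labels$data
  out <- list()
  for (subj in seq_along(subject_wtas)) {
    w <- subject_wtas[[subj]]
    if (!all(dim(w$labels$data) == dim(glab)))
      stop("subject and group maps are not on the same grid", call. = FALSE)
    if (w$S != S) stop("label ranges differ", call. = FALSE)
    for (m in seq_len(S)) {
      idx <- which(glab == m)
      cnt <- tabulate(w$labels$data[idx], nbins = S)
      out[[length(out) + 1L]] <- data.frame(
        group_mask_label = m, subject = subj,
        assigned_label = seq_len(S), n_voxels = cnt)
    }
  }
  do.call(rbind, out)
}
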