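#' Framewise displacement
#'
#' Per-volume motion summary from realignment parameters. Brain (6
#' parameters: 3 translations in mm, 3 rotations in rad) uses the Power
#' convention: sum of absolute backward differences of the translations plus
#' `rotation_radius_mm` times the same for the rotations. Cord realignment
#' is slice-wise in-plane (2 translations), so cord FD is the mean of
#' |delta x| and |delta y|. The first volume has FD 0 by convention, and runs
#' whose mean FD exceeds 0.3 mm are flagged as excess motion.
#'
#' @param motion numeric matrix / data.frame, `n_volumes` rows, 6 (brain) or
#'   2 (cord) columns.
#' @param organ `"brain"` or `"cord"`.
#' @param rotation_radius_mm sphere radius converting radians to mm
#'   (brain only).
#' @return list with `fd_series` (mm, first entry 0), `fd_mean` and
#'   `excess_flag` (`fd_mean > 0.3`).
#' @export
framewise_displacement <- function(motion, organ = c("brain", "cord"),
                                   rotation_radius_mm = 50) {
  organ <- match.arg(organ)
  m <- as.matrix(motion)
  if (!all(is.finite(m))) stop("motion parameters must be finite", call. = FALSE)
  want <- if (organ == "brain") 6L else 2L
  if (ncol(m) != want)
    stop(sprintf("%s motion table must have %d columns, got %d",
                 organ, want, ncol(m)), call. = FALSE)
  d <- abs(diff(m))
  fd <- if (organ == "brain") {
    rowSums(d[, 1:3, drop = FALSE]) +
      rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  } else {
    rowMeans(d)
  }
  fd <- c(0, fd)
  list(fd_series = fd, fd_mean = mean(fd), excess_flag = mean(fd) > 0.3)
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel mean over time divided by the population (ddof = 0) standard
#' deviation over time; voxels with zero temporal variance get tSNR 0 and
#' are counted as degenerate.
#'
#' @param img a [bold_image].
#' @param mask logical 3D array on the image grid (non-empty).
#' @return list with `tsnr_map` (3D array, 0 outside the mask), `tsnr_mean`
#'   (mean over in-mask voxels) and `n_degenerate`.
#' @export
tsnr <- function(img, mask) {
  stopifnot(inherits(img, "bold_image"))
  Y <- mask_series(img, mask)               # T x V (errors on empty mask)
  T <- nrow(Y)
  mu <- colMeans(Y)
  sdev <- sqrt(colMeans(Y^2) - mu^2)        # population std
  sdev[sdev < 0] <- 0
  deg <- sdev == 0
  val <- ifelse(deg, 0, mu / ifelse(deg, 1, sdev))
  if (any(deg))
    warning(sum(deg), " voxel(s) with zero temporal variance: tSNR set to 0")
  out <- array(0, dim(img$data)[1:3])
  out[which(mask)] <- val
  list(tsnr_map = out, tsnr_mean = mean(val), n_degenerate = sum(deg))
}

#' Quality-control report for one run
#'
#' Bundles [framewise_displacement()] and [tsnr()].
#'
#' @param img a [bold_image]; `motion` its realignment table; `mask` the
#'   tissue mask tSNR is averaged over.
#' @inheritParams framewise_displacement
#' @return object of class `qc_report`.
#' @export
qc_report <- function(img, motion, mask, rotation_radius_mm = 50) {
  fd <- framewise_displacement(motion, img$organ, rotation_radius_mm)
  ts <- tsnr(img, mask)
  structure(c(fd, ts, list(organ = img$organ)), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: mean FD %.4f mm%s, mean tSNR %.2f (%d degenerate)\n",
              x$organ, x$fd_mean,
              if (x$excess_flag) " [EXCESS MOTION]" else "",
              x$tsnr_mean, x$n_degenerate))
  invisible(x)
}
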