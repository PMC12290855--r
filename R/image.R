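#' 4D BOLD image container
#'
#' Light S3 container for a 4D voxel time series on a fixed grid: the
#' substrate every pipeline stage operates on. Data are stored as a plain
#' (i, j, k, t) array together with the repetition time and the voxel-to-world
#' affine.
#'
#' @param data 4D numeric array (i, j, k, t), at least 2 volumes, all finite.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param affine 4x4 invertible voxel-to-world transform (mm).
#' @param organ `"brain"` or `"cord"`.
#' @return an object of class `bold_image`.
#' @export
bold_image <- function(data, tr_seconds, affine = diag(4),
                       organ = c("brain", "cord")) {
  organ <- match.arg(organ)
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (i, j, k, t)", call. = FALSE)
  if (dim(data)[4] < 2L)
    stop("a BOLD image needs at least 2 volumes", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("`tr_seconds` must be a positive scalar", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(data = data, tr_seconds = tr_seconds, affine = affine,
                 organ = organ),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %s, %d x %d x %d voxels, %d volumes, TR = %g s\n",
              x$organ, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' @export
dim.bold_image <- function(x) dim(x$data)

#' Integer label map
#'
#' 3D volume of integer labels on a fixed grid; used for seeds, atlases,
#' cluster solutions and winner-take-all outputs. Label 0 means background /
#' unassigned.
#'
#' @param data 3D array of non-negative integers (integer-valued numerics
#'   are accepted and coerced).
#' @param affine 4x4 voxel-to-world transform.
#' @return an object of class `label_map`.
#' @export
label_map <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  if (any(data != round(data)) || any(data < 0))
    stop("label maps must hold non-negative integers", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = as.matrix(affine)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$data)
  labs <- sort(unique(as.integer(x$data[x$data > 0L])))
  cat(sprintf("<label_map> %d x %d x %d, labels: %s\n", d[1], d[2], d[3],
              if (length(labs)) paste(labs, collapse = " ") else "(none)"))
  invisible(x)
}

#' Voxel sizes (mm) from an affine
#'
#' Column norms of the rotation/scaling block; used by smoothing to convert
#' FWHM in mm into voxel units.
#' @param affine 4x4 transform.
#' @return length-3 numeric vector of voxel edge lengths in mm.
#' @export
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Read a NIfTI-1 image
#'
#' 4D files become [bold_image] (TR read from the header's 4th pixdim entry
#' unless overridden); 3D files become [label_map] after an integer check.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr_seconds optional TR override; required if the header carries no
#'   usable timing information.
#' @param organ organ tag for 4D images.
#' @return a `bold_image` or `label_map`.
#' @export
read_image <- function(path, tr_seconds = NULL, organ = c("brain", "cord")) {
  organ <- match.arg(organ)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "not a readable NIfTI-1 file: %s (%s)",
                    path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4L, 4L)
  if (length(dim(arr)) == 4L) {
    # the NIfTI reader normalizes an absent (zero) time step to 1, which
    # would silently mask a header without timing information -- check the
    # raw on-disk field instead
    tr <- if (!is.null(tr_seconds)) tr_seconds else raw_time_step(path)
    if (!is.finite(tr) || tr <= 0)
      stop("header has no usable TR; pass `tr_seconds` explicitly",
           call. = FALSE)
    bold_image(arr, tr_seconds = tr, affine = aff, organ = organ)
  } else if (length(dim(arr)) == 3L) {
    if (any(arr != round(arr)) || any(arr < 0))
      stop("3D image is not an integer label map", call. = FALSE)
    label_map(arr, affine = aff)
  } else {
    stop("expected a 3D label map or 4D BOLD image", call. = FALSE)
  }
}

#' Write a `bold_image` or `label_map` as NIfTI-1
#'
#' Lossless round trip of data, affine and (for 4D) TR; see [read_image()].
#'
#' @param obj object to write.
#' @param path destination `.nii` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(obj, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  vs <- voxel_sizes(obj$affine)
  img <- RNifti::asNifti(obj$data)
  if (inherits(obj, "bold_image")) {
    RNifti::pixdim(img) <- c(vs, obj$tr_seconds)
  } else {
    RNifti::pixdim(img) <- vs
  }
  RNifti::sform(img) <- structure(obj$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# internal: the time step exactly as stored in the NIfTI-1 header
# (pixdim[4], float32 at byte offset 92), before any library normalization
raw_time_step <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) return(NA_real_)
  sz <- readBin(hdr[1:4], "integer", 1L, size = 4L)
  endian <- if (sz == 348L) .Platform$endian else
    setdiff(c("big", "little"), .Platform$endian)
  readBin(hdr[93:96], "double", 1L, size = 4L, endian = endian)
}

# internal: flatten in-mask voxels to a T x V matrix (column j = series of
# the j-th TRUE voxel in array order)
mask_series <- function(img, mask) {
  stopifnot(inherits(img, "bold_image"))
  d <- dim(img$data)
  if (!all(dim(mask) == d[1:3]))
    stop("mask extents do not match the image grid", call. = FALSE)
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  nvox <- prod(d[1:3])
  m <- matrix(img$data, nrow = nvox, ncol = d[4])
  t(m[idx, , drop = FALSE])
}

# internal: write a T x V matrix back into in-mask voxels of a 4D array
set_mask_series <- function(img, mask, series) {
  d <- dim(img$data)
  idx <- which(mask)
  m <- matrix(img$data, nrow = prod(d[1:3]), ncol = d[4])
  m[idx, ] <- t(series)
  img$data <- array(m, d)
  img
}
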