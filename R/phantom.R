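#' Phantom configuration
#'
#' Defines the synthetic study conditions: paired brain/cord 4D acquisitions
#' in which each of `n_segments` cervical cord segments shares a latent
#' neural signal with one patch of a 1-D cortical sensorimotor strip, with a
#' graded (geometric) falloff of coupling towards neighbouring patches — the
#' somatotopic gradient every downstream stage must recover. On top of the
#' neural signal the phantom carries cardiac and respiratory sinusoids
#' (sampled at the TR, aliasing permitted), CSF compartments holding only
#' physiological noise and drift, slow per-voxel drift, and bounded
#' random-walk motion traces whose framewise displacement modulates image
#' intensity.
#'
#' Acquisition defaults mirror a 3T cervical protocol: TR 1.55 s, 230
#' volumes, 7 segments. `coupling_snr` is the ratio of the shared-signal
#' standard deviation to the idiosyncratic-noise standard deviation of a
#' voxel; the default of 1 puts the shared fluctuation at the same scale as
#' voxel noise, a realistic regime for resting-state BOLD.
#'
#' @param n_subjects number of subjects a cohort run generates.
#' @param tr_seconds repetition time (s).
#' @param n_volumes number of volumes per run.
#' @param n_segments number of cord segments / cortical patches.
#' @param cord_grid,cortex_grid 3 integer extents. Cord segments are stacked
#'   along the 3rd cord axis (extent divisible by `n_segments`); the cortical
#'   gradient runs along the 1st cortex axis.
#' @param coupling_snr shared-signal sd / idiosyncratic-noise sd.
#' @param event_rate expected spontaneous events per volume per segment.
#' @param cardiac_hz,resp_hz physiological frequencies (Hz).
#' @param physio_amplitude named amplitudes per tissue (`gm`, `csf`), signal
#'   units.
#' @param drift_amplitude scale of the slow per-voxel drift.
#' @param motion_step_mm sd of one random-walk motion step (mm; rotations use
#'   `motion_step_mm / 50` rad).
#' @param coupling_falloff geometric decay of cortical coupling with patch /
#'   segment distance.
#' @param rng_seed integer seed; identical configurations reproduce
#'   bit-identical phantoms.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 8L, tr_seconds = 1.55,
                           n_volumes = 230L, n_segments = 7L,
                           cord_grid = c(6L, 6L, 42L),
                           cortex_grid = c(42L, 14L, 3L),
                           coupling_snr = 1.0, event_rate = 0.05,
                           cardiac_hz = 1.0, resp_hz = 0.3,
                           physio_amplitude = c(gm = 0.3, csf = 1.5),
                           drift_amplitude = 1.0, motion_step_mm = 0.02,
                           coupling_falloff = 0.3, rng_seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), tr_seconds = tr_seconds,
              n_volumes = as.integer(n_volumes),
              n_segments = as.integer(n_segments),
              cord_grid = as.integer(cord_grid),
              cortex_grid = as.integer(cortex_grid),
              coupling_snr = coupling_snr, event_rate = event_rate,
              cardiac_hz = cardiac_hz, resp_hz = resp_hz,
              physio_amplitude = physio_amplitude,
              drift_amplitude = drift_amplitude,
              motion_step_mm = motion_step_mm,
              coupling_falloff = coupling_falloff,
              rng_seed = as.integer(rng_seed))
  if (any(cfg$cord_grid < 1L) || any(cfg$cortex_grid < 1L))
    stop("all grid extents must be >= 1", call. = FALSE)
  if (cfg$n_volumes < 2L) stop("n_volumes must be >= 2", call. = FALSE)
  if (cfg$n_segments < 2L) stop("n_segments must be >= 2", call. = FALSE)
  if (cfg$cord_grid[3] %% cfg$n_segments != 0L)
    stop("cord 3rd-axis extent must be divisible by n_segments ",
         "(equal-thickness segments)", call. = FALSE)
  if (cfg$tr_seconds <= 0) stop("tr_seconds must be > 0", call. = FALSE)
  if (cfg$coupling_snr <= 0) stop("coupling_snr must be > 0", call. = FALSE)
  structure(cfg, class = "phantom_config")
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' SPM-style double gamma: response gamma with shape 6 / rate 1 (mode 5 s),
#' undershoot gamma with shape 16 / rate 1, undershoot ratio 1/6. Sampled at
#' the TR over `duration_seconds` and normalized so the peak equals 1.
#'
#' @param tr_seconds sampling interval (s).
#' @param duration_seconds kernel support (s).
#' @return numeric vector of length `ceiling(duration_seconds / tr_seconds)`.
#' @export
hrf_kernel <- function(tr_seconds, duration_seconds = 32) {
  if (tr_seconds <= 0 || duration_seconds <= 0)
    stop("tr_seconds and duration_seconds must be > 0", call. = FALSE)
  n <- ceiling(duration_seconds / tr_seconds)
  t <- (seq_len(n) - 1) * tr_seconds
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# internal: causal convolution of each column of x with kernel h, truncated
# to the original length
conv_hrf <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (j in seq_len(ncol(x)))
    out[, j] <- stats::convolve(x[, j], rev(h), type = "open")[seq_len(n)]
  out
}

#' Physiological trace container
#'
#' @param samples numeric samples (arbitrary units).
#' @param sampling_rate_hz sampling rate (> 0).
#' @param modality `"cardiac"` or `"respiratory"`.
#' @param peak_times_seconds optional strictly increasing event (pulse) times.
#' @return an object of class `physio_trace`.
#' @export
physio_trace <- function(samples, sampling_rate_hz,
                         modality = c("cardiac", "respiratory"),
                         peak_times_seconds = NULL) {
  modality <- match.arg(modality)
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0", call. = FALSE)
  if (!is.null(peak_times_seconds) &&
      any(diff(peak_times_seconds) <= 0))
    stop("peak times must be strictly increasing", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz, modality = modality,
                 peak_times_seconds = peak_times_seconds),
            class = "physio_trace")
}

# internal: reflect a random walk into [-bound, bound]
reflect_walk <- function(steps, bound) {
  x <- cumsum(steps)
  b <- bound
  abs(((x + b) %% (4 * b)) - 2 * b) - b
}

#' Generate one subject's paired brain/cord phantom
#'
#' Each cord gray-matter voxel in segment s carries the HRF-convolved event
#' train of segment s (weighted by the coupling diagonal) plus idiosyncratic
#' Gaussian noise scaled by `coupling_snr`; each cortical strip voxel in
#' patch p carries the coupling-weighted mixture of all segments' trains
#' (geometric falloff with |p - s|) plus noise. CSF voxels hold only
#' physiological sinusoids, drift, and white noise. Motion enters as an
#' intensity modulation proportional to the framewise-displacement trace
#' (the phantom stays analytically aligned; no resampling).
#'
#' @param config a [phantom_config()].
#' @param subject subject index (>= 1); determines the subject-level seed
#'   `rng_seed + 1000 * (subject - 1)` so cohort members share the spatial
#'   layout but draw independent events, noise, physiology and motion.
#' @return list with elements `brain` ([bold_image]), `cord` ([bold_image])
#'   and `truth` (class `phantom_truth`: `cord_labels`, `cortex_labels`
#'   label maps; `event_trains` S x T; `coupling` S x S; `csf_masks`;
#'   `motion` tables; `physio` traces; `volume_times`; `neural` S x T
#'   HRF-convolved trains).
#' @export
generate_phantom <- function(config, subject = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  seed <- config$rng_seed + 1000L * (as.integer(subject) - 1L)
  set.seed(seed)
  S <- config$n_segments
  T <- config$n_volumes
  tr <- config$tr_seconds
  vt <- (seq_len(T) - 1) * tr

  # --- spatial layout (deterministic; shared across subjects) -------------
  cg <- config$cord_grid
  xg <- config$cortex_grid
  # cord: gray matter = central in-plane block, CSF = surrounding ring
  gm_i <- gm_extent(cg[1]); gm_j <- gm_extent(cg[2])
  cord_gm <- array(FALSE, cg)
  cord_gm[gm_i, gm_j, ] <- TRUE
  cord_csf <- !cord_gm
  thick <- cg[3] %/% S
  seg_of_k <- rep(seq_len(S), each = thick)
  cord_lab <- array(0L, cg)
  for (k in seq_len(cg[3])) {
    sl <- cord_lab[, , k]
    sl[cord_gm[, , k]] <- seg_of_k[k]
    cord_lab[, , k] <- sl
  }
  # cortex: sensorimotor strip over the first ~70% of axis 2, CSF behind it;
  # patches tile axis 1
  strip_j <- seq_len(max(1L, floor(xg[2] * 10 / 14)))
  ctx_strip <- array(FALSE, xg)
  ctx_strip[, strip_j, ] <- TRUE
  ctx_csf <- !ctx_strip
  patch_of_i <- pmin(S, 1L + ((seq_len(xg[1]) - 1L) * S) %/% xg[1])
  ctx_lab <- array(0L, xg)
  for (i in seq_len(xg[1])) {
    sl <- ctx_lab[i, , ]
    sl[ctx_strip[i, , ]] <- patch_of_i[i]
    ctx_lab[i, , ] <- sl
  }

  # --- latent neural structure -------------------------------------------
  events <- matrix(stats::rbinom(S * T, 1L, min(1, config$event_rate)), S, T)
  h <- hrf_kernel(tr)
  neural <- t(conv_hrf(t(events), h))          # S x T, HRF-convolved trains
  fall <- config$coupling_falloff
  coupling <- fall^abs(outer(seq_len(S), seq_len(S), "-"))

  # --- physiology, drift, motion -----------------------------------------
  phys_sr <- 100
  nphys <- ceiling(T * tr * phys_sr)
  tau <- (seq_len(nphys) - 1) / phys_sr
  phi_c <- stats::runif(1, 0, 2 * pi)
  phi_r <- stats::runif(1, 0, 2 * pi)
  card_full <- sin(2 * pi * config$cardiac_hz * tau + phi_c)
  resp_full <- sin(2 * pi * config$resp_hz * tau + phi_r)
  # analytic pulse maxima of the cardiac sinusoid
  k0 <- ceiling((phi_c - pi / 2) / (2 * pi))
  pk <- (pi / 2 - phi_c + 2 * pi * seq(k0, k0 + ceiling(T * tr * config$cardiac_hz) + 1)) /
    (2 * pi * config$cardiac_hz)
  pk <- pk[pk >= 0 & pk <= T * tr]
  cardiac <- physio_trace(card_full, phys_sr, "cardiac", pk)
  resp <- physio_trace(resp_full, phys_sr, "respiratory")
  card_vol <- sin(2 * pi * config$cardiac_hz * vt + phi_c)
  resp_vol <- sin(2 * pi * config$resp_hz * vt + phi_r)

  drift_basis <- cbind(vt / max(vt), cos(pi * vt / max(vt)))   # T x 2

  steps_b <- cbind(matrix(stats::rnorm(T * 3, 0, config$motion_step_mm), T, 3),
                   matrix(stats::rnorm(T * 3, 0, config$motion_step_mm / 50), T, 3))
  bounds_b <- c(1, 1, 1, 0.02, 0.02, 0.02)
  mb <- vapply(1:6, function(j) reflect_walk(steps_b[, j], bounds_b[j]),
               numeric(T))
  dimnames(mb) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  steps_c <- matrix(stats::rnorm(T * 2, 0, config$motion_step_mm), T, 2)
  mc <- vapply(1:2, function(j) reflect_walk(steps_c[, j], 1), numeric(T))
  dimnames(mc) <- list(NULL, c("tx", "ty"))

  fd_b <- framewise_displacement(mb, organ = "brain")$fd_series
  fd_c <- framewise_displacement(mc, organ = "cord")$fd_series

  # --- assemble the two organs -------------------------------------------
  cord_arr <- build_organ(cg, cord_lab, cord_gm, cord_csf, neural, coupling,
                          diag_only = TRUE, config, card_vol, resp_vol,
                          drift_basis, fd_c)
  ctx_arr <- build_organ(xg, ctx_lab, ctx_strip, ctx_csf, neural, coupling,
                         diag_only = FALSE, config, card_vol, resp_vol,
                         drift_basis, fd_b)

  aff_cord <- diag(c(2, 2, 2, 1))
  aff_ctx <- diag(c(2, 2, 2, 1))
  truth <- structure(list(
    cord_labels = label_map(cord_lab, aff_cord),
    cortex_labels = label_map(ctx_lab, aff_ctx),
    event_trains = events, coupling = coupling, neural = neural,
    csf_masks = list(cord = cord_csf, brain = ctx_csf),
    gm_masks = list(cord = cord_gm, brain = ctx_strip),
    motion = list(brain = mb, cord = mc),
    physio = list(cardiac = cardiac, respiratory = resp),
    volume_times = vt, subject = as.integer(subject), seed = seed),
    class = "phantom_truth")
  list(brain = bold_image(ctx_arr, tr, aff_ctx, "brain"),
       cord = bold_image(cord_arr, tr, aff_cord, "cord"),
       truth = truth)
}

# internal: central in-plane extent for the cord gray-matter block; always
# leaves at least a one-voxel CSF ring when the plane allows it
gm_extent <- function(n) {
  lo <- max(2L, floor(n / 6) + 1L)
  hi <- min(n - 1L, n - floor(n / 6))
  if (lo > hi) seq_len(n) else lo:hi
}

# internal: fill one organ's 4D array from the latent structure
build_organ <- function(grid, labels, gm_mask, csf_mask, neural, coupling,
                        diag_only, config, card_vol, resp_vol, drift_basis,
                        fd) {
  T <- config$n_volumes
  nvox <- prod(grid)
  dat <- matrix(0, nvox, T)
  baseline <- 100
  amp <- config$physio_amplitude
  snr <- config$coupling_snr
  lab_vec <- as.integer(labels)
  S <- nrow(coupling)
  for (s in seq_len(S)) {
    vox <- which(gm_mask & array(lab_vec == s, grid))
    if (!length(vox)) next
    shared <- if (diag_only) coupling[s, s] * neural[s, ] else
      drop(coupling[s, , drop = FALSE] %*% neural)
    sd_sh <- stats::sd(shared)
    sd_n <- if (is.finite(snr)) sd_sh / snr else 0
    noise <- if (sd_n > 0)
      matrix(stats::rnorm(length(vox) * T, 0, sd_n), length(vox), T)
    else 0
    dat[vox, ] <- matrix(shared, length(vox), T, byrow = TRUE) + noise
    dat[vox, ] <- dat[vox, ] +
      matrix(amp[["gm"]] * (card_vol + resp_vol), length(vox), T, byrow = TRUE)
  }
  csf_idx <- which(csf_mask)
  if (length(csf_idx)) {
    w1 <- stats::runif(length(csf_idx), 0.5, 1.5)
    w2 <- stats::runif(length(csf_idx), 0.5, 1.5)
    dat[csf_idx, ] <- amp[["csf"]] *
      (outer(w1, card_vol) + outer(w2, resp_vol))
    if (amp[["csf"]] > 0)
      dat[csf_idx, ] <- dat[csf_idx, ] +
        matrix(stats::rnorm(length(csf_idx) * T, 0, 0.2 * amp[["csf"]]),
               length(csf_idx), T)
  }
  if (config$drift_amplitude > 0) {
    coefs <- matrix(stats::rnorm(nvox * 2, 0, config$drift_amplitude), nvox, 2)
    dat <- dat + coefs %*% t(drift_basis)
  }
  dat <- dat + baseline
  # motion as intensity modulation proportional to the FD trace
  dat <- dat * matrix(1 + 0.2 * fd, nvox, T, byrow = TRUE)
  array(dat, c(grid, T))
}

#' Generate a cohort of phantom subjects
#'
#' @param config a [phantom_config()].
#' @return list of length `config$n_subjects`, each a [generate_phantom()]
#'   result. Spatial layout and ground-truth labels are shared; events,
#'   noise, physiology and motion are subject-specific.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects), function(s) generate_phantom(config, s))
}

#' Write a phantom subject to disk
#'
#' NIfTI images per organ, TSV motion and physiology files, a JSON
#' ground-truth sidecar, and a manifest listing every path. Reading the
#' manifest back with [read_phantom_dataset()] reproduces all arrays
#' exactly.
#'
#' @param phantom result of [generate_phantom()].
#' @param directory output directory (created if needed).
#' @return the manifest (named list of paths), invisibly written to
#'   `manifest.json`.
#' @export
write_phantom_dataset <- function(phantom, directory) {
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  p <- function(f) file.path(directory, f)
  tr <- phantom$brain$tr_seconds
  write_image(phantom$brain, p("brain.nii"))
  write_image(phantom$cord, p("cord.nii"))
  tw <- function(x, f) utils::write.table(
    x, p(f), sep = "\t", row.names = FALSE, quote = FALSE)
  tw(as.data.frame(phantom$truth$motion$brain), "brain_motion.tsv")
  tw(as.data.frame(phantom$truth$motion$cord), "cord_motion.tsv")
  for (m in c("cardiac", "respiratory")) {
    tr_ph <- phantom$truth$physio[[m]]
    tw(data.frame(sample = tr_ph$samples), paste0(m, ".tsv"))
  }
  truth <- phantom$truth
  sidecar <- list(
    tr_seconds = tr,
    cord_labels = list(dim = dim(truth$cord_labels$data),
                       values = as.integer(truth$cord_labels$data)),
    cortex_labels = list(dim = dim(truth$cortex_labels$data),
                         values = as.integer(truth$cortex_labels$data)),
    event_trains = truth$event_trains, coupling = truth$coupling,
    csf_masks = lapply(truth$csf_masks,
                       function(m) list(dim = dim(m), values = which(m))),
    physio = list(cardiac = list(sampling_rate_hz =
                                   truth$physio$cardiac$sampling_rate_hz,
                                 peak_times = truth$physio$cardiac$peak_times_seconds),
                  respiratory = list(sampling_rate_hz =
                                       truth$physio$respiratory$sampling_rate_hz)),
    subject = truth$subject, seed = truth$seed)
  jsonlite::write_json(sidecar, p("truth.json"), digits = NA,
                       auto_unbox = TRUE)
  manifest <- list(images = c(p("brain.nii"), p("cord.nii")),
                   motion = c(p("brain_motion.tsv"), p("cord_motion.tsv")),
                   physio = c(p("cardiac.tsv"), p("respiratory.tsv")),
                   truth = p("truth.json"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Read back a phantom dataset written by [write_phantom_dataset()]
#'
#' @param directory directory holding `manifest.json`.
#' @return list with `brain`, `cord` ([bold_image]) and selected truth
#'   fields (`cord_labels`, `cortex_labels`, `event_trains`, `coupling`).
#' @export
read_phantom_dataset <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", directory, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  truth <- jsonlite::read_json(manifest$truth, simplifyVector = TRUE)
  unpack <- function(x) label_map(array(x$values, x$dim))
  list(brain = read_image(manifest$images[1], organ = "brain"),
       cord = read_image(manifest$images[2], organ = "cord"),
       cord_labels = unpack(truth$cord_labels),
       cortex_labels = unpack(truth$cortex_labels),
       event_trains = truth$event_trains,
       coupling = truth$coupling)
}
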