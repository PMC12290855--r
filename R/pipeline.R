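#' Pipeline run configuration
#'
#' Single source of truth for an end-to-end run on a phantom cohort: stage
#' toggles and every stage parameter, with explicit seeds for every random
#' operation. Unknown keys are rejected.
#'
#' @param phantom a [phantom_config()] describing the cohort to generate.
#' @param stages character subset of
#'   `c("qc", "denoise", "icap", "seedfc", "parcellation")`.
#' @param band_hz band-pass edges (Hz) for the denoising projection.
#' @param n_cardiac,n_resp,n_interaction RETROICOR harmonic counts.
#' @param n_compcor_brain,n_compcor_cord CompCor component counts.
#' @param n_dct DCT detrending functions.
#' @param fwhm_brain_mm,fwhm_cord_mm smoothing kernels (mm, length 3).
#' @param k_cord,k_brain iCAP cluster counts.
#' @param icap_alpha,icap_n_surrogates,icap_min_active_fraction innovation
#'   frame selection settings.
#' @param k_values parcellation cut levels.
#' @param seed_source `"truth"` (ground-truth segment labels seed the FC
#'   analysis) or `"icap"` (winner-take-all over the cord iCAP maps).
#' @param match_weight `"dice"` or `"overlap"` for label matching.
#' @param out_dir optional output directory; when set, NIfTI/TSV/JSON
#'   artifacts are written and hashed into the manifest.
#' @param seed master seed for the analysis stages (phantom generation uses
#'   `phantom$rng_seed`).
#' @return object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       stages = c("qc", "denoise", "icap", "seedfc",
                                  "parcellation"),
                       band_hz = c(0.01, 0.17),
                       n_cardiac = 3L, n_resp = 4L, n_interaction = 1L,
                       n_compcor_brain = 12L, n_compcor_cord = 5L,
                       n_dct = 5L,
                       fwhm_brain_mm = c(6, 6, 6),
                       fwhm_cord_mm = c(3, 3, 6),
                       k_cord = phantom$n_segments, k_brain = 10L,
                       icap_alpha = 0.05, icap_n_surrogates = 100L,
                       icap_min_active_fraction = 0.05,
                       k_values = NULL,
                       seed_source = c("truth", "icap"),
                       match_weight = c("dice", "overlap"),
                       out_dir = NULL, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed_source <- match.arg(seed_source)
  match_weight <- match.arg(match_weight)
  if (is.null(k_values))
    k_values <- pmax(1L, (phantom$n_segments - 2L):(phantom$n_segments + 2L))
  structure(list(phantom = phantom, stages = stages, band_hz = band_hz,
                 n_cardiac = n_cardiac, n_resp = n_resp,
                 n_interaction = n_interaction,
                 n_compcor_brain = n_compcor_brain,
                 n_compcor_cord = n_compcor_cord, n_dct = n_dct,
                 fwhm_brain_mm = fwhm_brain_mm, fwhm_cord_mm = fwhm_cord_mm,
                 k_cord = k_cord, k_brain = k_brain,
                 icap_alpha = icap_alpha,
                 icap_n_surrogates = icap_n_surrogates,
                 icap_min_active_fraction = icap_min_active_fraction,
                 k_values = k_values, seed_source = seed_source,
                 match_weight = match_weight, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# internal: full nuisance design for one subject/organ of a phantom
phantom_design <- function(ph, organ, config) {
  truth <- ph$truth
  img <- ph[[if (organ == "brain") "brain" else "cord"]]
  phases <- retroicor_phases(truth$physio$cardiac, truth$physio$respiratory,
                             truth$volume_times)
  retro <- retroicor_design(phases$phi_c, phases$phi_r,
                            config$n_cardiac, config$n_resp,
                            config$n_interaction)
  ncomp <- if (organ == "brain") config$n_compcor_brain else
    config$n_compcor_cord
  cc <- compcor(img, truth$csf_masks[[organ]], ncomp)
  dct <- dct_basis(dim(img$data)[4], config$n_dct)
  mot <- motion_design(truth$motion[[organ]])
  combine_designs(retro, cc, dct, mot)
}

#' Run the full phantom pipeline
#'
#' Generates the cohort, then runs the enabled stages in order: QC,
#' nuisance-model denoising (band-passed for FC analyses, unfiltered for
#' the deconvolution path), cord iCAPs, seed-to-voxel FC with group
#' winner-take-all, and connectivity-based parcellation with matching
#' against the ground-truth segments. Every stage consumes only its
#' declared inputs; seed extraction uses unsmoothed denoised data and the
#' deconvolution uses the un-band-passed denoised data.
#'
#' @param config a [run_config()].
#' @return object of class `run_manifest`: config snapshot, per-stage
#'   wall-clock seconds, summary metrics per stage, output file hashes
#'   (when `out_dir` is set), and the key result objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_all <- list(); res <- list(); summaries <- list()
  stamp <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    t_all[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  cohort <- stamp("synth", generate_cohort(config$phantom))
  truth <- cohort[[1]]$truth
  S <- config$phantom$n_segments

  if ("qc" %in% config$stages) {
    qcs <- stamp("qc", lapply(cohort, function(ph) list(
      brain = qc_report(ph$brain, ph$truth$motion$brain,
                        ph$truth$gm_masks$brain),
      cord = qc_report(ph$cord, ph$truth$motion$cord,
                       ph$truth$gm_masks$cord))))
    summaries$qc <- list(
      fd_mean_brain = mean(vapply(qcs, function(q) q$brain$fd_mean, 1)),
      fd_mean_cord = mean(vapply(qcs, function(q) q$cord$fd_mean, 1)),
      tsnr_mean_brain = mean(vapply(qcs, function(q) q$brain$tsnr_mean, 1)),
      tsnr_mean_cord = mean(vapply(qcs, function(q) q$cord$tsnr_mean, 1)),
      any_excess = any(vapply(qcs, function(q)
        q$brain$excess_flag || q$cord$excess_flag, TRUE)))
    res$qc <- qcs
  }

  denoised <- NULL
  if (any(c("denoise", "icap", "seedfc", "parcellation") %in% config$stages)) {
    denoised <- stamp("denoise", lapply(cohort, function(ph) {
      db <- phantom_design(ph, "brain", config)
      dc <- phantom_design(ph, "cord", config)
      list(
        brain = denoise(ph$brain, db, config$band_hz),
        cord = denoise(ph$cord, dc, config$band_hz),
        cord_nofilt = denoise(ph$cord, dc, apply_bandpass = FALSE))
    }))
    summaries$denoise <- list(n_subjects = length(denoised))
  }

  if ("icap" %in% config$stages) {
    icaps <- stamp("icap", {
      ph <- cohort[[1]]
      sm <- smooth_bold(denoised[[1]]$cord_nofilt, config$fwhm_cord_mm)
      act <- deconvolve(sm, truth$gm_masks$cord)
      fr <- select_significant_frames(act, config$icap_alpha,
                                      config$icap_n_surrogates,
                                      config$icap_min_active_fraction,
                                      seed = config$seed)
      set <- cluster_frames(fr, config$k_cord, seed = config$seed)
      cons <- consensus_cluster(fr, config$k_cord, seed = config$seed)
      list(frames = fr, set = set, consensus = cons)
    })
    summaries$icap <- list(
      n_frames = length(icaps$frames$selected),
      mean_consensus = icaps$consensus$mean_consensus,
      converged = TRUE)
    res$icap <- icaps
  }

  if ("seedfc" %in% config$stages) {
    fc <- stamp("seedfc", {
      seeds <- if (config$seed_source == "truth" || is.null(res$icap)) {
        truth$cord_labels
      } else {
        icap_seeds(res$icap$set, truth$gm_masks$cord,
                   dim(truth$cord_labels$data))
      }
      strip <- truth$gm_masks$brain
      subj_maps <- lapply(seq_along(cohort), function(i) {
        ss <- extract_seed_series(denoised[[i]]$cord, seeds)
        lapply(seq_len(S), function(s)
          fisher_z(seed_to_voxel_fc(ss[, s], denoised[[i]]$brain, strip,
                                    seed = s, subject = i)))
      })
      group_maps <- lapply(seq_len(S), function(s)
        group_average(lapply(subj_maps, `[[`, s)))
      gw <- winner_take_all(group_maps)
      sw <- lapply(subj_maps, winner_take_all)
      counts <- wta_subject_counts(sw, gw)
      truth_lab <- truth$cortex_labels$data[which(strip)]
      acc <- mean(gw$labels$data[which(strip)] == truth_lab)
      list(seeds = seeds, group_maps = group_maps, group_wta = gw,
           subject_wtas = sw, counts = counts, accuracy = acc)
    })
    summaries$seedfc <- list(wta_accuracy = fc$accuracy,
                             n_ties = fc$group_wta$n_ties)
    res$seedfc <- fc
  }

  if ("parcellation" %in% config$stages) {
    parc <- stamp("parcellation", {
      cord_mask <- truth$gm_masks$cord
      strip <- truth$gm_masks$brain
      z_list <- lapply(seq_along(cohort), function(i)
        fc_feature_matrix(denoised[[i]]$cord, denoised[[i]]$brain,
                          cord_mask, strip))
      s_list <- lapply(z_list, similarity_from_features)
      s_group <- group_mean_similarity(s_list)
      sol <- hierarchical_cluster(s_group, config$k_values)
      kcol <- as.character(S)
      lab_arr <- array(0L, dim(truth$cord_labels$data))
      lab_arr[which(cord_mask)] <- sol$labels[, kcol]
      match <- match_labels_max_weight(label_map(lab_arr),
                                       truth$cord_labels,
                                       config$match_weight)
      stab <- intersubject_profile_stability(s_list)
      indiv <- lapply(s_list, function(Si)
        hierarchical_cluster(Si, S)$labels[, 1])
      align <- subject_group_alignment(indiv, sol$labels[, kcol])
      fp <- cluster_fingerprints(sol$labels[, kcol], z_list)
      list(z_list = z_list, similarity = s_group, solution = sol,
           cluster_map = label_map(lab_arr), match = match,
           stability = stab, alignment = align, fingerprints = fp)
    })
    summaries$parcellation <- list(
      mean_dice = parc$match$mean_dice, sd_dice = parc$match$sd_dice,
      stability_grand_mean = parc$stability$grand_mean)
    res$parcellation <- parc
  }

  hashes <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    if (!is.null(res$seedfc)) {
      p <- file.path(config$out_dir, "group_wta.nii")
      write_image(res$seedfc$group_wta$labels, p); paths <- c(paths, p)
      p <- file.path(config$out_dir, "wta_counts.tsv")
      utils::write.table(res$seedfc$counts, p, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(res$parcellation)) {
      p <- file.path(config$out_dir, "parcellation_k.nii")
      write_image(res$parcellation$cluster_map, p); paths <- c(paths, p)
    }
    hashes <- as.list(tools::md5sum(paths))
  }

  structure(list(config = config, version = as.character(
    utils::packageVersion("cordmap")),
    stage_seconds = t_all, summaries = summaries,
    hashes = hashes, results = res),
    class = "run_manifest")
}

# internal: winner-take-all over cord iCAP maps -> seed label map
icap_seeds <- function(icap_set, cord_mask, dims, z_threshold = 1.5) {
  maps <- icap_set$maps
  lab <- max.col(maps, ties.method = "first")
  lab[maps[cbind(seq_len(nrow(maps)), lab)] < z_threshold] <- 0L
  arr <- array(0L, dims)
  arr[which(cord_mask)] <- lab
  label_map(arr)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n  stages:",
      paste(names(x$stage_seconds), collapse = ", "), "\n")
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %s: %s\n", nm, paste(
      sprintf("%s=%s", names(s),
              vapply(s, function(v) format(v, digits = 4), "")),
      collapse = ", ")))
  }
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Regenerates the QC / consensus / Dice / stability summary from a
#' manifest alone, as markdown plus a JSON-ready list.
#'
#' @param manifest a `run_manifest`.
#' @param path optional file to write the markdown to (a sibling `.json`
#'   is written alongside).
#' @return list with `markdown` (character vector of lines) and `json`
#'   (the summary list), invisibly when `path` is given.
#' @export
emit_report <- function(manifest, path = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  all_stages <- c("qc", "denoise", "icap", "seedfc", "parcellation")
  lines <- c("# Pipeline report", "",
             sprintf("- package version: %s", manifest$version))
  for (st in all_stages) {
    s <- manifest$summaries[[st]]
    if (is.null(s)) {
      lines <- c(lines, sprintf("- stage `%s`: skipped", st))
      next
    }
    lines <- c(lines, sprintf("- stage `%s` (%.2f s):", st,
                              manifest$stage_seconds[[st]] %||% NA_real_))
    lines <- c(lines, vapply(names(s), function(k)
      sprintf("    - %s: %s", k, format(s[[k]], digits = 4)), ""))
  }
  if (!is.null(manifest$summaries$parcellation))
    lines <- c(lines, "",
               sprintf("Mean matched Dice: %.4f",
                       manifest$summaries$parcellation$mean_dice))
  json <- list(version = manifest$version,
               stage_seconds = manifest$stage_seconds,
               summaries = manifest$summaries)
  if (!is.null(path)) {
    writeLines(lines, path)
    jsonlite::write_json(json, sub("\\.md$", ".json", paste0(path, ".json")),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(markdown = lines, json = json)))
  }
  list(markdown = lines, json = json)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
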