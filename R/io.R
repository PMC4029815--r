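# File I/O and the end-to-end pipeline entry points: NIfTI readers/writers
# for runs, masks and statistic maps, TSV logs, the run manifest, and the
# simulate / analyze drivers that chain every stage.

#' NIfTI I/O for runs, masks and maps
#'
#' Thin wrappers around RNifti that carry the acquisition grid's voxel
#' size and TR into the NIfTI header.
#'
#' @param series a `volume_series`.
#' @param grid an [acquisition_grid()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return Writers return `path` invisibly.
#' @export
write_series_nifti <- function(series, path) {
  grid <- series$grid
  arr <- array(series$data, c(grid$dims, ncol(series$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(grid$voxel_size_mm, grid$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_series_nifti
#' @param design the [block_design()] of the stored run (re-attached on
#'   read; the NIfTI itself has no protocol information).
#' @export
read_series_nifti <- function(path, design, grid = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(grid)) {
    pd <- RNifti::pixdim(img)
    grid <- acquisition_grid(d[1:3], pd[1:3],
                             if (length(pd) >= 4L && pd[4] > 0) pd[4] else 2)
  }
  structure(list(grid = grid,
                 data = matrix(as.vector(img), prod(d[1:3]), d[4]),
                 run_id = design$run_id, design = design,
                 feedback_stream = NULL),
            class = "volume_series")
}

#' @rdname write_series_nifti
#' @param mask logical 3D array.
#' @export
write_mask_nifti <- function(mask, grid, path) {
  img <- RNifti::asNifti(array(as.integer(mask), grid$dims))
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_series_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img) != 0, dim(img))
}

#' @rdname write_series_nifti
#' @param map numeric 3D array (e.g. a t or consistency map).
#' @export
write_map_nifti <- function(map, grid, path) {
  img <- RNifti::asNifti(array(as.numeric(map), grid$dims))
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Feedback-log TSV
#'
#' @param frames feedback-frame data frame ([map_level()] /
#'   [random_stream()]).
#' @param path output path.
#' @export
write_feedback_log <- function(frames, path) {
  utils::write.table(frames, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feedback_log
#' @export
read_feedback_log <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# training-run-only dataset (no classification sessions): same per-subject
# seeding as simulate_cohort, but only run 1 is generated
.simulate_training_only <- function(cfg, grid, base_state) {
  atlas <- make_atlas(grid, seed = cfg$seed)
  n_sub <- 2L * cfg$n_per_group
  groups <- rep(c("NFB", "CTR"), each = cfg$n_per_group)
  draws <- .cohort_draws(cfg$seed, n_sub, base_state, 0.1, c(0.6, 1.4))
  for (s in seq_len(n_sub)) {
    start_cond <- if (s %% 2L == 1L) "tenderness" else "pride"
    st <- subject_state(amp_tenderness = max(0.05, draws$amp_t[s]),
                        amp_pride = max(0.05, draws$amp_p[s]),
                        learning_rate = base_state$learning_rate *
                          draws$eta_mult[s],
                        noise_sd = base_state$noise_sd,
                        ar_coeff = base_state$ar_coeff,
                        drift_slope = base_state$drift_slope,
                        group = groups[s],
                        rng_seed = (draws$sub_seed[s] + 7919L) %%
                          .Machine$integer.max)
    run <- simulate_run(st, atlas, make_default_design(start_cond, 0L))
    .write_run_artifacts(cfg$out_dir, s, 1L, run, NULL)
  }
  list(outcomes = data.frame(subject_id = sprintf("sub-%02d",
                                                  seq_len(n_sub)),
                             group = groups, stringsAsFactors = FALSE),
       atlas = atlas)
}

# write one run's artifacts for cli_simulate; returns the run NIfTI path
.write_run_artifacts <- function(out_dir, subject, run_k, run, frames) {
  sdir <- file.path(out_dir, sprintf("sub-%02d", subject))
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(sdir, sprintf("run-%d", run_k))
  write_series_nifti(run, paste0(base, "_bold.nii.gz"))
  write_design_tsv(run$design, paste0(base, "_design.tsv"))
  if (!is.null(frames))
    write_feedback_log(frames, paste0(base, "_feedback.tsv"))
  paste0(base, "_bold.nii.gz")
}

#' Simulate a cohort to disk
#'
#' Runs [simulate_cohort()] and writes the complete dataset: per-subject
#' run NIfTIs with design and feedback-log TSVs, the shared feature mask
#' and SVC ROI, the outcome table, and a JSON manifest tying it together.
#'
#' @param config a named list or the path of a YAML file with any of the
#'   keys `out_dir` (required), `seed`, `n_per_group`, `n_runs`, `dims`,
#'   `voxel_size_mm`, `tr_seconds`, `fwhm_mm`, `c_param`, `d_max`, and the
#'   [subject_state()] fields (`amp_tenderness`, `amp_pride`,
#'   `learning_rate`, `noise_sd`, `ar_coeff`, `drift_slope`).
#' @return The manifest (list), invisibly; also written as
#'   `<out_dir>/manifest.json`.
#' @export
cli_simulate <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("out_dir", "seed", "n_per_group", "n_runs", "dims",
             "voxel_size_mm", "tr_seconds", "fwhm_mm", "c_param", "d_max",
             "amp_tenderness", "amp_pride", "learning_rate", "noise_sd",
             "ar_coeff", "drift_slope")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("invalid config keys: ", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  cfg <- utils::modifyList(list(seed = 1L, n_per_group = 12L, n_runs = 4L,
                                dims = c(24L, 24L, 12L),
                                voxel_size_mm = c(3, 3, 3), tr_seconds = 2,
                                fwhm_mm = 6, c_param = 1, d_max = 1),
                           config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- acquisition_grid(cfg$dims, cfg$voxel_size_mm, cfg$tr_seconds)
  st_args <- config[intersect(names(config),
                              c("amp_tenderness", "amp_pride",
                                "learning_rate", "noise_sd", "ar_coeff",
                                "drift_slope"))]
  base_state <- do.call(subject_state, st_args)
  if (cfg$n_runs < 2L) {
    coh <- .simulate_training_only(cfg, grid, base_state)
  } else
  coh <- simulate_cohort(n_per_group = cfg$n_per_group,
                         n_runs = cfg$n_runs, seed = cfg$seed, grid = grid,
                         base_state = base_state,
                         preproc = preproc_config(fwhm_mm = cfg$fwhm_mm),
                         c_param = cfg$c_param,
                         feedback_cfg = feedback_config(d_max = cfg$d_max),
                         out_dir = cfg$out_dir)
  write_mask_nifti(coh$atlas$feature_mask, grid,
                   file.path(cfg$out_dir, "feature_mask.nii.gz"))
  write_mask_nifti(coh$atlas$svc_roi, grid,
                   file.path(cfg$out_dir, "svc_roi.nii.gz"))
  utils::write.table(coh$outcomes,
                     file.path(cfg$out_dir, "outcomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = cfg$seed, n_per_group = cfg$n_per_group, n_runs = cfg$n_runs,
    dims = grid$dims, voxel_size_mm = grid$voxel_size_mm,
    tr_seconds = grid$tr_seconds, fwhm_mm = cfg$fwhm_mm,
    c_param = cfg$c_param, d_max = cfg$d_max,
    feature_mask = "feature_mask.nii.gz", svc_roi = "svc_roi.nii.gz",
    notes = if (cfg$n_runs < 2L) "no classification sessions" else "",
    subjects = lapply(seq_len(2L * cfg$n_per_group), function(s) list(
      subject_id = sprintf("sub-%02d", s),
      group = coh$outcomes$group[s],
      start_condition = if (s %% 2L == 1L) "tenderness" else "pride",
      runs = lapply(seq_len(cfg$n_runs), function(k) {
        base <- sprintf("sub-%02d/run-%d", s, k)
        list(bold = paste0(base, "_bold.nii.gz"),
             design = paste0(base, "_design.tsv"),
             feedback = if (k >= 2L) paste0(base, "_feedback.tsv")
                        else NULL)
      }))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Read and validate a dataset manifest
#'
#' @param path manifest JSON path (as written by [cli_simulate()]).
#' @return The manifest list with an added `root` element.
#' @export
read_manifest <- function(path) {
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  manifest$root <- dirname(path)
  for (sub in manifest$subjects) {
    for (run in sub$runs) {
      for (f in c(run$bold, run$design, run$feedback)) {
        fp <- file.path(manifest$root, f)
        if (!file.exists(fp))
          stop("manifest references missing file: ", fp)
      }
    }
  }
  for (f in c(manifest$feature_mask, manifest$svc_roi)) {
    if (!is.null(f) && !file.exists(file.path(manifest$root, f)))
      stop("manifest references missing file: ", f)
  }
  manifest
}

#' Analyse a simulated dataset end to end
#'
#' Re-runs the full offline pipeline on a dataset written by
#' [cli_simulate()]: per-subject preprocessing and per-session decoder
#' retraining, the classification outcome table and group report,
#' per-group discriminant-voxel consistency maps (top 2%), the first-level
#' block GLM per classification run, and the second-level covariate
#' regression with permutation small-volume correction inside the stored
#' ROI.  All results are written under `out_dir`.
#'
#' @param manifest a manifest list from [read_manifest()], or its path.
#' @param out_dir output directory for reports and maps.
#' @param n_perm permutations for the SVC step.
#' @param fraction discriminant-map top fraction.
#' @return list with `outcomes`, `report`, `consistency` (per group),
#'   `svc` (or `NULL` with a note when fewer than 3 subjects have a
#'   covariate), invisibly.
#' @export
cli_analyze <- function(manifest, out_dir, n_perm = 499L,
                        fraction = 0.02) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  root <- manifest$root
  grid <- acquisition_grid(unlist(manifest$dims),
                           unlist(manifest$voxel_size_mm),
                           manifest$tr_seconds)
  mask <- read_mask_nifti(file.path(root, manifest$feature_mask))
  roi <- read_mask_nifti(file.path(root, manifest$svc_roi))
  pp <- preproc_config(fwhm_mm = manifest$fwhm_mm)
  n_runs <- manifest$n_runs
  if (n_runs < 2L)
    stop("analysis stage 'decode': dataset has no classification sessions")
  subs <- manifest$subjects
  n_sessions <- n_runs - 1L
  pct <- matrix(NA_real_, length(subs), n_sessions)
  n_usable_t <- integer(length(subs))
  dmaps <- list()
  contrasts <- matrix(NA_real_, length(subs), grid$n_voxels)
  groups <- vapply(subs, `[[`, character(1), "group")
  for (s in seq_along(subs)) {
    sub <- subs[[s]]
    prev_feat <- NULL
    glm_acc <- NULL
    sub_dmaps <- list()
    for (k in seq_len(n_runs)) {
      run_info <- sub$runs[[k]]
      design <- read_design_tsv(file.path(root, run_info$design))
      run <- read_series_nifti(file.path(root, run_info$bold), design,
                               grid)
      feat <- preprocess_run(run, mask, pp)
      if (k >= 2L) {
        dec <- train_decoder(prev_feat$features, prev_feat$condition,
                             c_param = manifest$c_param)
        pred <- classify(dec, feat$features)
        sel_t <- feat$condition == "tenderness"
        pct[s, k - 1L] <- 100 * mean(pred[sel_t] == "tenderness")
        n_usable_t[s] <- sum(sel_t)
        sub_dmaps[[length(sub_dmaps) + 1L]] <-
          discriminant_map(dec, fraction)
        X <- build_design(design)
        cm <- fit_subject(run, X)
        glm_acc <- if (is.null(glm_acc)) cm$contrast
                   else glm_acc + cm$contrast
      }
      prev_feat <- feat
    }
    cmb <- consistency_map(sub_dmaps)  # per-subject union across sessions
    dm <- sub_dmaps[[length(sub_dmaps)]]
    dm$top_mask <- cmb$fraction > 0
    dmaps[[s]] <- dm
    contrasts[s, ] <- glm_acc / n_sessions
  }
  outcomes <- data.frame(
    subject_id = vapply(subs, `[[`, character(1), "subject_id"),
    group = groups, stringsAsFactors = FALSE)
  for (j in seq_len(n_sessions))
    outcomes[[sprintf("pct_session_%d", j)]] <- pct[, j]
  outcomes$delta_last_first <- pct[, n_sessions] - pct[, 1L]
  outcomes$covariate <- outcomes$delta_last_first
  outcomes$n_usable_tenderness <- n_usable_t
  report <- cohort_report(outcomes)
  write_report(report, file.path(out_dir, "decoding"))
  utils::write.table(outcomes, file.path(out_dir, "outcomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  consistency <- list()
  for (g in unique(groups)) {
    cm <- consistency_map(dmaps[groups == g])
    vox <- numeric(grid$n_voxels)
    vox[as.vector(mask)] <- cm$fraction
    write_map_nifti(array(vox, grid$dims), grid,
                    file.path(out_dir,
                              sprintf("consistency_%s.nii.gz", g)))
    consistency[[g]] <- cm
  }
  svc <- NULL
  svc_note <- ""
  if (length(subs) >= 3L && stats::sd(outcomes$covariate) > 0 &&
      n_sessions >= 2L) {
    sl <- second_level(contrasts, outcomes$covariate)
    vox <- array(sl$t, grid$dims)
    write_map_nifti(vox, grid, file.path(out_dir, "covariate_t.nii.gz"))
    svc <- svc_correct(sl, roi, contrasts, outcomes$covariate,
                       n_perm = n_perm, seed = manifest$seed, grid = grid,
                       roi_name = "svc_roi")
    utils::write.table(
      data.frame(roi = svc$roi_name, peak_t = svc$peak_t,
                 peak_x = svc$peak_voxel[1], peak_y = svc$peak_voxel[2],
                 peak_z = svc$peak_voxel[3], cluster_k = svc$cluster_k,
                 fwe_p = svc$fwe_p, n_perm = svc$n_perm),
      file.path(out_dir, "svc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  } else {
    svc_note <- "second level skipped: needs >= 3 subjects, >= 2 sessions and a non-constant covariate"
  }
  invisible(list(outcomes = outcomes, report = report,
                 consistency = consistency, svc = svc,
                 svc_note = svc_note))
}
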