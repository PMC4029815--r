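# Closed-loop synthetic subject: latent activation amplitudes for the two
# emotional conditions, HRF-shaped block responses on spatial patterns,
# drift + AR(1) noise, and a feedback-driven learning rule that only acts
# on contingently-fed-back (NFB) subjects.

#' Acquisition grid geometry
#'
#' Desk-scale stand-in for an EPI acquisition matrix: voxel lattice
#' dimensions, voxel size and repetition time.
#'
#' @param dims integer vector of 3 lattice dimensions (all >= 4).
#' @param voxel_size_mm numeric vector of 3 voxel edge lengths in mm.
#' @param tr_seconds repetition time in seconds.
#' @return An object of class `acquisition_grid`.
#' @export
acquisition_grid <- function(dims = c(24L, 24L, 12L),
                             voxel_size_mm = c(3, 3, 3),
                             tr_seconds = 2) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, length(voxel_size_mm) == 3L)
  if (any(dims < 4L)) stop("all grid dimensions must be >= 4")
  if (any(voxel_size_mm <= 0) || tr_seconds <= 0)
    stop("voxel sizes and TR must be positive")
  structure(list(dims = dims, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_seconds = tr_seconds, n_voxels = prod(dims)),
            class = "acquisition_grid")
}

#' @export
print.acquisition_grid <- function(x, ...) {
  cat(sprintf("<acquisition_grid> %dx%dx%d voxels, %gx%gx%g mm, TR %g s\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_mm[1],
              x$voxel_size_mm[2], x$voxel_size_mm[3], x$tr_seconds))
  invisible(x)
}

# logical ellipsoid on the grid; center/semi in (possibly fractional) voxel
# coordinates (1-based)
.ellipsoid_mask <- function(dims, center, semi) {
  x <- (seq_len(dims[1]) - center[1]) / semi[1]
  y <- (seq_len(dims[2]) - center[2]) / semi[2]
  z <- (seq_len(dims[3]) - center[3]) / semi[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d2 <= 1
}

.ellipsoid_dist2 <- function(dims, center, semi) {
  x <- (seq_len(dims[1]) - center[1]) / semi[1]
  y <- (seq_len(dims[2]) - center[2]) / semi[2]
  z <- (seq_len(dims[3]) - center[3]) / semi[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

#' Build the pattern atlas for a synthetic subject
#'
#' Places two disjoint ellipsoidal activation patterns (tenderness and
#' pride) inside a larger ellipsoidal feature mask, plus a small
#' "small-volume correction" ROI overlapping the tenderness pattern
#' (emulating an a-priori basal-forebrain ROI of a few dozen voxels).
#' Pattern values fall off smoothly from the region centre and carry a
#' seeded multiplicative jitter, so the two patterns are fixed, linearly
#' independent spatial signatures.
#'
#' @param grid an [acquisition_grid()].
#' @param seed integer seed controlling the pattern jitter (deterministic).
#' @return An object of class `pattern_atlas` with logical 3D arrays
#'   `feature_mask`, `svc_roi` and numeric 3D arrays `tenderness_pattern`,
#'   `pride_pattern` (zero outside their regions).
#' @export
make_atlas <- function(grid, seed = 1L) {
  stopifnot(inherits(grid, "acquisition_grid"))
  dims <- grid$dims
  ctr <- (dims + 1) / 2
  feat_semi <- 0.45 * dims
  feature_mask <- .ellipsoid_mask(dims, ctr, feat_semi)
  pat_semi <- pmax(0.15 * dims, 1.2)
  off <- 0.22 * dims[1]
  t_ctr <- c(ctr[1] - off, ctr[2], ctr[3])
  p_ctr <- c(ctr[1] + off, ctr[2], ctr[3])
  t_d2 <- .ellipsoid_dist2(dims, t_ctr, pat_semi)
  p_d2 <- .ellipsoid_dist2(dims, p_ctr, pat_semi)
  t_region <- (t_d2 <= 1) & feature_mask
  p_region <- (p_d2 <= 1) & feature_mask
  if (!any(t_region) || !any(p_region))
    stop("grid too small to place the two pattern regions")
  if (any(t_region & p_region))
    stop("grid too small: pattern regions overlap")
  jitter <- withr::with_seed(as.integer(seed), {
    array(stats::runif(prod(dims), 0.8, 1.2), dims)
  })
  t_pat <- ifelse(t_region, exp(-2 * t_d2) * jitter, 0)
  p_pat <- ifelse(p_region, exp(-2 * p_d2) * jitter, 0)
  roi_semi <- pmax(c(0.125, 0.125, 0.13) * dims, 1.1)
  svc_roi <- .ellipsoid_mask(dims, t_ctr, roi_semi) & feature_mask
  structure(list(grid = grid,
                 feature_mask = feature_mask,
                 tenderness_pattern = t_pat,
                 pride_pattern = p_pat,
                 svc_roi = svc_roi,
                 seed = as.integer(seed)),
            class = "pattern_atlas")
}

#' @export
print.pattern_atlas <- function(x, ...) {
  cat(sprintf(paste0("<pattern_atlas> feature mask %d voxels; tenderness ",
                     "pattern %d, pride pattern %d, SVC ROI %d voxels\n"),
              sum(x$feature_mask), sum(x$tenderness_pattern > 0),
              sum(x$pride_pattern > 0), sum(x$svc_roi)))
  invisible(x)
}

#' Latent state of a synthetic subject
#'
#' Holds the condition-specific signal amplitudes (in units of the BOLD
#' baseline, i.e. an amplitude of 1 on a pattern value of 1 is a 1-unit
#' deflection on a baseline of 100), the learning rate that converts
#' feedback into amplitude gain, and the noise model.  Control (CTR)
#' subjects never update their amplitudes from feedback, whatever their
#' nominal learning rate.
#'
#' @param amp_tenderness,amp_pride signal amplitudes (arbitrary units).
#' @param learning_rate eta >= 0; amplitude gain per unit of normalised
#'   feedback (see [update_state()]).
#' @param noise_sd marginal standard deviation of the AR(1) voxel noise.
#' @param ar_coeff AR(1) coefficient phi in [0, 1).
#' @param drift_slope linear drift in signal units per volume.
#' @param group `"NFB"` (contingent feedback) or `"CTR"` (random feedback).
#' @param rng_seed integer seed for the run noise.
#' @return An object of class `subject_state`.
#' @export
subject_state <- function(amp_tenderness = 0.6, amp_pride = 0.6,
                          learning_rate = 2, noise_sd = 5,
                          ar_coeff = 0.3, drift_slope = 0.02,
                          group = c("NFB", "CTR"), rng_seed = 1L) {
  group <- match.arg(group)
  stopifnot(learning_rate >= 0, noise_sd >= 0,
            ar_coeff >= 0, ar_coeff < 1)
  structure(list(amp_tenderness = amp_tenderness, amp_pride = amp_pride,
                 learning_rate = learning_rate, noise_sd = noise_sd,
                 ar_coeff = ar_coeff, drift_slope = drift_slope,
                 group = group, rng_seed = as.integer(rng_seed)),
            class = "subject_state")
}

#' Canonical double-gamma haemodynamic response function
#'
#' Standard canonical HRF: a gamma response peaking near 5-6 s minus a
#' 1/6-amplitude undershoot gamma peaking near 15-16 s, 32 s support,
#' normalised so the (continuous-time) peak equals 1, sampled at the TR.
#'
#' @param tr_seconds sampling interval (the TR), > 0.
#' @param duration_s kernel support in seconds.
#' @return Numeric vector of kernel taps at times `0, tr, 2*tr, ...`
#'   (attribute `times`).
#' @export
hrf_kernel <- function(tr_seconds, duration_s = 32) {
  stopifnot(tr_seconds > 0)
  tfine <- seq(0, duration_s, by = 0.01)
  shape <- function(t) stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  peak <- max(shape(tfine))
  tt <- seq(0, duration_s, by = tr_seconds)
  h <- shape(tt) / peak
  attr(h, "times") <- tt
  h
}

# per-subject seeded jitter of amplitudes and learning rates
.cohort_draws <- function(seed, n_sub, base_state, amp_jitter_sd,
                          eta_jitter_range) {
  withr::with_seed(as.integer(seed), {
    list(sub_seed = sample.int(.Machine$integer.max %/% 2L, n_sub),
         amp_t = stats::rnorm(n_sub, base_state$amp_tenderness,
                              amp_jitter_sd),
         amp_p = stats::rnorm(n_sub, base_state$amp_pride, amp_jitter_sd),
         eta_mult = stats::runif(n_sub, eta_jitter_range[1],
                                 eta_jitter_range[2]))
  })
}

# convolve a per-volume boxcar with the HRF, truncated to run length
.convolve_boxcar <- function(box, h) {
  n <- length(box)
  full <- stats::convolve(box, rev(h), type = "open")
  full[seq_len(n)]
}

#' Simulate one run of a synthetic subject
#'
#' Voxel time series = baseline (100) + per-condition amplitude x spatial
#' pattern x HRF-convolved block boxcar + linear drift + AR(1) Gaussian
#' noise.  Neutral blocks carry baseline + drift + noise only.  The
#' optional per-volume feedback stream does not alter the signal (learning
#' acts between runs, see [update_state()]); it is stored with the series
#' for logging.
#'
#' @param state a [subject_state()]; `state$rng_seed` fixes the noise.
#' @param atlas a [make_atlas()] atlas on the target grid.
#' @param design a [block_design()].
#' @param feedback_stream optional integer vector of ring levels, one per
#'   volume (NA where no feedback was shown).
#' @return An object of class `volume_series`: list with `grid`, `data`
#'   (matrix, voxels x volumes, voxel order = x fastest), `run_id`,
#'   `design`, `feedback_stream`.
#' @export
simulate_run <- function(state, atlas, design, feedback_stream = NULL) {
  stopifnot(inherits(state, "subject_state"),
            inherits(atlas, "pattern_atlas"),
            inherits(design, "block_design"))
  grid <- atlas$grid
  nt <- design$n_volumes
  if (!is.null(feedback_stream) && length(feedback_stream) != nt)
    stop("feedback_stream length must match the design's volume count")
  labels <- label_volumes(design)
  h <- hrf_kernel(grid$tr_seconds)
  nv <- grid$n_voxels
  data <- matrix(100 + state$drift_slope * (seq_len(nt) - 1),
                 nrow = nv, ncol = nt, byrow = TRUE)
  amps <- c(tenderness = state$amp_tenderness, pride = state$amp_pride)
  pats <- list(tenderness = as.vector(atlas$tenderness_pattern),
               pride = as.vector(atlas$pride_pattern))
  for (cond in names(amps)) {
    box <- as.numeric(labels$condition == cond)
    if (!any(box > 0) || amps[[cond]] == 0) next
    reg <- .convolve_boxcar(box, h)
    data <- data + amps[[cond]] * tcrossprod(pats[[cond]], reg)
  }
  if (state$noise_sd > 0) {
    phi <- state$ar_coeff
    sd_innov <- state$noise_sd * sqrt(1 - phi^2)
    noise <- withr::with_seed(state$rng_seed, {
      e <- matrix(stats::rnorm(nv * nt), nv, nt)
      e[, 1L] <- state$noise_sd * e[, 1L]
      if (phi > 0 && nt > 1L) {
        for (t in 2:nt) e[, t] <- phi * e[, t - 1L] + sd_innov * e[, t]
      } else if (nt > 1L) {
        e[, 2:nt] <- state$noise_sd * e[, 2:nt]
      }
      e
    })
    data <- data + noise
  }
  structure(list(grid = grid, data = data, run_id = design$run_id,
                 design = design, feedback_stream = feedback_stream),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> run %d: %d voxels x %d volumes\n",
              x$run_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Between-run learning update
#'
#' Converts the feedback a subject received during a run into an amplitude
#' change before the next run.  Contingent (neurofeedback) subjects gain
#' `eta * (mean_level - 10.5) / 9.5` on the tenderness amplitude (floored
#' at 0), so feedback above the mid-level (10.5 of 1..20) reinforces the
#' target pattern and feedback below it weakens it.  Non-contingent
#' (control) feedback leaves the state unchanged.
#'
#' @param state a [subject_state()].
#' @param mean_feedback_level mean ring level in [1, 20] over the run's
#'   tenderness volumes.
#' @param contingent logical; was the feedback driven by the decoder?
#' @return The updated `subject_state`.
#' @export
update_state <- function(state, mean_feedback_level, contingent) {
  stopifnot(inherits(state, "subject_state"))
  if (!contingent) return(state)
  if (is.na(mean_feedback_level) || mean_feedback_level < 1 ||
      mean_feedback_level > 20)
    stop("mean_feedback_level must lie in [1, 20]")
  delta <- state$learning_rate * (mean_feedback_level - 10.5) / 9.5
  state$amp_tenderness <- max(0, state$amp_tenderness + delta)
  state
}

#' Simulate a full closed-loop cohort
#'
#' Runs the entire experiment for `n_per_group` neurofeedback (NFB) and
#' `n_per_group` control (CTR) subjects: run 1 is decoder training (no
#' feedback); in each later run the decoder trained on the previous run
#' classifies every usable volume in real time and drives ring feedback
#' (contingent for NFB subjects, seeded-uniform random levels for CTR
#' subjects).  Between runs each NFB subject's tenderness amplitude is
#' updated from the mean feedback level over tenderness volumes
#' ([update_state()]); CTR states never change.  Subjects differ by seeded
#' jitter of their amplitudes and learning rates, and the emotional block
#' order is counterbalanced within each group.
#'
#' @param n_per_group subjects per group.
#' @param n_runs total runs including the training run (>= 2).
#' @param seed master seed; all randomness derives from it.
#' @param grid acquisition grid shared by the cohort.
#' @param base_state template [subject_state()]; per-subject amplitudes are
#'   jittered around it and learning rates scaled by a seeded factor.
#' @param preproc a [preproc_config()].
#' @param c_param soft-margin penalty for decoder training.
#' @param feedback_cfg a [feedback_config()].
#' @param amp_jitter_sd SD of the per-subject amplitude jitter.
#' @param eta_jitter_range per-subject learning-rate multiplier range.
#' @param compute_glm if `TRUE`, fit the offline block GLM to every
#'   classification run and return per-subject mean tenderness - pride
#'   contrast maps.
#' @param hp_cutoff_s high-pass cutoff for the GLM design (seconds).
#' @param out_dir optional directory; when given, every run is written as
#'   NIfTI together with design and feedback-log TSVs (see [cli_simulate()]).
#' @return list with `outcomes` (one row per subject: per-session percent
#'   tenderness, last-minus-first delta, covariate), `feedback` (per-subject
#'   list of per-run feedback-frame tables), `states` (final subject
#'   states), `atlas`, and `contrasts` (subjects x voxels matrix, if
#'   requested).
#' @export
simulate_cohort <- function(n_per_group = 12L, n_runs = 4L, seed = 1L,
                            grid = acquisition_grid(),
                            base_state = subject_state(),
                            preproc = preproc_config(),
                            c_param = 1,
                            feedback_cfg = feedback_config(d_max = 0.08),
                            amp_jitter_sd = 0.1,
                            eta_jitter_range = c(0.6, 1.4),
                            compute_glm = FALSE,
                            hp_cutoff_s = 448,
                            out_dir = NULL) {
  if (n_runs < 2L) stop("n_runs must be >= 2 (run 1 is decoder training)")
  atlas <- make_atlas(grid, seed = seed)
  n_sub <- 2L * n_per_group
  groups <- rep(c("NFB", "CTR"), each = n_per_group)
  draws <- .cohort_draws(seed, n_sub, base_state, amp_jitter_sd,
                         eta_jitter_range)
  mask <- atlas$feature_mask
  n_sessions <- n_runs - 1L
  pct <- matrix(NA_real_, n_sub, n_sessions)
  n_usable_t <- integer(n_sub)
  feedback_logs <- vector("list", n_sub)
  states <- vector("list", n_sub)
  contrasts <- if (compute_glm) matrix(NA_real_, n_sub, grid$n_voxels)
               else NULL
  manifest_runs <- if (!is.null(out_dir)) vector("list", n_sub) else NULL
  design_cache <- list()
  for (s in seq_len(n_sub)) {
    start_cond <- if (s %% 2L == 1L) "tenderness" else "pride"
    st <- subject_state(amp_tenderness = max(0.05, draws$amp_t[s]),
                        amp_pride = max(0.05, draws$amp_p[s]),
                        learning_rate = base_state$learning_rate *
                          draws$eta_mult[s],
                        noise_sd = base_state$noise_sd,
                        ar_coeff = base_state$ar_coeff,
                        drift_slope = base_state$drift_slope,
                        group = groups[s], rng_seed = draws$sub_seed[s])
    st$amp_tenderness_init <- st$amp_tenderness
    prev_feat <- NULL
    fb_runs <- vector("list", n_runs)
    sub_paths <- character(0)
    glm_acc <- NULL
    for (k in seq_len(n_runs)) {
      key <- paste(start_cond, k)
      if (is.null(design_cache[[key]]))
        design_cache[[key]] <- make_default_design(start_cond,
                                                   run_id = k - 1L)
      design <- design_cache[[key]]
      st$rng_seed <- (draws$sub_seed[s] + 7919L * k) %% .Machine$integer.max
      run <- simulate_run(st, atlas, design)
      feat <- preprocess_run(run, mask, preproc)
      if (k >= 2L) {
        dec <- train_decoder(prev_feat$features, prev_feat$condition,
                             c_param = c_param)
        dec$trained_on <- k - 2L
        d <- decision_value(dec, feat$features)
        pred <- classify(dec, feat$features)
        sel_t <- feat$condition == "tenderness"
        pct[s, k - 1L] <- 100 * mean(pred[sel_t] == "tenderness")
        n_usable_t[s] <- sum(sel_t)
        if (groups[s] == "NFB") {
          frames <- map_level(d, feat$condition, cfg = feedback_cfg,
                              volume_index = feat$volume_index)
        } else {
          cfg_s <- feedback_cfg
          cfg_s$seed <- (draws$sub_seed[s] + 104729L * k) %%
            .Machine$integer.max
          frames <- random_stream(length(d), cfg_s)
          frames$volume_index <- feat$volume_index
          frames$target_condition <- feat$condition
        }
        fb_runs[[k]] <- frames
        mean_lvl <- mean(frames$level[feat$condition == "tenderness"])
        st <- update_state(st, mean_lvl, contingent = groups[s] == "NFB")
        if (compute_glm) {
          X <- build_design(design, hp_cutoff_s = hp_cutoff_s)
          cm <- fit_subject(run, X)
          glm_acc <- if (is.null(glm_acc)) cm$contrast
                     else glm_acc + cm$contrast
        }
      }
      if (!is.null(out_dir)) {
        sub_paths <- c(sub_paths,
                       .write_run_artifacts(out_dir, s, k, run,
                                            fb_runs[[k]]))
      }
      prev_feat <- feat
    }
    feedback_logs[[s]] <- fb_runs
    states[[s]] <- st
    if (compute_glm) contrasts[s, ] <- glm_acc / n_sessions
    if (!is.null(out_dir)) manifest_runs[[s]] <- sub_paths
  }
  outcomes <- data.frame(subject_id = sprintf("sub-%02d", seq_len(n_sub)),
                         group = groups, stringsAsFactors = FALSE)
  for (j in seq_len(n_sessions))
    outcomes[[sprintf("pct_session_%d", j)]] <- pct[, j]
  outcomes$delta_last_first <- pct[, n_sessions] - pct[, 1L]
  outcomes$covariate <- outcomes$delta_last_first
  outcomes$n_usable_tenderness <- n_usable_t
  res <- list(outcomes = outcomes, feedback = feedback_logs,
              states = states, atlas = atlas, contrasts = contrasts,
              seed = as.integer(seed), n_runs = n_runs)
  if (!is.null(out_dir)) res$run_paths <- manifest_runs
  class(res) <- "nf_cohort"
  res
}

#' @export
print.nf_cohort <- function(x, ...) {
  o <- x$outcomes
  for (g in unique(o$group)) {
    d <- o$delta_last_first[o$group == g]
    cat(sprintf("  %s (n=%d): delta last-first = %.1f%% +/- %.1f%%\n",
                g, length(d), mean(d), stats::sd(d)))
  }
  invisible(x)
}
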