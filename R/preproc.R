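# Incremental (volume-by-volume) preprocessing: optional translation
# realignment, separable Gaussian smoothing, preceding-neutral-block
# baseline subtraction, feature extraction over the mask.
#
# Order of operations mirrors the online pipeline: realign -> smooth ->
# baseline-normalise.  Everything is causal: the output for volume t uses
# only volumes <= t (the baseline is the most recent *completed* neutral
# block).

#' Real-time preprocessing configuration
#'
#' @param fwhm_mm Gaussian smoothing kernel full width at half maximum in
#'   mm (0 disables smoothing). Default 6 mm.
#' @param realign enable translation-only realignment to the run's first
#'   volume (off by default; simulated data are motion-free).
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(fwhm_mm = 6, realign = FALSE) {
  stopifnot(fwhm_mm >= 0)
  structure(list(fwhm_mm = fwhm_mm, realign = realign,
                 baseline_mode = "preceding-neutral-mean"),
            class = "preproc_config")
}

# 1D smoothing matrix: truncated Gaussian rows, each renormalised to sum 1
# so constant fields are preserved exactly, including at the boundaries.
.smoother_1d <- function(n, sd_vox) {
  if (sd_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sd_vox))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= r, exp(-d^2 / (2 * sd_vox^2)), 0)
  })
  K / rowSums(K)
}

# Apply separable per-axis smoothing to data laid out voxels x time with
# x the fastest-varying voxel index.
.smooth_matrix <- function(data, dims, sds) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nt <- ncol(data)
  if (sds[1] > 0) {
    K <- .smoother_1d(nx, sds[1])
    data <- matrix(K %*% matrix(data, nx, ny * nz * nt), nrow = nx * ny * nz)
  }
  if (sds[2] > 0) {
    K <- .smoother_1d(ny, sds[2])
    a <- aperm(array(data, c(nx, ny, nz * nt)), c(2, 1, 3))
    a <- array(K %*% matrix(a, ny, nx * nz * nt), c(ny, nx, nz * nt))
    data <- matrix(aperm(a, c(2, 1, 3)), nrow = nx * ny * nz)
  }
  if (sds[3] > 0) {
    K <- .smoother_1d(nz, sds[3])
    a <- aperm(array(data, c(nx * ny, nz, nt)), c(2, 1, 3))
    a <- array(K %*% matrix(a, nz, nx * ny * nt), c(nz, nx * ny, nt))
    data <- matrix(aperm(a, c(2, 1, 3)), nrow = nx * ny * nz)
  }
  data
}

#' Spatial Gaussian smoothing of one volume
#'
#' Separable 3D Gaussian with per-axis standard deviation
#' `fwhm / (2 sqrt(2 ln 2))` converted to voxel units.  The kernel is
#' renormalised at the lattice boundaries, so constant volumes pass through
#' unchanged and `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D numeric array.
#' @param grid the [acquisition_grid()] supplying voxel sizes.
#' @param fwhm_mm kernel FWHM in millimetres.
#' @return Smoothed 3D array of the same dimensions.
#' @export
smooth_volume <- function(volume, grid, fwhm_mm = 6) {
  stopifnot(fwhm_mm >= 0, identical(dim(volume), as.integer(grid$dims)) ||
              all(dim(volume) == grid$dims))
  if (fwhm_mm == 0) return(volume)
  sds <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  out <- .smooth_matrix(matrix(as.vector(volume), ncol = 1L), grid$dims, sds)
  array(out, grid$dims)
}

#' Smooth every volume of a run
#'
#' @param data voxels x volumes matrix (x fastest voxel order).
#' @param grid the [acquisition_grid()].
#' @param fwhm_mm kernel FWHM in millimetres.
#' @return Matrix of the same shape.
#' @export
smooth_series <- function(data, grid, fwhm_mm = 6) {
  stopifnot(nrow(data) == grid$n_voxels, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(data)
  sds <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  .smooth_matrix(data, grid$dims, sds)
}

# shift a 3D array by a continuous voxel displacement (trilinear,
# replicate boundary): out(x) = in(x - shift)
.shift_volume <- function(volume, shift) {
  dims <- dim(volume)
  coords <- lapply(1:3, function(a) seq_len(dims[a]) - shift[a])
  cl <- lapply(1:3, function(a) pmin(pmax(coords[[a]], 1), dims[a]))
  f <- lapply(cl, floor)
  c0 <- lapply(1:3, function(a) pmin(f[[a]], dims[a] - 1L))
  w <- lapply(1:3, function(a) cl[[a]] - c0[[a]])
  i0 <- c0[[1]]; j0 <- c0[[2]]; k0 <- c0[[3]]
  wx <- w[[1]]; wy <- w[[2]]; wz <- w[[3]]
  out <- array(0, dims)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- outer(outer(ifelse(rep(dx, dims[1]) == 1, wx, 1 - wx),
                       ifelse(rep(dy, dims[2]) == 1, wy, 1 - wy), `*`),
                 ifelse(rep(dz, dims[3]) == 1, wz, 1 - wz), `*`)
    out <- out + wgt * volume[i0 + dx, j0 + dy, k0 + dz, drop = FALSE]
  }
  out
}

# integer-shifted overlap correlation
.shift_cor <- function(a, b, s) {
  dims <- dim(a)
  ix <- list(); iy <- list()
  for (d in 1:3) {
    if (s[d] >= 0) {
      ia <- (1 + s[d]):dims[d]; ib <- 1:(dims[d] - s[d])
    } else {
      ia <- 1:(dims[d] + s[d]); ib <- (1 - s[d]):dims[d]
    }
    ix[[d]] <- ia; iy[[d]] <- ib
  }
  av <- a[ix[[1]], ix[[2]], ix[[3]]]
  bv <- b[iy[[1]], iy[[2]], iy[[3]]]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(as.vector(av), as.vector(bv))
}

#' Translation-only realignment to a reference volume
#'
#' Estimates the 3D translation that maximises the cross-correlation with
#' the reference over an integer search window, refines each axis to
#' subvoxel precision by quadratic interpolation of the correlation peak,
#' and resamples the volume back by that shift (trilinear).  A stand-in
#' for full rigid-body realignment, adequate for translation-dominated
#' motion.
#'
#' @param volume 3D array to realign.
#' @param reference 3D array on the same grid.
#' @param max_shift integer search radius in voxels per axis.
#' @return list with `volume` (realigned), `shift` (estimated translation,
#'   voxels), `confidence` (peak correlation; low values flag unreliable
#'   estimates, attribute `low_confidence`).
#' @export
realign_translation <- function(volume, reference, max_shift = 3L) {
  stopifnot(all(dim(volume) == dim(reference)))
  if (stats::sd(as.vector(volume)) == 0 ||
      stats::sd(as.vector(reference)) == 0) {
    warning("flat volume: no realignment applied")
    return(list(volume = volume, shift = c(0, 0, 0), confidence = 0,
                low_confidence = TRUE))
  }
  rng <- -max_shift:max_shift
  cc <- array(NA_real_, rep(length(rng), 3L))
  for (i in seq_along(rng)) for (j in seq_along(rng))
    for (k in seq_along(rng))
      cc[i, j, k] <- .shift_cor(volume, reference,
                                c(rng[i], rng[j], rng[k]))
  best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  shift <- c(rng[best[1]], rng[best[2]], rng[best[3]])
  # per-axis quadratic refinement around the integer peak
  refine <- numeric(3)
  for (a in 1:3) {
    idx <- best
    if (best[a] > 1L && best[a] < length(rng)) {
      im <- idx; im[a] <- im[a] - 1L
      ip <- idx; ip[a] <- ip[a] + 1L
      cm <- cc[im[1], im[2], im[3]]
      c0 <- cc[idx[1], idx[2], idx[3]]
      cp <- cc[ip[1], ip[2], ip[3]]
      den <- cm - 2 * c0 + cp
      if (is.finite(den) && den < -1e-12)
        refine[a] <- max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    }
  }
  shift <- shift + refine
  conf <- max(cc)
  list(volume = .shift_volume(volume, -shift), shift = shift,
       confidence = conf, low_confidence = conf < 0.2)
}

#' Mean of the most recent completed neutral block
#'
#' The online normalisation baseline: the voxelwise mean over all volumes
#' of the last neutral block that finished before `current_index`.
#'
#' @param series voxels x volumes matrix of the run so far (columns beyond
#'   `current_index` are ignored, keeping the computation causal).
#' @param labels per-volume labels from [label_volumes()].
#' @param current_index 0-based index of the volume being normalised.
#' @return Numeric vector (one value per voxel).
#' @export
neutral_baseline <- function(series, labels, current_index) {
  neutral_blocks <- unique(labels$block_index[labels$condition == "neutral"])
  ends <- vapply(neutral_blocks, function(b)
    max(labels$volume_index[labels$block_index == b]), numeric(1))
  done <- neutral_blocks[ends < current_index]
  if (!length(done))
    stop("protocol error: no completed neutral block precedes volume ",
         current_index)
  b <- done[length(done)]
  cols <- labels$volume_index[labels$block_index == b] + 1L
  rowMeans(series[, cols, drop = FALSE])
}

#' Extract the masked, baseline-normalised feature vector
#'
#' `values = (volume - baseline)` at mask voxels, in the grid's native
#' voxel order (x fastest, then y, then z) — the ordering shared with the
#' decoder's weight vector.
#'
#' @param volume 3D array or voxel vector.
#' @param baseline same shape as `volume`.
#' @param mask logical array/vector over the grid.
#' @return Numeric feature vector of length `sum(mask)`.
#' @export
extract_features <- function(volume, baseline, mask) {
  v <- as.vector(volume); b <- as.vector(baseline); m <- as.vector(mask)
  stopifnot(length(v) == length(b), length(v) == length(m))
  if (!any(m)) stop("configuration error: empty feature mask")
  (v - b)[m]
}

#' Preprocess a whole run for decoding
#'
#' Applies the real-time pipeline to every volume of a simulated or
#' recorded run — optional realignment to the first volume, Gaussian
#' smoothing, then, for each usable emotional volume, subtraction of the
#' preceding-neutral-block mean — and stacks the masked feature vectors.
#'
#' @param series a [simulate_run()] `volume_series` (or any list with
#'   `data`, `grid`, `design`).
#' @param mask logical feature mask on the grid.
#' @param cfg a [preproc_config()].
#' @return list with `features` (usable volumes x mask voxels matrix),
#'   `condition`, `volume_index` (0-based), `labels` (full label table).
#' @export
preprocess_run <- function(series, mask, cfg = preproc_config()) {
  grid <- series$grid
  data <- series$data
  labels <- label_volumes(series$design)
  if (isTRUE(cfg$realign)) {
    ref <- array(data[, 1L], grid$dims)
    for (t in seq_len(ncol(data))[-1L]) {
      ra <- realign_translation(array(data[, t], grid$dims), ref)
      data[, t] <- as.vector(ra$volume)
    }
  }
  if (cfg$fwhm_mm > 0) data <- smooth_series(data, grid, cfg$fwhm_mm)
  usable <- which(labels$usable)
  m <- as.vector(mask)
  if (!any(m)) stop("configuration error: empty feature mask")
  feats <- matrix(NA_real_, length(usable), sum(m))
  base_cache <- list()
  for (i in seq_along(usable)) {
    row <- usable[i]
    vi <- labels$volume_index[row]
    key <- as.character(labels$block_index[row])
    if (is.null(base_cache[[key]]))
      base_cache[[key]] <- neutral_baseline(data, labels, vi)
    feats[i, ] <- (data[, vi + 1L] - base_cache[[key]])[m]
  }
  list(features = feats,
       condition = labels$condition[usable],
       volume_index = labels$volume_index[usable],
       labels = labels)
}
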