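# Offline univariate analysis: HRF-convolved block GLM with DCT high-pass
# drift regressors, tenderness - pride contrast maps, second-level
# covariate regression, and max-statistic permutation FWE within an ROI
# (small-volume correction).

#' Build the first-level design matrix
#'
#' One HRF-convolved boxcar per condition (the whole block duration),
#' high-pass drift regressors — a linear trend plus discrete-cosine terms
#' for periods longer than the cutoff — and an intercept.  The number of
#' DCT columns follows the usual rule `floor(2 * T * TR / cutoff)`
#' (2 columns for a 296-volume run at TR 2 s and a 448 s cutoff); the
#' explicit linear term makes removal of linear scanner drift exact.
#'
#' @param design a [block_design()].
#' @param hp_cutoff_s high-pass cutoff in seconds (> 2 TR; `Inf` disables
#'   drift columns).
#' @return An object of class `nf_design_matrix`: list with `X` (volumes x
#'   regressors, named columns), `design`, `hp_cutoff_s`.
#' @export
build_design <- function(design, hp_cutoff_s = 448) {
  stopifnot(inherits(design, "block_design"))
  tr <- design$tr_seconds
  if (hp_cutoff_s <= 2 * tr)
    stop("hp_cutoff_s must exceed twice the TR")
  labels <- label_volumes(design)
  nt <- design$n_volumes
  h <- hrf_kernel(tr)
  cols <- list(intercept = rep(1, nt))
  for (cond in .conditions) {
    box <- as.numeric(labels$condition == cond)
    cols[[cond]] <- .convolve_boxcar(box, h)
  }
  k_max <- if (is.finite(hp_cutoff_s)) floor(2 * nt * tr / hp_cutoff_s)
           else 0L
  if (k_max >= 1L) {
    t0 <- seq_len(nt) - 1L
    # linear trend first: the cosine set alone only approximates a ramp,
    # and the residual would leak into the condition regressors
    cols[["drift_linear"]] <- (t0 - mean(t0)) / nt
    for (k in seq_len(k_max))
      cols[[sprintf("dct_%d", k)]] <-
        sqrt(2 / nt) * cos(pi * (2 * t0 + 1) * k / (2 * nt))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (qr(X)$rank < ncol(X))
    stop("design error: rank-deficient design matrix (a condition ",
         "regressor is constant or collinear)")
  structure(list(X = X, design = design, hp_cutoff_s = hp_cutoff_s,
                 n_dct = max(0L, k_max)),
            class = "nf_design_matrix")
}

#' First-level voxelwise GLM and contrast map
#'
#' Ordinary-least-squares fit of the design matrix to every voxel's time
#' series; the contrast is the difference of condition betas
#' (tenderness - pride by default).
#'
#' @param series a `volume_series` (see [simulate_run()]).
#' @param X an [build_design()] design matrix for the same run.
#' @param contrast named numeric vector of weights over design columns.
#' @return An object of class `contrast_map`: list with `contrast` (numeric
#'   per voxel), `betas` (regressors x voxels), `grid`, `run_id`.
#' @export
fit_subject <- function(series, X,
                        contrast = c(tenderness = 1, pride = -1)) {
  M <- X$X
  if (nrow(M) != ncol(series$data))
    stop("design matrix rows must match the run's volume count")
  qrX <- qr(M)
  if (qrX$rank < ncol(M)) stop("design error: singular design matrix")
  B <- qr.coef(qrX, t(series$data))
  cvec <- numeric(ncol(M))
  names(cvec) <- colnames(M)
  cvec[names(contrast)] <- contrast
  structure(list(contrast = drop(crossprod(B, cvec)), betas = B,
                 grid = series$grid, run_id = series$run_id),
            class = "contrast_map")
}

# correlation-based slope t for covariate regression (equals the OLS slope
# t with intercept); Y: subjects x voxels, z: covariate
.cov_tmap <- function(Y, z) {
  n <- length(z)
  df <- n - 2L
  zc <- z - mean(z)
  sz <- sqrt(sum(zc^2))
  Yc <- sweep(Y, 2L, colMeans(Y))
  sy <- sqrt(colSums(Yc^2))
  r <- as.vector(crossprod(zc, Yc)) / (sz * sy)
  r[!is.finite(r)] <- 0
  r <- pmin(1, pmax(-1, r))
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  t[abs(r) >= 1 - 1e-12] <- sign(r[abs(r) >= 1 - 1e-12]) * Inf
  list(t = t, slope = as.vector(crossprod(zc, Yc)) / sz^2)
}

#' Second-level covariate regression
#'
#' Per-voxel simple linear regression (with intercept) of subject contrast
#' values on a subject covariate (e.g. the last-minus-first change in
#' percent tenderness classification); returns the covariate-slope t map
#' with `df = n - 2`.  Voxels with an exactly linear relation get infinite
#' t and are flagged.
#'
#' @param contrasts subjects x voxels matrix (or list of `contrast_map`s).
#' @param covariate numeric vector, one value per subject.
#' @return An object of class `nf_second_level`: list with `t`, `slope`,
#'   `df`, `n`, `flagged` (voxels with infinite t).
#' @export
second_level <- function(contrasts, covariate) {
  if (is.list(contrasts) && !is.matrix(contrasts))
    contrasts <- do.call(rbind, lapply(contrasts, `[[`, "contrast"))
  stopifnot(is.matrix(contrasts))
  n <- nrow(contrasts)
  if (n < 3L) stop("need at least 3 subjects for the covariate regression")
  if (length(covariate) != n)
    stop("one covariate value per subject required")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  res <- .cov_tmap(contrasts, covariate)
  structure(list(t = res$t, slope = res$slope, df = n - 2L, n = n,
                 flagged = which(!is.finite(res$t))),
            class = "nf_second_level")
}

# connected component (6-connectivity) containing `seed` within `keep`
.cluster_size <- function(keep, dims, seed) {
  if (!keep[seed]) return(0L)
  idx <- arrayInd(seed, dims)
  visited <- logical(length(keep))
  stack <- seed
  visited[seed] <- TRUE
  count <- 0L
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    count <- count + 1L
    ci <- arrayInd(cur, dims)
    for (m in seq_len(6L)) {
      p <- ci + nbr[m, ]
      if (any(p < 1L) || any(p > dims)) next
      lin <- p[1] + (p[2] - 1L) * dims[1] + (p[3] - 1L) * dims[1] * dims[2]
      if (!visited[lin] && keep[lin]) {
        visited[lin] <- TRUE
        stack <- c(stack, lin)
      }
    }
  }
  count
}

#' Small-volume correction by max-statistic permutation
#'
#' Family-wise-error-corrected inference restricted to an a-priori ROI:
#' the subject covariate is permuted `n_perm` times (seeded), the ROI
#' maximum |t| recomputed each time, and the corrected p of the observed
#' ROI peak is its rank in that null distribution,
#' `(1 + #{max_perm >= peak}) / (n_perm + 1)`.  Also reports the size of
#' the suprathreshold cluster containing the peak at an uncorrected
#' forming threshold (default p < .005, one-sided on |t|).
#'
#' @param slmap an [second_level()] result (observed t map).
#' @param roi logical array/vector over the grid (nonempty).
#' @param contrasts subjects x voxels matrix used for `slmap`.
#' @param covariate the observed covariate vector.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param forming_p uncorrected cluster-forming threshold.
#' @param grid the [acquisition_grid()] (for cluster connectivity).
#' @param roi_name label carried into the report.
#' @return An object of class `nf_svc`: list with `roi_name`, `peak_t`,
#'   `peak_voxel` (0-based grid indices), `cluster_k`, `fwe_p`, `df`,
#'   `n_perm`, `degenerate`.
#' @export
svc_correct <- function(slmap, roi, contrasts, covariate, n_perm = 999L,
                        seed = 1L, forming_p = 0.005, grid = NULL,
                        roi_name = "ROI") {
  if (is.list(contrasts) && !is.matrix(contrasts))
    contrasts <- do.call(rbind, lapply(contrasts, `[[`, "contrast"))
  m <- as.vector(roi)
  if (!any(m)) stop("ROI is empty")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  tobs <- slmap$t[m]
  if (all(tobs == 0)) {
    return(structure(list(roi_name = roi_name, peak_t = 0,
                          peak_voxel = NULL, cluster_k = 0L, fwe_p = 1,
                          df = slmap$df, n_perm = n_perm,
                          degenerate = TRUE), class = "nf_svc"))
  }
  peak <- max(abs(tobs))
  peak_lin <- which(m)[which.max(abs(tobs))]
  Yroi <- contrasts[, m, drop = FALSE]
  n <- length(covariate)
  null_max <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      zp <- sample(covariate)
      max(abs(.cov_tmap(Yroi, zp)$t))
    }, numeric(1))
  })
  fwe_p <- (1 + sum(null_max >= peak - 1e-12)) / (n_perm + 1)
  cluster_k <- NA_integer_
  peak_voxel <- NULL
  if (!is.null(grid)) {
    dims <- grid$dims
    tcrit <- stats::qt(1 - forming_p, slmap$df)
    keep <- logical(grid$n_voxels)
    keep[m] <- abs(tobs) >= tcrit
    cluster_k <- .cluster_size(keep, dims, peak_lin)
    peak_voxel <- as.integer(arrayInd(peak_lin, dims)) - 1L
  }
  structure(list(roi_name = roi_name, peak_t = peak,
                 peak_voxel = peak_voxel, cluster_k = cluster_k,
                 fwe_p = fwe_p, df = slmap$df, n_perm = n_perm,
                 degenerate = FALSE),
            class = "nf_svc")
}

#' @export
print.nf_svc <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<nf_svc> %s: degenerate (all-zero t map in ROI)\n",
                x$roi_name))
    return(invisible(x))
  }
  cat(sprintf(
    "<nf_svc> %s: peak |t| = %.3f (df %g), k = %s, FWE p = %.4g (%d perms)\n",
    x$roi_name, x$peak_t, x$df,
    ifelse(is.na(x$cluster_k), "NA", x$cluster_k), x$fwe_p, x$n_perm))
  invisible(x)
}
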