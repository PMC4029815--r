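# Two-class linear max-margin decoder over masked voxel features.
# Training delegates to the libsvm soft-margin solver (e1071); the package
# fixes the sign convention (positive decision value = tenderness side),
# exposes raw decision values for feedback, and derives discriminant-weight
# maps from |w|.

.to_signed_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1))) stop("numeric labels must be +/-1")
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("tenderness", "pride")))
    stop("labels must be 'tenderness'/'pride' or +/-1")
  ifelse(labels == "tenderness", 1, -1)
}

#' Train the linear decoder
#'
#' Fits a two-class soft-margin linear SVM on feature vectors and returns
#' the explicit hyperplane `(w, b)`, oriented so that positive decision
#' values `x . w + b` fall on the tenderness side (class +1).  With large
#' `c_param` on separable data the solution approaches the hard-margin
#' optimum (support vectors at decision value +/-1).
#'
#' @param x numeric matrix, samples x features.
#' @param labels per-sample labels: `"tenderness"`/`"pride"` or +1/-1
#'   (+1 = tenderness).
#' @param c_param soft-margin penalty C > 0 (default 1).
#' @param tolerance solver termination tolerance.
#' @return An object of class `nf_decoder`: list with `w`, `b`, `c_param`,
#'   `n_features`, `class_sign`, `trained_on`.
#' @export
train_decoder <- function(x, labels, c_param = 1, tolerance = 0.001) {
  x <- as.matrix(x)
  y <- .to_signed_labels(labels)
  stopifnot(nrow(x) == length(y), c_param > 0)
  if (length(unique(y)) < 2L)
    stop("training error: both classes must be present")
  fit <- e1071::svm(x, factor(y, levels = c(1, -1)),
                    type = "C-classification", kernel = "linear",
                    cost = c_param, scale = FALSE, tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's internal sign depends on label ordering; orient so that
  # positive decision values correspond to the +1 (tenderness) class
  d <- drop(x %*% w) + b
  agree <- sum(sign(d) * y)
  if (agree < 0) { w <- -w; b <- -b }
  structure(list(w = as.numeric(w), b = as.numeric(b),
                 c_param = c_param, n_features = ncol(x),
                 class_sign = c(tenderness = 1, pride = -1),
                 trained_on = NA_integer_),
            class = "nf_decoder")
}

#' @export
print.nf_decoder <- function(x, ...) {
  cat(sprintf("<nf_decoder> %d features, |w| = %.4g, b = %.4g, C = %g\n",
              x$n_features, sqrt(sum(x$w^2)), x$b, x$c_param))
  invisible(x)
}

#' Decision value of feature vectors
#'
#' The signed projection `x . w + b` onto the decoder hyperplane; positive
#' values lie on the tenderness side, and the magnitude grows with the
#' distance from the class boundary (scaled by `|w|`).
#'
#' @param decoder an [train_decoder()] `nf_decoder`.
#' @param x feature vector, or matrix with one sample per row.
#' @return Numeric decision value(s).
#' @export
decision_value <- function(decoder, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != decoder$n_features)
    stop("feature error: expected ", decoder$n_features, " features, got ",
         ncol(x))
  drop(x %*% decoder$w + decoder$b)
}

#' Classify feature vectors
#'
#' `"tenderness"` iff the decision value is strictly positive; an exact
#' zero resolves to `"pride"` (conservative tie-break, so
#' tenderness-classified counts are never inflated).
#'
#' @inheritParams decision_value
#' @return Character vector of class labels.
#' @export
classify <- function(decoder, x) {
  d <- decision_value(decoder, x)
  ifelse(d > 0, "tenderness", "pride")
}

#' Per-session retraining schedule
#'
#' The decoder used during classification session k is trained on the
#' usable volumes of run k-1 only: run 1 trains the session-2 decoder,
#' run 2 the session-3 decoder, and so on.  Session 1 (the training run)
#' has no decoder.
#'
#' @param runs list of runs in order; each element a list with `features`
#'   (matrix) and `condition` (labels), e.g. from [preprocess_run()].
#' @param c_param soft-margin penalty passed to [train_decoder()].
#' @return Named list `session_2`, `session_3`, ... of `nf_decoder`s, each
#'   with `trained_on` set to the 0-based index of its training run.
#' @export
retrain_schedule <- function(runs, c_param = 1) {
  stopifnot(length(runs) >= 1L)
  out <- list()
  for (k in seq_along(runs)[-1L]) {
    dec <- train_decoder(runs[[k - 1L]]$features,
                         runs[[k - 1L]]$condition, c_param = c_param)
    dec$trained_on <- k - 2L
    out[[sprintf("session_%d", k)]] <- dec
  }
  out
}

# round half away from zero (deterministic voxel-count rule)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Discriminant-weight map
#'
#' Ranks feature voxels by the absolute hyperplane coefficient `|w|` and
#' flags the top fraction (default 2%) as the most discriminant voxels.
#' The flagged count is `round(fraction * n)` (half away from zero); ties
#' in `|w|` are broken by voxel order.
#'
#' @param decoder an `nf_decoder`.
#' @param fraction fraction of mask voxels to flag, in (0, 1].
#' @return An object of class `discriminant_map`: list with `abs_weight`,
#'   `top_mask` (logical over feature voxels), `fraction`, `n_top`.
#' @export
discriminant_map <- function(decoder, fraction = 0.02) {
  stopifnot(fraction > 0, fraction <= 1)
  aw <- abs(decoder$w)
  n <- length(aw)
  n_top <- max(0L, min(n, as.integer(.round_half_away(fraction * n))))
  top <- logical(n)
  if (n_top > 0L)
    top[order(-aw, seq_len(n))[seq_len(n_top)]] <- TRUE
  structure(list(abs_weight = aw, top_mask = top, fraction = fraction,
                 n_top = n_top),
            class = "discriminant_map")
}

#' Across-subject consistency of discriminant voxels
#'
#' For each feature voxel, the fraction of subjects whose top-discriminant
#' mask includes it.  The conventional display thresholds are >= 40% and
#' > 66% of subjects.
#'
#' @param maps list of [discriminant_map()]s on the same feature space.
#' @return An object of class `consistency_map`: list with `fraction`
#'   (numeric per voxel) and `n_subjects`.
#' @export
consistency_map <- function(maps) {
  if (!length(maps)) stop("input error: empty list of discriminant maps")
  lens <- vapply(maps, function(m) length(m$top_mask), integer(1))
  if (length(unique(lens)) != 1L)
    stop("discriminant maps must share one feature space")
  acc <- Reduce(`+`, lapply(maps, function(m) as.numeric(m$top_mask)))
  structure(list(fraction = acc / length(maps), n_subjects = length(maps)),
            class = "consistency_map")
}

#' Threshold a consistency map
#'
#' @param cm a [consistency_map()].
#' @param threshold subject fraction; default 0.40.
#' @param strict if `TRUE` use `>` (the convention for the 66% threshold),
#'   otherwise `>=` (the convention for the 40% threshold).
#' @return Logical vector over feature voxels.
#' @export
consistency_threshold <- function(cm, threshold = 0.40, strict = FALSE) {
  if (strict) cm$fraction > threshold else cm$fraction >= threshold
}

#' Persist / load a decoder
#'
#' The weight vector is written as a NIfTI map over the grid (zeros outside
#' the feature mask) and the scalar metadata (`b`, `c_param`, `trained_on`)
#' as a JSON sidecar.
#'
#' @param decoder an `nf_decoder`.
#' @param mask logical feature mask defining the voxel order.
#' @param grid the [acquisition_grid()].
#' @param prefix output path prefix; writes `<prefix>_weights.nii.gz` and
#'   `<prefix>_meta.json`.
#' @return `write_decoder` returns the two paths invisibly; `read_decoder`
#'   returns the reconstructed `nf_decoder`.
#' @export
write_decoder <- function(decoder, mask, grid, prefix) {
  m <- as.vector(mask)
  stopifnot(sum(m) == decoder$n_features)
  wmap <- numeric(grid$n_voxels)
  wmap[m] <- decoder$w
  wpath <- paste0(prefix, "_weights.nii.gz")
  mpath <- paste0(prefix, "_meta.json")
  write_map_nifti(array(wmap, grid$dims), grid, wpath)
  jsonlite::write_json(list(b = decoder$b, c_param = decoder$c_param,
                            trained_on = decoder$trained_on,
                            n_features = decoder$n_features),
                       mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(weights = wpath, meta = mpath))
}

#' @rdname write_decoder
#' @export
read_decoder <- function(prefix, mask) {
  wmap <- as.vector(RNifti::readNifti(paste0(prefix, "_weights.nii.gz")))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  m <- as.vector(mask)
  structure(list(w = wmap[m], b = meta$b, c_param = meta$c_param,
                 n_features = meta$n_features,
                 class_sign = c(tenderness = 1, pride = -1),
                 trained_on = meta$trained_on),
            class = "nf_decoder")
}
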