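# Decision-value -> ring-distortion feedback.  20 levels: level 1 (most
# distorted) signals misclassification; levels 2..20 quantise the signed
# distance toward the target condition, saturating at d_max (perfectly
# smooth ring).

#' Feedback configuration
#'
#' @param d_max decision-value distance at which the ring saturates to
#'   perfectly smooth (level 20).  Default 1, the canonical margin of the
#'   decoder's support vectors, so the scale tracks the classifier itself.
#' @param seed integer seed for non-contingent (random) streams.
#' @return An object of class `feedback_config` (`n_levels` is fixed at 20).
#' @export
feedback_config <- function(d_max = 1, seed = 1L) {
  stopifnot(d_max > 0)
  structure(list(n_levels = 20L, d_max = d_max, seed = as.integer(seed)),
            class = "feedback_config")
}

#' Map decision values to ring levels
#'
#' The signed distance toward the target is `s = d` when the target
#' condition is tenderness and `s = -d` when it is pride.  Misclassified
#' volumes (`s <= 0`) always show the most distorted ring (level 1);
#' correctly classified volumes map to levels
#' `1 + min(19, ceiling(min(s, d_max) / d_max * 19))`, a monotone
#' non-decreasing step function of `s` reaching the perfectly smooth ring
#' (level 20) at `s >= d_max`.
#'
#' @param d numeric decision value(s) `x . w + b`.
#' @param target_condition `"tenderness"` or `"pride"`, recycled along `d`.
#' @param cfg a [feedback_config()].
#' @param volume_index optional 0-based volume indices for the log.
#' @return Data frame of feedback frames: `volume_index`, `decision_value`,
#'   `target_condition`, `correct`, `level`, `contingent`.
#' @export
map_level <- function(d, target_condition, cfg = feedback_config(),
                      volume_index = NA_integer_) {
  stopifnot(all(is.finite(d)),
            all(target_condition %in% c("tenderness", "pride")))
  target_condition <- rep_len(target_condition, length(d))
  s <- ifelse(target_condition == "tenderness", d, -d)
  correct <- s > 0
  lvl <- ifelse(correct,
                1L + pmin(19L, as.integer(ceiling(
                  pmin(s, cfg$d_max) / cfg$d_max * 19))),
                1L)
  data.frame(volume_index = rep_len(volume_index, length(d)),
             decision_value = d,
             target_condition = target_condition,
             correct = correct,
             level = as.integer(lvl),
             contingent = TRUE)
}

#' Non-contingent random feedback stream
#'
#' The control group's stimulus: i.i.d. uniform ring levels on 1..20,
#' reproducible from the configuration seed, unrelated to any decision
#' value.
#'
#' @param n number of frames (>= 0).
#' @param cfg a [feedback_config()]; `cfg$seed` fixes the stream.
#' @return Data frame of feedback frames with `contingent = FALSE` and
#'   `NA` decision values.
#' @export
random_stream <- function(n, cfg = feedback_config()) {
  stopifnot(n >= 0)
  lvl <- if (n > 0)
    withr::with_seed(cfg$seed, sample.int(20L, n, replace = TRUE))
  else integer(0)
  data.frame(volume_index = rep(NA_integer_, n),
             decision_value = rep(NA_real_, n),
             target_condition = rep(NA_character_, n),
             correct = rep(NA, n),
             level = lvl,
             contingent = rep(FALSE, n))
}

#' Ring stimulus coordinates
#'
#' Coordinates-only stub for the visual feedback: a unit circle with a
#' seeded smooth radial perturbation whose amplitude scales with
#' `(20 - level) / 19`, so level 20 is a perfect circle and level 1 the
#' most distorted ring.
#'
#' @param level integer ring level in 1..20.
#' @param n_points number of distinct polyline vertices.
#' @param seed integer seed for the perturbation shape.
#' @return `(n_points + 1) x 2` matrix of x, y coordinates; the first and
#'   last rows coincide (closed curve).
#' @export
ring_coordinates <- function(level, n_points = 128L, seed = 1L) {
  stopifnot(level >= 1L, level <= 20L, n_points >= 3L)
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[seq_len(n_points)]
  amp <- 0.25 * (20L - level) / 19
  r <- rep(1, n_points)
  if (amp > 0) {
    pert <- withr::with_seed(as.integer(seed), {
      ks <- 3:8
      a <- stats::runif(length(ks), 0.3, 1)
      ph <- stats::runif(length(ks), 0, 2 * pi)
      rowSums(vapply(seq_along(ks), function(i)
        a[i] * cos(ks[i] * theta + ph[i]), numeric(n_points)))
    })
    pert <- pert / max(abs(pert))
    r <- 1 + amp * pert
  }
  xy <- cbind(x = r * cos(theta), y = r * sin(theta))
  rbind(xy, xy[1L, , drop = FALSE])
}
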