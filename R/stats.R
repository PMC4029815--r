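# Brain-decoding outcome statistics: per-session tenderness-classification
# percentages, within/between-group t tests (data or printed summary
# statistics), exact binomial above-chance tests, and the cohort report.

.nf_test <- function(statistic, df, p_value, kind) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 kind = kind), class = "nf_test")
}

#' @export
print.nf_test <- function(x, ...) {
  cat(sprintf("<nf_test> %s: statistic = %.4g, df = %g, p = %.4g\n",
              x$kind, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Percent of usable tenderness volumes classified as tenderness
#'
#' @param predictions either a character vector of predicted classes
#'   aligned with `labels` rows (`NA` allowed on non-usable volumes), or a
#'   data frame with columns `volume_index`, `predicted`.
#' @param labels per-volume label table from [label_volumes()].
#' @return Percentage in [0, 100].
#' @export
pct_tenderness <- function(predictions, labels) {
  sel <- labels$usable & labels$condition == "tenderness"
  if (!any(sel))
    stop("undefined metric: no usable tenderness volumes in this design")
  if (is.data.frame(predictions)) {
    m <- match(labels$volume_index[sel], predictions$volume_index)
    if (anyNA(m))
      stop("predictions must cover all usable tenderness volumes")
    pred <- predictions$predicted[m]
  } else {
    if (length(predictions) != nrow(labels))
      stop("prediction vector must align with the label table")
    pred <- predictions[sel]
  }
  if (anyNA(pred))
    stop("predictions must cover all usable tenderness volumes")
  100 * mean(pred == "tenderness")
}

#' One-sample Student t test
#'
#' @param values numeric sample (n >= 2, nonzero variance).
#' @param mu0 null mean.
#' @return An `nf_test` with `t = (mean - mu0) / (sd / sqrt(n))`,
#'   `df = n - 1`, two-sided p.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2L) stop("need at least 2 observations")
  if (stats::sd(values) == 0)
    stop("degenerate test: sample variance is zero")
  r <- stats::t.test(values, mu = mu0)
  .nf_test(unname(r$statistic), unname(r$parameter), r$p.value,
           "one_sample_t")
}

#' Pooled-variance two-sample Student t test
#'
#' @param a,b numeric samples (each n >= 2).
#' @return An `nf_test` for `mean(a) - mean(b)`, `df = n_a + n_b - 2`,
#'   two-sided p.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate test: both groups have zero variance")
  r <- stats::t.test(a, b, var.equal = TRUE)
  .nf_test(unname(r$statistic), unname(r$parameter), r$p.value,
           "two_sample_t_pooled")
}

#' t tests from printed summary statistics
#'
#' Recompute a one-sample or pooled two-sample Student t from reported
#' mean / SD / n summaries (as printed in results tables), rather than raw
#' data.
#'
#' @param mean,sd,n sample summary.
#' @param mu0 null mean (one-sample version).
#' @return An `nf_test`.
#' @export
one_sample_t_summary <- function(mean, sd, n, mu0 = 0) {
  stopifnot(n >= 2, sd > 0)
  t <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  .nf_test(t, df, 2 * stats::pt(-abs(t), df), "one_sample_t")
}

#' @rdname one_sample_t_summary
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summaries; the statistic is
#'   for `mean1 - mean2`.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  .nf_test(t, df, 2 * stats::pt(-abs(t), df), "two_sample_t_pooled")
}

#' Exact binomial test
#'
#' Exact tail probability for a classifier-accuracy count under
#' Binomial(n, p0); the default upper tail gives
#' `P(X >= successes | n, p0)`.
#'
#' @param successes,n observed count and number of trials.
#' @param p0 null success probability.
#' @param tail `"greater"` (default), `"less"` or `"two.sided"`.
#' @return An `nf_test` (statistic = `successes`, df = `n`).
#' @export
binomial_exact <- function(successes, n, p0 = 0.5,
                           tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(successes >= 0, successes <= n, p0 > 0, p0 < 1)
  p <- stats::binom.test(successes, n, p = p0, alternative = tail)$p.value
  .nf_test(successes, n, p, "binomial_exact")
}

.group_t_or_note <- function(values, mu0) {
  if (length(values) < 2L)
    return(list(test = NULL, note = "insufficient n (< 2)"))
  if (stats::sd(values) == 0)
    return(list(test = NULL, note = "zero variance"))
  list(test = one_sample_t(values, mu0), note = NA_character_)
}

#' Cohort-level decoding report
#'
#' Reproduces the standard results panel for a two-group neurofeedback
#' decoding experiment: per-group mean +/- SD of the last-minus-first
#' session change in percent tenderness classification, one-sample t of
#' the change within each group, pooled two-sample t between groups,
#' per-group last-session accuracy against chance (50%), the between-group
#' test on last-session accuracy, and per-subject exact binomial
#' above-chance flags (significant at p < .05, which with 80 usable
#' volumes corresponds to accuracy exceeding the 60% criterion).
#'
#' @param outcomes data frame with one row per subject and columns
#'   `subject_id`, `group` (`"NFB"`/`"CTR"`), per-session percentages
#'   `pct_session_*`, `delta_last_first`, `n_usable_tenderness` (defaults
#'   to 80 when absent).
#' @param alpha per-subject binomial significance level.
#' @return An object of class `nf_cohort_report`.
#' @export
cohort_report <- function(outcomes, alpha = 0.05) {
  stopifnot(all(c("subject_id", "group", "delta_last_first") %in%
                  names(outcomes)))
  pct_cols <- grep("^pct_session_", names(outcomes), value = TRUE)
  if (!length(pct_cols)) stop("no per-session percentage columns found")
  last_col <- pct_cols[length(pct_cols)]
  n_use <- if ("n_usable_tenderness" %in% names(outcomes))
    outcomes$n_usable_tenderness else rep(80L, nrow(outcomes))
  groups <- unique(outcomes$group)
  per_group <- lapply(groups, function(g) {
    d <- outcomes$delta_last_first[outcomes$group == g]
    l <- outcomes[[last_col]][outcomes$group == g]
    delta_t <- .group_t_or_note(d, 0)
    last_t <- .group_t_or_note(l, 50)
    list(group = g, n = length(d),
         mean_delta = mean(d), sd_delta = stats::sd(d),
         delta_test = delta_t$test, delta_note = delta_t$note,
         mean_last = mean(l), sd_last = stats::sd(l),
         last_test = last_t$test, last_note = last_t$note)
  })
  names(per_group) <- groups
  between <- between_last <- NULL
  between_note <- NA_character_
  if (all(c("NFB", "CTR") %in% groups)) {
    a <- outcomes$delta_last_first[outcomes$group == "CTR"]
    b <- outcomes$delta_last_first[outcomes$group == "NFB"]
    al <- outcomes[[last_col]][outcomes$group == "CTR"]
    bl <- outcomes[[last_col]][outcomes$group == "NFB"]
    if (length(a) >= 2L && length(b) >= 2L) {
      between <- tryCatch(two_sample_t(a, b), error = function(e) NULL)
      between_last <- tryCatch(two_sample_t(bl, al),
                               error = function(e) NULL)
      if (is.null(between))
        between_note <- "between-group test degenerate (zero variance)"
    } else between_note <- "insufficient n for between-group test"
  } else {
    between_note <- "between-group tests unavailable (one group only)"
  }
  subj <- data.frame(subject_id = outcomes$subject_id,
                     group = outcomes$group,
                     pct_last = outcomes[[last_col]],
                     n = n_use, stringsAsFactors = FALSE)
  subj$successes <- as.integer(round(subj$pct_last / 100 * subj$n))
  subj$binom_p <- vapply(seq_len(nrow(subj)), function(i)
    binomial_exact(subj$successes[i], subj$n[i], 0.5)$p_value, numeric(1))
  subj$reliable <- subj$binom_p < alpha
  structure(list(per_group = per_group, between_delta = between,
                 between_last = between_last, between_note = between_note,
                 subjects = subj, alpha = alpha),
            class = "nf_cohort_report")
}

#' @export
print.nf_cohort_report <- function(x, ...) {
  cat("Neurofeedback decoding report\n")
  for (g in x$per_group) {
    cat(sprintf("  %s (n=%d): delta last-first = %.1f%% +/- %.1f%%",
                g$group, g$n, g$mean_delta, g$sd_delta))
    if (!is.null(g$delta_test))
      cat(sprintf(" (t[%g] = %.2f, p = %.3g)", g$delta_test$df,
                  g$delta_test$statistic, g$delta_test$p_value))
    else cat(sprintf(" [%s]", g$delta_note))
    cat(sprintf("\n      last session = %.1f%% +/- %.1f%% vs 50%%",
                g$mean_last, g$sd_last))
    if (!is.null(g$last_test))
      cat(sprintf(" (t[%g] = %.2f, p = %.3g)", g$last_test$df,
                  g$last_test$statistic, g$last_test$p_value))
    cat("\n")
  }
  if (!is.null(x$between_delta))
    cat(sprintf("  CTR - NFB delta: t[%g] = %.2f, p = %.3g\n",
                x$between_delta$df, x$between_delta$statistic,
                x$between_delta$p_value))
  else cat(" ", x$between_note, "\n")
  cat(sprintf("  reliable subjects (binomial p < %.2g): %d of %d\n",
              x$alpha, sum(x$subjects$reliable), nrow(x$subjects)))
  invisible(x)
}

#' Write the cohort report to disk
#'
#' @param report an [cohort_report()] object.
#' @param prefix path prefix; writes `<prefix>_groups.tsv`,
#'   `<prefix>_subjects.tsv` and `<prefix>_summary.txt`.
#' @return The paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  gr <- do.call(rbind, lapply(report$per_group, function(g)
    data.frame(group = g$group, n = g$n, mean_delta = g$mean_delta,
               sd_delta = g$sd_delta,
               t_delta = if (is.null(g$delta_test)) NA
                         else g$delta_test$statistic,
               p_delta = if (is.null(g$delta_test)) NA
                         else g$delta_test$p_value,
               mean_last = g$mean_last, sd_last = g$sd_last,
               t_last_vs_50 = if (is.null(g$last_test)) NA
                              else g$last_test$statistic,
               p_last_vs_50 = if (is.null(g$last_test)) NA
                              else g$last_test$p_value)))
  gpath <- paste0(prefix, "_groups.tsv")
  spath <- paste0(prefix, "_subjects.tsv")
  tpath <- paste0(prefix, "_summary.txt")
  utils::write.table(gr, gpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$subjects, spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sink(tpath); print(report); sink()
  invisible(c(groups = gpath, subjects = spath, summary = tpath))
}
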