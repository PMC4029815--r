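test_that("percent tenderness counts usable tenderness volumes only", {
  d <- make_default_design("tenderness")
  lab <- label_volumes(d)
  all_t <- rep(NA_character_, nrow(lab))
  all_t[lab$usable] <- "tenderness"
  expect_equal(pct_tenderness(all_t, lab), 100)
  # 48 of 80 -> 60.0%
  sel <- which(lab$usable & lab$condition == "tenderness")
  pred <- all_t
  pred[sel[49:80]] <- "pride"
  expect_equal(pct_tenderness(pred, lab), 60)
  # order of a prediction data frame is irrelevant
  df <- data.frame(volume_index = lab$volume_index[lab$usable],
                   predicted = pred[lab$usable])
  df_shuf <- df[rev(seq_len(nrow(df))), ]
  expect_equal(pct_tenderness(df_shuf, lab), 60)
  # fair-coin predictions average 50% over seeds
  mc <- vapply(1:200, function(s) withr::with_seed(s, {
    p <- all_t
    p[sel] <- sample(c("tenderness", "pride"), 80, replace = TRUE)
    pct_tenderness(p, lab)
  }), numeric(1))
  expect_equal(mean(mc), 50, tolerance = 2)
  neutral_only <- label_volumes(block_design(
    data.frame(condition = "neutral", n_volumes = 15L)))
  expect_error(pct_tenderness(character(15), neutral_only),
               "undefined metric")
})

test_that("t statistics from summaries reproduce the printed values", {
  # within-NFB change: mean 26.0, SD 32.1, n 12 vs 0
  expect_equal(round(one_sample_t_summary(26.0, 32.1, 12)$statistic, 2),
               2.81)
  # within-CTR change: mean -12.3, SD 21.7, n 12 vs 0
  expect_equal(round(one_sample_t_summary(-12.3, 21.7, 12)$statistic, 2),
               -1.96)
  # last-session CTR accuracy vs chance: 54.6 +/- 26.1, n 12 vs 50
  expect_equal(round(one_sample_t_summary(54.6, 26.1, 12, 50)$statistic, 2),
               0.61)
  # CTR - NFB pooled two-sample comparison of changes
  tt <- two_sample_t_summary(-12.3, 21.7, 12, 26.0, 32.1, 12)
  expect_equal(round(tt$statistic, 1), -3.4)
  expect_equal(tt$df, 22)
})

test_that("data-based t tests agree with summaries and handle degeneracy", {
  withr::with_seed(8, x <- rnorm(12, 5, 3))
  a <- one_sample_t(x, 2)
  b <- one_sample_t_summary(mean(x), sd(x), 12, 2)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$df, 11)
  # numerical-integration oracle for the two-sided p-value
  p_int <- 2 * stats::integrate(function(u) stats::dt(u, a$df),
                                abs(a$statistic), Inf,
                                rel.tol = 1e-12)$value
  expect_equal(a$p_value, p_int, tolerance = 1e-8)
  withr::with_seed(9, y <- rnorm(10, 3, 3))
  t2 <- two_sample_t(x, y)
  t2s <- two_sample_t_summary(mean(x), sd(x), 12, mean(y), sd(y), 10)
  expect_equal(t2$statistic, t2s$statistic, tolerance = 1e-12)
  expect_equal(t2$df, 20)
  # symmetry and degenerate inputs
  expect_equal(two_sample_t(y, x)$statistic, -t2$statistic)
  expect_equal(two_sample_t(x, x)$statistic, 0)
  expect_error(one_sample_t(rep(3, 5), 3), "zero")
  expect_error(one_sample_t(3, 0), "at least 2")
  expect_error(two_sample_t(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("exact binomial tail probabilities are exact", {
  expect_equal(binomial_exact(80, 80, 0.5)$p_value, 2^-80)
  expect_equal(binomial_exact(0, 80, 0.5)$p_value, 1)
  # enumeration oracle for small n
  for (n in c(5, 9, 12)) for (k in c(0, 2, n)) {
    enum <- sum(choose(n, k:n) * 0.6^(k:n) * 0.4^(n - (k:n)))
    expect_equal(binomial_exact(k, n, 0.6)$p_value, enum,
                 tolerance = 1e-12)
  }
  # the 60% criterion at 80 usable volumes is significant at .05
  p48 <- binomial_exact(48, 80, 0.5)$p_value
  expect_lt(p48, 0.05)
  expect_gt(binomial_exact(47, 80, 0.5)$p_value, 0.05)
})

test_that("cohort report reproduces the group panel and binomial flags", {
  outcomes <- data.frame(
    subject_id = sprintf("s%02d", 1:8),
    group = rep(c("NFB", "CTR"), each = 4),
    pct_session_1 = c(50, 55, 45, 60, 50, 55, 45, 60),
    pct_session_3 = c(80, 75, 60, 90, 45, 55, 50, 65),
    n_usable_tenderness = rep(80L, 8))
  outcomes$delta_last_first <- outcomes$pct_session_3 -
    outcomes$pct_session_1
  rep_ <- cohort_report(outcomes)
  nfb <- rep_$per_group$NFB
  expect_equal(nfb$mean_delta,
               mean(outcomes$delta_last_first[1:4]))
  expect_equal(nfb$delta_test$statistic,
               one_sample_t(outcomes$delta_last_first[1:4], 0)$statistic)
  expect_equal(rep_$between_delta$statistic,
               two_sample_t(outcomes$delta_last_first[5:8],
                            outcomes$delta_last_first[1:4])$statistic)
  expect_equal(rep_$per_group$CTR$last_test$statistic,
               one_sample_t(outcomes$pct_session_3[5:8], 50)$statistic)
  # binomial flags: 80% of 80 = 64 successes is reliable, 50% is not
  expect_true(rep_$subjects$reliable[1])
  expect_false(rep_$subjects$reliable[7])
  expect_equal(rep_$subjects$successes[1], 64L)
  # all-zero deltas: within-group tests flagged, binomial flags intact
  oz <- outcomes
  oz$delta_last_first <- 0
  rz <- cohort_report(oz)
  expect_null(rz$per_group$NFB$delta_test)
  expect_equal(rz$per_group$NFB$delta_note, "zero variance")
  expect_equal(rz$subjects$reliable, rep_$subjects$reliable)
  # single-subject groups degrade gracefully
  o1 <- outcomes[c(1, 5), ]
  r1 <- cohort_report(o1)
  expect_null(r1$per_group$NFB$delta_test)
  expect_match(r1$per_group$NFB$delta_note, "insufficient")
  expect_match(r1$between_note, "insufficient")
  # report files round-trip
  prefix <- file.path(withr::local_tempdir(), "rep")
  write_report(rep_, prefix)
  gr <- utils::read.delim(paste0(prefix, "_groups.tsv"))
  expect_equal(nrow(gr), 2L)
  expect_equal(gr$mean_delta[gr$group == "NFB"], nfb$mean_delta)
})
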