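test_that("atlas construction is deterministic with disjoint patterns", {
  a1 <- tiny_atlas(seed = 5)
  a2 <- tiny_atlas(seed = 5)
  expect_identical(a1$tenderness_pattern, a2$tenderness_pattern)
  expect_identical(a1$feature_mask, a2$feature_mask)
  # zero voxelwise overlap between the two patterns
  expect_equal(sum(a1$tenderness_pattern > 0 & a1$pride_pattern > 0), 0L)
  # strict containment: pattern < feature mask < whole grid
  n_pat <- sum(a1$tenderness_pattern > 0)
  n_mask <- sum(a1$feature_mask)
  expect_true(n_pat > 0 && n_pat < n_mask)
  expect_true(n_mask < prod(tiny_grid()$dims))
  # patterns vanish outside the feature mask; SVC ROI inside it
  expect_true(all(a1$tenderness_pattern[!a1$feature_mask] == 0))
  expect_true(all(a1$pride_pattern[!a1$feature_mask] == 0))
  expect_true(all(a1$feature_mask[a1$svc_roi]))
  expect_true(any(a1$svc_roi & a1$tenderness_pattern > 0))
})

test_that("hrf kernel has canonical double-gamma shape", {
  h <- hrf_kernel(2)
  expect_equal(h[1], 0)
  # dense-grid argmax of the underlying double-gamma lies in 5-6 s
  tfine <- seq(0, 32, by = 0.01)
  dense <- stats::dgamma(tfine, 6, 1) - stats::dgamma(tfine, 16, 1) / 6
  expect_gte(tfine[which.max(dense)], 5)
  expect_lte(tfine[which.max(dense)], 6)
  expect_lt(min(h), 0)            # undershoot
  expect_lte(max(h), 1)           # peak-normalised
  expect_equal(max(hrf_kernel(0.01)), 1, tolerance = 1e-6)
})

test_that("noise-free, amplitude-free runs are pure baseline plus drift", {
  atlas <- tiny_atlas()
  d <- short_design()
  st <- quiet_state(amp_tenderness = 0, amp_pride = 0, drift_slope = 0.5)
  run <- simulate_run(st, atlas, d)
  expected <- matrix(100 + 0.5 * (seq_len(d$n_volumes) - 1),
                     nrow = tiny_grid()$n_voxels, ncol = d$n_volumes,
                     byrow = TRUE)
  expect_equal(run$data, expected)
})

test_that("a decoder trained on a noise-free run classifies it perfectly", {
  atlas <- tiny_atlas()
  d <- make_default_design("tenderness")
  st <- quiet_state(amp_tenderness = 1, amp_pride = 0.7)
  run <- simulate_run(st, atlas, d)
  feat <- preprocess_run(run, atlas$feature_mask, preproc_config())
  dec <- train_decoder(feat$features, feat$condition, c_param = 100)
  expect_equal(mean(classify(dec, feat$features) == feat$condition), 1)
})

test_that("simulated noise matches the requested AR(1) structure", {
  atlas <- tiny_atlas()
  d <- make_default_design("tenderness")
  st0 <- quiet_state(noise_sd = 2, ar_coeff = 0, rng_seed = 9)
  run0 <- simulate_run(st0, atlas, d)
  resid <- run0$data - 100
  lag1 <- mean(vapply(sample.int(nrow(resid), 50),
                      function(v) stats::cor(resid[v, -1],
                                             resid[v, -ncol(resid)]),
                      numeric(1)))
  expect_lt(abs(lag1), 0.08)
  st1 <- quiet_state(noise_sd = 2, ar_coeff = 0.5, rng_seed = 9)
  run1 <- simulate_run(st1, atlas, d)
  resid1 <- run1$data - 100
  lag1b <- mean(vapply(sample.int(nrow(resid1), 50),
                       function(v) stats::cor(resid1[v, -1],
                                              resid1[v, -ncol(resid1)]),
                       numeric(1)))
  expect_equal(lag1b, 0.5, tolerance = 0.1)
  expect_equal(stats::sd(as.vector(resid1)), 2, tolerance = 0.05)
  # determinism
  expect_identical(run1$data, simulate_run(st1, atlas, d)$data)
})

test_that("feedback update rule follows the normalised mean-level rule", {
  st <- quiet_state(learning_rate = 0, amp_tenderness = 1)
  expect_equal(update_state(st, 20, TRUE)$amp_tenderness, 1)
  st$learning_rate <- 0.5
  # eta = 0.5 at the maximum level adds exactly eta
  expect_equal(update_state(st, 20, TRUE)$amp_tenderness, 1.5)
  # non-contingent feedback never changes the state
  expect_identical(update_state(st, 20, FALSE), st)
  # below-midpoint feedback decreases, floored at zero
  st$amp_tenderness <- 0.01
  st$learning_rate <- 2
  expect_equal(update_state(st, 1, TRUE)$amp_tenderness, 0)
  expect_error(update_state(st, 25, TRUE), "1, 20")
})

test_that("GLM betas recover planted amplitudes on noise-free runs", {
  atlas <- tiny_atlas()
  d <- make_default_design("pride")
  st <- quiet_state(amp_tenderness = 1.5, amp_pride = 0.5,
                    drift_slope = 0.3)
  run <- simulate_run(st, atlas, d)
  X <- build_design(d, hp_cutoff_s = 448)
  cm <- fit_subject(run, X)
  pat_diff <- 1.5 * as.vector(atlas$tenderness_pattern) -
    0.5 * as.vector(atlas$pride_pattern)
  active <- which(abs(pat_diff) > 0.1)
  expect_equal(cm$contrast[active], pat_diff[active], tolerance = 0.05)
})

test_that("small closed-loop cohorts are reproducible and learning-dependent", {
  base <- subject_state(noise_sd = 3)
  g <- acquisition_grid(c(12L, 12L, 6L))
  coh1 <- simulate_cohort(n_per_group = 1, n_runs = 3, seed = 11, grid = g,
                          base_state = base)
  coh2 <- simulate_cohort(n_per_group = 1, n_runs = 3, seed = 11, grid = g,
                          base_state = base)
  expect_identical(coh1$outcomes, coh2$outcomes)
  expect_identical(coh1$feedback, coh2$feedback)
  # control subjects never learn: final amplitude equals the initial one
  for (i in which(coh1$outcomes$group == "CTR"))
    expect_equal(coh1$states[[i]]$amp_tenderness,
                 coh1$states[[i]]$amp_tenderness_init)
  # feedback-contingent subjects do update
  nfb <- which(coh1$outcomes$group == "NFB")
  expect_true(any(vapply(coh1$states[nfb], function(s)
    s$amp_tenderness != s$amp_tenderness_init, logical(1))))
  expect_error(simulate_cohort(n_per_group = 1, n_runs = 1, seed = 1,
                               grid = g), "n_runs")
})
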