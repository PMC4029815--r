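test_that("two-point instances match the analytic hard-margin solution", {
  # 1D points -1 / +1: boundary at 0, supports at +/-1
  x <- matrix(c(-1, 1), ncol = 1)
  dec <- train_decoder(x, c(-1, 1), c_param = 1e5, tolerance = 1e-8)
  expect_equal(dec$w, 1, tolerance = 1e-4)
  expect_equal(dec$b, 0, tolerance = 1e-4)
  expect_equal(decision_value(dec, 1), 1, tolerance = 1e-4)
  # 2D points (0,0)- and (2,0)+: w = (1, 0), boundary x = 1
  x2 <- rbind(c(0, 0), c(2, 0))
  dec2 <- train_decoder(x2, c(-1, 1), c_param = 1e5, tolerance = 1e-8)
  expect_equal(dec2$w, c(1, 0), tolerance = 1e-4)
  expect_equal(dec2$b, -1, tolerance = 1e-4)
  # label swap negates the hyperplane
  dec3 <- train_decoder(x2, c(1, -1), c_param = 1e5, tolerance = 1e-8)
  expect_equal(dec3$w, -dec2$w, tolerance = 1e-4)
  expect_equal(dec3$b, -dec2$b, tolerance = 1e-4)
  expect_error(train_decoder(x2, c(1, 1)), "both classes")
})

test_that("hard-margin solutions match the brute-force oracle on random 2D instances", {
  for (seed in 1:6) {
    inst <- make_separable_2d(n_per_class = sample(3:10, 1), gap = 0.8,
                              spread = 0.8, seed = seed)
    oracle <- hard_margin_oracle(inst$X, inst$y)
    expect_false(is.null(oracle))
    dec <- train_decoder(inst$X, inst$y, c_param = 1e6, tolerance = 1e-9)
    scale <- max(abs(c(oracle$w, oracle$b)))
    expect_equal(dec$w / scale, oracle$w / scale, tolerance = 1e-4)
    expect_equal(dec$b / scale, oracle$b / scale, tolerance = 1e-4)
    # margin property: min of y * f(x) over training points equals 1
    marg <- min(inst$y * (inst$X %*% dec$w + dec$b))
    expect_equal(marg, 1, tolerance = 1e-4)
  }
})

test_that("input scaling moves the hyperplane covariantly", {
  inst <- make_separable_2d(5, seed = 3)
  dec <- train_decoder(inst$X, inst$y, c_param = 1e6, tolerance = 1e-9)
  s <- 2.5
  dec_s <- train_decoder(s * inst$X, inst$y, c_param = 1e6,
                         tolerance = 1e-9)
  # w scales by 1/s, b is unchanged: the boundary is invariant in input space
  expect_equal(dec_s$w, dec$w / s, tolerance = 1e-3)
  expect_equal(dec_s$b, dec$b, tolerance = 1e-3)
})

test_that("decision values, classification and the tie-break are consistent", {
  dec <- structure(list(w = c(1, -2), b = 0.5, n_features = 2L,
                        c_param = 1, class_sign = c(tenderness = 1,
                                                    pride = -1),
                        trained_on = NA_integer_),
                   class = "nf_decoder")
  expect_equal(decision_value(dec, c(0, 0)), 0.5)
  x_on_plane <- c(1.5, 1)              # 1.5 - 2 + 0.5 = 0
  expect_equal(decision_value(dec, x_on_plane), 0)
  expect_equal(classify(dec, x_on_plane), "pride")   # exact zero -> pride
  X <- rbind(c(3, 0), c(0, 3), c(0, 0))
  d <- decision_value(dec, X)
  expect_equal(classify(dec, X),
               ifelse(d > 0, "tenderness", "pride"))
  expect_error(decision_value(dec, c(1, 2, 3)), "feature error")
})

test_that("retraining schedule pairs session k with run k-1", {
  withr::with_seed(1, {
    runs <- lapply(1:4, function(k) {
      n <- 20
      x <- matrix(rnorm(n * 3), n, 3)
      y <- rep(c("tenderness", "pride"), each = n / 2)
      x[y == "tenderness", 1] <- x[y == "tenderness", 1] + 3
      list(features = x, condition = y)
    })
  })
  sched <- retrain_schedule(runs)
  expect_named(sched, c("session_2", "session_3", "session_4"))
  expect_equal(vapply(sched, `[[`, integer(1), "trained_on"),
               c(session_2 = 0L, session_3 = 1L, session_4 = 2L))
  # identical runs give identical decoders
  sched2 <- retrain_schedule(list(runs[[1]], runs[[1]], runs[[1]]))
  expect_equal(sched2$session_2$w, sched2$session_3$w)
  expect_equal(sched2$session_2$b, sched2$session_3$b)
  expect_length(retrain_schedule(runs[1]), 0L)
})

test_that("discriminant maps flag the top fraction with deterministic rounding", {
  dec <- structure(list(w = c(0, 5, -3, 0.5, -0.5, 1, 0, 0, 0, 2),
                        b = 0, n_features = 10L, c_param = 1,
                        trained_on = NA_integer_),
                   class = "nf_decoder")
  dm <- discriminant_map(dec, fraction = 0.2)
  expect_equal(dm$n_top, 2L)
  expect_equal(which(dm$top_mask), c(2L, 3L))
  expect_equal(dm$abs_weight, abs(dec$w))
  expect_true(all(discriminant_map(dec, 1)$top_mask))
  # round(0.02 * 100) = 2 voxels; single dominant weight wins
  dec2 <- dec
  dec2$w <- c(9, rep(0, 99))
  dec2$n_features <- 100L
  dm2 <- discriminant_map(dec2, 0.02)
  expect_equal(dm2$n_top, 2L)
  expect_true(dm2$top_mask[1])
  # |w| ties break by voxel order
  dec3 <- dec
  dec3$w <- rep(1, 10)
  expect_equal(which(discriminant_map(dec3, 0.2)$top_mask), c(1L, 2L))
})

test_that("consistency maps count subject fractions with threshold helpers", {
  mk <- function(top) structure(list(abs_weight = as.numeric(top),
                                     top_mask = top, fraction = 0.5,
                                     n_top = sum(top)),
                                class = "discriminant_map")
  maps <- c(replicate(5, mk(c(TRUE, FALSE, TRUE)), simplify = FALSE),
            replicate(7, mk(c(FALSE, FALSE, TRUE)), simplify = FALSE))
  cm <- consistency_map(maps)
  expect_equal(cm$fraction, c(5 / 12, 0, 1))
  expect_equal(consistency_threshold(cm, 0.40), c(TRUE, FALSE, TRUE))
  expect_equal(consistency_threshold(cm, 0.66, strict = TRUE),
               c(FALSE, FALSE, TRUE))
  # identical maps or a single subject give only fractions 0 and 1
  cm1 <- consistency_map(maps[12])
  expect_true(all(cm1$fraction %in% c(0, 1)))
  expect_error(consistency_map(list()), "empty")
})

test_that("decoders round-trip through NIfTI weights plus JSON metadata", {
  g <- tiny_grid()
  atlas <- tiny_atlas()
  mask <- atlas$feature_mask
  withr::with_seed(2, {
    x <- matrix(rnorm(20 * sum(mask)), 20)
    y <- rep(c("tenderness", "pride"), 10)
    x[y == "tenderness", 1:5] <- x[y == "tenderness", 1:5] + 2
  })
  dec <- train_decoder(x, y)
  dec$trained_on <- 1L
  prefix <- file.path(withr::local_tempdir(), "dec")
  write_decoder(dec, mask, g, prefix)
  dec2 <- read_decoder(prefix, mask)
  expect_equal(dec2$w, dec$w, tolerance = 1e-6)
  expect_equal(dec2$b, dec$b, tolerance = 1e-12)
  expect_equal(dec2$trained_on, 1L)
})
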