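# Brute-force hard-margin oracle for small 2D separable instances.
#
# The optimal hard-margin hyperplane is supported by either one point per
# class (margin = half their distance, boundary through the midpoint) or
# two points of one class and one of the other (boundary parallel to the
# same-class segment).  Enumerating all such candidates and keeping the
# feasible one with the largest margin recovers the exact optimum, in the
# canonical scaling where support vectors sit at decision value +/-1.
hard_margin_oracle <- function(X, y, tol = 1e-9) {
  stopifnot(ncol(X) == 2, all(y %in% c(-1, 1)))
  Xp <- X[y == 1, , drop = FALSE]
  Xn <- X[y == -1, , drop = FALSE]
  feasible <- function(w, b) {
    all(y * (X %*% w + b) >= 1 - 1e-6)
  }
  canonical <- function(u, gamma, mid) {
    # f(x) = (x - mid) . u / gamma: +/-1 at the supports
    w <- u / gamma
    list(w = w, b = -sum(mid * u) / gamma, margin = gamma)
  }
  best <- NULL
  consider <- function(cand) {
    if (feasible(cand$w, cand$b) &&
        (is.null(best) || cand$margin > best$margin)) best <<- cand
  }
  for (i in seq_len(nrow(Xp))) for (j in seq_len(nrow(Xn))) {
    v <- Xp[i, ] - Xn[j, ]
    nv <- sqrt(sum(v^2))
    if (nv < tol) next
    consider(canonical(v / nv, nv / 2, (Xp[i, ] + Xn[j, ]) / 2))
  }
  triple <- function(a, b2, c, sgn) {
    # a, b2 in class sgn; c in class -sgn; boundary parallel to a-b2
    d <- b2 - a
    dn2 <- sum(d^2)
    if (dn2 < tol) return()
    tt <- sum((c - a) * d) / dn2
    if (tt < -1e-9 || tt > 1 + 1e-9) return()
    proj <- a + tt * d
    v <- c - proj
    nv <- sqrt(sum(v^2))
    if (nv < tol) return()
    cand <- canonical(v / nv, nv / 2, (proj + c) / 2)
    if (sgn * (sum(a * cand$w) + cand$b) < 0) {
      cand$w <- -cand$w
      cand$b <- -cand$b
    }
    consider(cand)
  }
  if (nrow(Xp) >= 2) for (i in seq_len(nrow(Xp) - 1))
    for (j in (i + 1):nrow(Xp)) for (k in seq_len(nrow(Xn)))
      triple(Xp[i, ], Xp[j, ], Xn[k, ], 1)
  if (nrow(Xn) >= 2) for (i in seq_len(nrow(Xn) - 1))
    for (j in (i + 1):nrow(Xn)) for (k in seq_len(nrow(Xp)))
      triple(Xn[i, ], Xn[j, ], Xp[k, ], -1)
  best
}

# Separable 2D two-class sample with a guaranteed margin along x.
make_separable_2d <- function(n_per_class, gap = 1, spread = 1, seed = 1) {
  withr::with_seed(seed, {
    Xp <- cbind(abs(rnorm(n_per_class, sd = spread)) + gap / 2,
                rnorm(n_per_class, sd = spread))
    Xn <- cbind(-abs(rnorm(n_per_class, sd = spread)) - gap / 2,
                rnorm(n_per_class, sd = spread))
    list(X = rbind(Xp, Xn), y = rep(c(1, -1), each = n_per_class))
  })
}
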