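# Brute-force threshold oracle: balanced training error over every midpoint
# of consecutive sorted projections, ties by widest flanking gap then
# smallest threshold.
scan_threshold_oracle <- function(p, y, orientation) {
  o <- order(p)
  ps <- p[o]; ys <- y[o]
  other <- setdiff(c("WT", "HYPO"), orientation)
  best <- NULL
  for (i in seq_len(length(ps) - 1)) {
    b <- (ps[i] + ps[i + 1]) / 2
    pred <- ifelse(p >= b, orientation, other)
    err <- mean(pred[y == orientation] != orientation) / 2 +
      mean(pred[y == other] != other) / 2
    gap <- ps[i + 1] - ps[i]
    cand <- c(err = err, gap = gap, b = b)
    if (is.null(best) || err < best["err"] - 1e-15 ||
        (abs(err - best["err"]) < 1e-15 &&
           (gap > best["gap"] + 1e-15 ||
              (abs(gap - best["gap"]) < 1e-15 && b < best["b"]))))
      best <- cand
  }
  best
}

test_that("a separable 1-D problem yields the midpoint threshold and zero error", {
  X <- matrix(c(1, 2, -2, -1), ncol = 1)
  y <- c("WT", "WT", "HYPO", "HYPO")
  cls <- fit_fisher(X, y)
  expect_gt(cls$w[1], 0)               # points toward the WT side
  expect_equal(cls$b, 0)
  expect_equal(cls$training_error, 0)
  expect_identical(cls$orientation, "WT")
  expect_identical(predict(cls, matrix(c(5, -5), ncol = 1)),
                   c("WT", "HYPO"))
})

test_that("identical class means give a degenerate majority classifier", {
  X <- rbind(matrix(c(1, 0, -1, 0), 2, byrow = TRUE),
             matrix(c(0, 1, 0, -1), 2, byrow = TRUE))
  y <- c("WT", "WT", "HYPO", "HYPO")
  cls <- fit_fisher(X, y)
  expect_true(cls$degenerate)
  expect_identical(cls$majority, "WT")  # tie goes to WT
  expect_identical(predict(cls, X), rep("WT", 4))
})

test_that("weights match the closed-form scatter solution and the scan oracle", {
  set.seed(13)
  for (rep in 1:5) {
    X <- rbind(matrix(rnorm(40, mean = 1), 20, 2),
               matrix(rnorm(40, mean = -0.5), 20, 2))
    y <- rep(c("WT", "HYPO"), each = 20)
    cls <- fit_fisher(X, y)
    mu1 <- colMeans(X[1:20, ]); mu2 <- colMeans(X[21:40, ])
    Sw <- crossprod(sweep(X[1:20, ], 2, mu1)) +
      crossprod(sweep(X[21:40, ], 2, mu2))
    w_ref <- solve(Sw, mu1 - mu2)
    cosang <- sum(cls$w * w_ref) / sqrt(sum(cls$w^2) * sum(w_ref^2))
    expect_gte(cosang, 0.9999)
    oracle <- scan_threshold_oracle(drop(X %*% cls$w), y, cls$orientation)
    expect_equal(cls$b, unname(oracle["b"]), tolerance = 1e-12)
  }
})

test_that("predictions are invariant to joint positive rescaling of (w, b)", {
  set.seed(14)
  X <- rbind(matrix(rnorm(30, 1), 15, 2), matrix(rnorm(30, -1), 15, 2))
  y <- rep(c("WT", "HYPO"), each = 15)
  cls <- fit_fisher(X, y)
  scaled <- cls
  scaled$w <- 2 * cls$w
  scaled$b <- 2 * cls$b
  Xt <- matrix(rnorm(40), 20, 2)
  expect_identical(predict(cls, Xt), predict(scaled, Xt))
  # boundary points go to the orientation class, deterministically
  axis_cls <- structure(list(w = c(1, 0), b = 0.5, orientation = "HYPO",
                             ridge = 0, training_error = 0,
                             degenerate = FALSE, majority = "WT"),
                        class = "erp_fisher")
  expect_identical(predict(axis_cls, matrix(c(0.5, 7), 1, 2)), "HYPO")
  expect_identical(predict(axis_cls, matrix(c(0.5 - 1e-9, 7), 1, 2)), "WT")
  expect_error(predict(cls, matrix(0, 2, 5)), "dimension mismatch")
  expect_error(fit_fisher(X, rep("WT", 30)), "both classes")
  expect_error(fit_fisher(X[c(1, 16:30), ], y[c(1, 16:30)]), "2 samples")
})

test_that("training error is invariant to a uniform affine feature transform", {
  set.seed(15)
  X <- rbind(matrix(rnorm(60, 1), 30, 2), matrix(rnorm(60, -1), 30, 2))
  y <- rep(c("WT", "HYPO"), each = 30)
  shift <- c(5, -3)
  Xa <- 2.5 * sweep(X, 2, shift, "+")
  a <- fit_fisher(X, y)
  b <- fit_fisher(Xa, y)
  expect_identical(predict(a, X), predict(b, Xa))
  expect_equal(a$training_error, b$training_error)
})

test_that("leave-one-animal-out never leaks held-out samples into training", {
  set.seed(16)
  n_an <- 6; n_per <- 10; d <- 8
  mu <- rep(c(2, -2), each = 3)
  X <- do.call(rbind, lapply(seq_len(n_an), function(a)
    matrix(rnorm(n_per * d, mean = mu[a]), n_per, d)))
  anim <- rep(sprintf("a%d", 1:n_an), each = n_per)
  geno <- rep(c("WT", "HYPO"), each = 3 * n_per)
  fm <- feature_matrix(X, anim, geno, "waveform", "FR")
  base <- epierp:::cv_cell(fm, "pc_multi", 1, pc_grid = c(1L, 2L, 4L))
  # poison every sample of one animal with large alternating constants
  Xp <- X
  Xp[anim == "a3", ] <- rep(c(1e6, -1e6), length.out = sum(anim == "a3"))
  poisoned <- epierp:::cv_cell(feature_matrix(Xp, anim, geno, "waveform", "FR"),
                               "pc_multi", 1, pc_grid = c(1L, 2L, 4L))
  expect_identical(base$folds[["a3"]]$w, poisoned$folds[["a3"]]$w)
  expect_identical(base$folds[["a3"]]$b, poisoned$folds[["a3"]]$b)
  expect_identical(base$folds[["a3"]]$chosen_pcs,
                   poisoned$folds[["a3"]]$chosen_pcs)
  # the poisoned animal's own predictions do change
  expect_false(identical(
    base$predictions$predicted[anim == "a3"],
    poisoned$predictions$predicted[anim == "a3"]))
})

test_that("a huge planted effect with almost no noise classifies perfectly", {
  set.seed(17)
  n_an <- 6; n_per <- 8; d <- 12
  X <- do.call(rbind, lapply(seq_len(n_an), function(a) {
    eff <- if (a <= 3) 10 else -10
    matrix(rnorm(n_per * d, mean = eff, sd = 0.1), n_per, d)
  }))
  anim <- rep(sprintf("a%d", 1:n_an), each = n_per)
  geno <- rep(c("WT", "HYPO"), each = 3 * n_per)
  fm <- feature_matrix(X, anim, geno, "waveform", "FR")
  cell <- epierp:::cv_cell(fm, "pc_multi", 1, pc_grid = c(1L, 2L))
  expect_equal(cell$error, 0)
  expect_identical(cell$votes$vote, cell$votes$genotype)
})

test_that("permuted labels drive aggregate error to chance", {
  set.seed(18)
  n_an <- 10; n_per <- 100; d <- 4   # low-dimensional: no room to overfit
  X <- matrix(rnorm(n_an * n_per * d), ncol = d)
  anim <- rep(sprintf("a%02d", 1:n_an), each = n_per)
  geno <- rep(rep(c("WT", "HYPO"), 5), each = n_per)
  fm <- feature_matrix(X, anim, geno, "waveform", "FR")
  cell <- epierp:::cv_cell(fm, "pc_multi", 1, pc_grid = c(1L, 2L, 3L))
  expect_lt(abs(cell$error - 0.5), 0.1)
})

test_that("the averaging grid report has one row per (k, kind) cell", {
  cfg <- default_config(n_per_genotype = 2L, n_trials = 24L, seed = 5L,
                        noise_sd_uV = 5)
  eps <- cohort_eps(cfg)
  rep <- error_vs_averaging(eps, k_grid = c(1, 4),
                            pc_grid = c(1L, 2L, 5L))
  expect_s3_class(rep, "cv_report")
  expect_equal(nrow(rep), 6)
  expect_setequal(unique(rep$feature_kind),
                  c("peaks_single", "peaks_multi", "pc_multi"))
  expect_true(all(rep$error >= 0 & rep$error <= 1))
  expect_true(all(!is.na(rep$n_pcs[rep$feature_kind == "pc_multi"])))
  # every held-out sample is predicted exactly once
  cells <- attr(rep, "cells")
  expect_equal(cells[["pc_multi_4"]]$n_samples,
               nrow(cells[["pc_multi_4"]]$predictions))
})
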