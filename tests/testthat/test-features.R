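test_that("peak detection matches a dense extremum search on the analytic mixture", {
  t_ms <- 0:249
  x <- mixture_frontal(t_ms)
  got <- detect_peak_components(x, 1000)
  oracle <- dense_extrema(mixture_frontal)
  expect_true(all(got$valid))
  expect_equal(oracle$type[1:3], c("min", "max", "min"))
  for (i in 1:3) {
    expect_lt(abs(got$latency_ms[i] - oracle$latency_ms[i]), 2)
    expect_lt(abs(got$amplitude_uV[i] - oracle$value[i]),
              0.05 * abs(oracle$value[i]))
  }
  # and the planted component latencies are recovered to within 2 ms
  expect_lt(abs(got$latency_ms[1] - 25), 2)
  expect_lt(abs(got$latency_ms[2] - 60), 2)
  expect_lt(abs(got$latency_ms[3] - 120), 2)
})

test_that("degenerate waveforms yield invalid components", {
  flat <- detect_peak_components(rep(0, 250), 1000)
  expect_false(any(flat$valid))
  # single positive bump: first extremum is a maximum, labeled P1
  bump <- 15 * exp(-((0:249) - 100)^2 / (2 * 10^2))
  got <- detect_peak_components(bump, 1000)
  expect_false(got$valid[1])                # no N1
  expect_true(got$valid[2])
  expect_lt(abs(got$latency_ms[2] - 100), 2)
  expect_false(got$valid[3])                # no N2
  expect_error(detect_peak_components(c(1, 2), 1000), "smoothing")
})

test_that("peak detection is equivariant to positive amplitude scaling", {
  t_ms <- 0:249
  x <- mixture_frontal(t_ms)
  a <- detect_peak_components(x, 1000)
  b <- detect_peak_components(3.7 * x, 1000)
  expect_equal(b$latency_ms, a$latency_ms)
  expect_equal(b$amplitude_uV, 3.7 * a$amplitude_uV, tolerance = 1e-12)
})

test_that("noise-free epochs recover planted latencies at every channel", {
  cfg <- default_config(noise_sd_uV = 0, animal_jitter_frac = 0,
                        artifact_prob = 0, n_trials = 4L)
  ep <- extract_epochs(simulate_animal(cfg, "WT", "a", seed = 1))
  sel <- ep$time_ms >= 0 & ep$time_ms < 250
  ga <- grand_average(ep)
  for (ch in names(cfg$channel_templates)) {
    tpl <- cfg$channel_templates[[ch]]
    f <- function(t) epierp:::template_waveform(tpl, t)
    oracle <- dense_extrema(f)
    got <- detect_peak_components(ga[ch, sel], 1000)
    expect_true(all(got$valid), info = ch)
    for (i in 1:3)
      expect_lt(abs(got$latency_ms[i] - oracle$latency_ms[i]), 2)
  }
})

test_that("peak feature matrices have the documented geometry", {
  cfg <- default_config(noise_sd_uV = 2, n_trials = 8L)
  ep <- reject_artifacts(extract_epochs(simulate_animal(cfg, "WT", "a", 1)))
  multi <- build_peak_feature_matrix(ep, c("FL", "FR", "PR", "OL", "OR"))
  expect_equal(ncol(multi$X), 30)
  expect_equal(nrow(multi$X), 8)
  expect_identical(multi$kind, "peaks_multi")
  single <- build_peak_feature_matrix(ep, "FR")
  expect_equal(ncol(single$X), 6)
  expect_identical(single$kind, "peaks_single")
  expect_error(build_peak_feature_matrix(ep, character()), "empty")
  expect_error(build_peak_feature_matrix(ep, "ZZ"), "ZZ")
})

test_that("invalid peaks are imputed with valid-entry column means", {
  X <- matrix(c(1, 2, NA, 4,
                10, NA, 30, 40), ncol = 2)
  fm <- feature_matrix(X, rep("a", 4), rep("WT", 4), "peaks_single", "FR")
  imp <- impute_features(fm)
  expect_equal(imp$X[3, 1], mean(c(1, 2, 4)))
  expect_equal(imp$X[2, 2], mean(c(10, 30, 40)))
  expect_false(anyNA(imp$X))
  # training-partition statistics override the matrix's own means
  imp2 <- impute_features(fm, stats = c(100, 200))
  expect_equal(imp2$X[3, 1], 100)
  expect_equal(imp2$X[2, 2], 200)
})

test_that("waveform features concatenate channels in declared order", {
  set.seed(8)
  dat <- array(rnorm(4 * 3 * 500), dim = c(4, 3, 500),
               dimnames = list(NULL, c("FR", "OL", "PR"), NULL))
  ep <- make_epochs(dat, time_ms = seq(-250, 249))
  fm <- build_waveform_feature_matrix(ep, c("PR", "FR"), c(0, 250))
  expect_equal(dim(fm$X), c(4, 500))
  sel <- which(ep$time_ms >= 0 & ep$time_ms < 250)
  expect_equal(unname(fm$X[2, 1:250]), dat[2, 3, sel])   # PR block first
  expect_equal(unname(fm$X[2, 251:500]), dat[2, 1, sel]) # FR block second
  # permuting storage order leaves the feature columns unchanged
  perm <- dat[, c(2, 3, 1), ]
  ep2 <- make_epochs(perm, time_ms = seq(-250, 249))
  fm2 <- build_waveform_feature_matrix(ep2, c("PR", "FR"), c(0, 250))
  expect_equal(fm2$X, fm$X)
  expect_error(build_waveform_feature_matrix(ep, "QQ"), "QQ")
})

test_that("five channels at 1 kHz over (0,250) ms give 1250 columns", {
  cfg <- default_config(noise_sd_uV = 1, n_trials = 2L)
  ep <- extract_epochs(simulate_animal(cfg, "WT", "a", 1))
  fm <- build_waveform_feature_matrix(ep, c("FL", "FR", "PR", "OL", "OR"))
  expect_equal(dim(fm$X), c(2, 1250))
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(9)
  X <- matrix(rnorm(15 * 6), 15, 6)
  m <- fit_pca(X)
  C <- cov(X)
  ee <- eigen(C, symmetric = TRUE)
  expect_equal(m$variance, ee$values[seq_along(m$variance)],
               tolerance = 1e-10)
  # principal angles between matched loading/eigenvector pairs
  for (i in seq_len(nrow(m$loadings))) {
    cosang <- abs(sum(m$loadings[i, ] * ee$vectors[, i]))
    expect_lt(acos(pmin(cosang, 1)), 1e-6)
  }
  # orthonormal rows
  G <- m$loadings %*% t(m$loadings)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
})

test_that("dual-route PCA (n < d) agrees with the covariance route", {
  set.seed(10)
  X <- matrix(rnorm(8 * 40), 8, 40)
  m <- fit_pca(X)                     # dual path: 8 obs, 40 features
  ee <- eigen(cov(X), symmetric = TRUE)
  r <- length(m$variance)
  expect_equal(m$variance, ee$values[seq_len(r)], tolerance = 1e-8)
  for (i in seq_len(r))
    expect_lt(acos(pmin(abs(sum(m$loadings[i, ] * ee$vectors[, i])), 1)),
              1e-6)
  G <- m$loadings %*% t(m$loadings)
  expect_lt(max(abs(G - diag(r))), 1e-8)
})

test_that("PCA handles the rank-one two-point case and rejects constants", {
  m <- fit_pca(rbind(c(1, 1), c(-1, -1)))
  expect_equal(length(m$variance), 1)
  expect_equal(abs(m$loadings[1, ]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(m$variance[1] / sum(m$variance), 1)
  expect_error(fit_pca(matrix(3, 5, 4)), "constant")
  expect_error(fit_pca(matrix(1, 1, 4)), "2 rows")
})

test_that("projection truncates, round-trips at full rank, and validates n_pcs", {
  set.seed(11)
  X <- matrix(rnorm(20 * 7), 20, 7)
  m <- fit_pca(X)
  s5 <- project_pca(m, X, 5)
  expect_equal(ncol(s5), 5)
  full <- project_pca(m, X, length(m$variance))
  recon <- full %*% m$loadings + matrix(m$center, 20, 7, byrow = TRUE)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_error(project_pca(m, X, 0), "out of range")
  expect_error(project_pca(m, X, 100), "out of range")
})

test_that("PC scores are rotation-invariant up to component sign", {
  set.seed(12)
  X <- matrix(rnorm(30 * 6), 30, 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  a <- project_pca(fit_pca(X), X, 4)
  b <- project_pca(fit_pca(X %*% Q), X %*% Q, 4)
  expect_equal(abs(a), abs(b), tolerance = 1e-6)
})
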