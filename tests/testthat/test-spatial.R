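test_that("the spanning plane contains its three defining grand averages", {
  set.seed(20)
  gas <- lapply(1:3, function(i) rnorm(60, sd = 10))
  pl <- spanning_plane(gas[[1]], gas[[2]], gas[[3]])
  for (g in gas) {
    xy <- project_onto_plane(pl, g)
    recon <- pl$origin + drop(xy %*% pl$basis)
    expect_lt(sqrt(sum((recon - g)^2)) / sqrt(sum(g^2)), 1e-9)
  }
  # basis orthonormal; projection idempotent
  B <- pl$basis %*% t(pl$basis)
  expect_lt(max(abs(B - diag(2))), 1e-10)
  w <- rnorm(60)
  xy1 <- project_onto_plane(pl, w)
  in_plane <- pl$origin + drop(xy1 %*% pl$basis)
  expect_equal(project_onto_plane(pl, in_plane), xy1, tolerance = 1e-9)
  expect_error(spanning_plane(gas[[1]], 2 * gas[[1]],
                              -0.5 * gas[[1]]), "collinear")
  expect_error(project_onto_plane(pl, rnorm(10)), "length")
})

test_that("plane projections match the least-squares oracle and the axes", {
  set.seed(21)
  gas <- lapply(1:3, function(i) rnorm(40, sd = 5))
  pl <- spanning_plane(gas[[1]], gas[[2]], gas[[3]])
  expect_equal(drop(project_onto_plane(pl, pl$origin)), c(0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(drop(project_onto_plane(pl, pl$origin + pl$basis[1, ])),
               c(1, 0), tolerance = 1e-12, ignore_attr = TRUE)
  # normal-equations least squares onto the spanning vectors
  w <- rnorm(40)
  B <- t(pl$basis)
  beta <- solve(crossprod(B), crossprod(B, w - pl$origin))
  expect_equal(drop(project_onto_plane(pl, w)), drop(beta),
               tolerance = 1e-10, ignore_attr = TRUE)
  # a waveform orthogonal to both spanning vectors projects to the origin
  v <- rnorm(40)
  v <- v - sum(v * pl$basis[1, ]) * pl$basis[1, ] -
    sum(v * pl$basis[2, ]) * pl$basis[2, ]
  expect_equal(drop(project_onto_plane(pl, pl$origin + v)), c(0, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  # isometry on the plane: in-plane inner products are preserved
  xy <- matrix(rnorm(10), 5, 2)
  W <- sweep(xy %*% pl$basis, 2, -pl$origin)
  expect_equal(tcrossprod(project_onto_plane(pl, W)), tcrossprod(xy),
               tolerance = 1e-9)
})

test_that("covariance ellipses recover a known isotropic generator", {
  set.seed(22)
  pts <- matrix(rnorm(20000), ncol = 2)
  e1 <- covariance_ellipse(pts, nsigma = 1)
  expect_true(all(e1$semi_axes >= 0.95 & e1$semi_axes <= 1.05))
  e2 <- covariance_ellipse(pts, nsigma = 2)
  expect_equal(e2$semi_axes, 2 * e1$semi_axes, tolerance = 1e-12)
  # collinear points: zero minor axis, no failure
  line <- cbind(1:10, 2 * (1:10))
  ec <- covariance_ellipse(line)
  expect_equal(ec$semi_axes[2], 0, tolerance = 1e-10)
  expect_error(covariance_ellipse(matrix(0, 1, 2)), "2 points")
  coords <- ellipse_coords(e1)
  expect_equal(ncol(coords), 2)
})

test_that("rank-one discriminants factor into the planted space-time parts", {
  set.seed(23)
  nch <- 5; nt <- 50; d <- nch * nt
  s <- c(1.5, -2, 0.5, 3, -1)
  tau <- sin(seq(0, 3 * pi, length.out = nt)) * exp(-seq(0, 2, length.out = nt))
  tau <- tau / sqrt(sum(tau^2))
  W <- outer(s, tau)                        # channels x time
  w_wave <- as.vector(t(W))                 # channel-major concatenation
  L <- random_orthonormal(d, d)
  w_pc <- drop(L %*% w_wave)
  pca <- structure(list(center = rep(0, d), loadings = L,
                        variance = rep(1, d), n_obs = 100),
                   class = "erp_pca")
  cls <- structure(list(w = w_pc, b = 0, orientation = "WT", ridge = 0,
                        training_error = 0, degenerate = FALSE,
                        majority = "WT"),
                   class = "erp_fisher")
  disc <- extract_temporal_discriminant(cls, pca, paste0("ch", 1:nch), nt)
  expect_equal(sqrt(sum(disc$temporal^2)), 1, tolerance = 1e-9)
  cosang <- abs(sum(disc$temporal * tau))
  expect_gte(cosang, 0.999)
  # spatial weights proportional to the planted channel pattern
  cos_sp <- abs(sum(disc$spatial * s)) /
    sqrt(sum(disc$spatial^2) * sum(s^2))
  expect_gte(cos_sp, 0.999)
  # sign convention: flipping the planted temporal sign changes nothing
  cls2 <- cls
  cls2$w <- drop(L %*% as.vector(t(outer(-s, -tau))))
  disc2 <- extract_temporal_discriminant(cls2, pca, paste0("ch", 1:nch), nt)
  expect_equal(disc2$temporal, disc$temporal, tolerance = 1e-9)
  expect_error(extract_temporal_discriminant(cls, pca, paste0("ch", 1:4), nt),
               "dimension")
})

test_that("thin-plate maps interpolate the electrode values exactly", {
  mont <- default_montage()
  eeg <- mont[mont$kind == "eeg", ]
  set.seed(24)
  erp <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(eeg$label, NULL))
  tau <- rnorm(40); tau <- tau / sqrt(sum(tau^2))
  map <- channel_projection_map(erp, tau, mont, grid_step = 0.5)
  vals <- drop(erp %*% tau)
  expect_equal(unname(map$channel_values), unname(vals), tolerance = 1e-12)
  for (i in seq_len(nrow(eeg))) {
    ai <- which.min(abs(map$ap - eeg$ap_mm[i]))
    mi <- which.min(abs(map$ml - eeg$ml_mm[i]))
    expect_lt(abs(map$values[ai, mi] - vals[i]), 1e-8)
  }
  # linearity: doubling the ERP doubles the map
  map2 <- channel_projection_map(2 * erp, tau, mont, grid_step = 0.5)
  expect_equal(map2$values, 2 * map$values, tolerance = 1e-9)
  # constant electrode values give a constant surface
  cst <- matrix(1, 6, 40, dimnames = list(eeg$label, NULL))
  cmap <- channel_projection_map(cst, rep(1 / 40, 40) * 40 / sqrt(40), mont,
                                 grid_step = 0.5)
  expect_lt(diff(range(cmap$values)), 1e-6)
  # missing electrode value errors with the channel name
  expect_error(channel_projection_map(erp[1:5, ], tau, mont), "OR")
})

test_that("serialized spatial maps keep grid and channel values together", {
  mont <- default_montage()
  eeg <- mont[mont$kind == "eeg", ]
  erp <- matrix(seq_len(6 * 10), 6, 10, dimnames = list(eeg$label, NULL))
  tau <- rep(1 / sqrt(10), 10)
  map <- channel_projection_map(erp, tau, mont, grid_step = 1,
                                animal_id = "wt01")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_spatial_map(map, tsv, js)
  grid <- read.delim(tsv)
  expect_equal(nrow(grid), length(map$ap) * length(map$ml))
  meta <- jsonlite::fromJSON(js)
  expect_equal(meta$animal_id, "wt01")
  expect_equal(unlist(meta$channel_values), map$channel_values,
               tolerance = 1e-12)
})
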