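#' Principal component analysis of waveform features
#'
#' Mean-centered PCA via eigendecomposition of the sample covariance,
#' using the dual (Gram-matrix) route automatically when there are fewer
#' observations than features. Loadings are orthonormal rows ordered by
#' explained variance (descending); each component's sign is fixed so its
#' largest-magnitude coefficient is positive.
#'
#' @param x A `feature_matrix` or numeric matrix (rows = samples).
#' @param rank. Optional cap on the number of components returned.
#' @return An `erp_pca`: `center`, `loadings` (components x features),
#'   `variance` (covariance eigenvalues), `n_obs`.
#' @export
fit_pca <- function(x, rank. = NULL) {
  X <- if (inherits(x, "feature_matrix")) x$X else as.matrix(x)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("fit_pca needs at least 2 rows")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  total_var <- sum(Xc^2) / (n - 1)
  if (total_var <= 0 || !is.finite(total_var))
    stop("constant feature matrix: no variance to decompose")
  rmax <- min(n - 1L, d)
  if (!is.null(rank.)) rmax <- min(rmax, as.integer(rank.))
  if (n - 1 < d) {
    G <- tcrossprod(Xc)
    ee <- eigen(G, symmetric = TRUE)
    vals <- ee$values[seq_len(rmax)]
    keep <- vals > max(ee$values) * 1e-12
    vals <- vals[keep]
    U <- ee$vectors[, seq_len(rmax), drop = FALSE][, keep, drop = FALSE]
    L <- crossprod(Xc, sweep(U, 2, sqrt(vals), "/"))   # d x r
    loadings <- t(L)
    variance <- vals / (n - 1)
  } else {
    C <- crossprod(Xc) / (n - 1)
    ee <- eigen(C, symmetric = TRUE)
    vals <- ee$values[seq_len(rmax)]
    keep <- vals > max(ee$values) * 1e-12
    loadings <- t(ee$vectors[, seq_len(rmax), drop = FALSE][, keep, drop = FALSE])
    variance <- vals[keep]
  }
  # sign convention: largest-magnitude coefficient positive
  for (i in seq_len(nrow(loadings))) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) loadings[i, ] <- -loadings[i, ]
  }
  structure(list(center = center, loadings = loadings, variance = variance,
                 n_obs = n),
            class = "erp_pca")
}

#' @export
print.erp_pca <- function(x, ...) {
  cat(sprintf("<erp_pca> %d components x %d features (n = %d); top variance share %.1f%%\n",
              nrow(x$loadings), ncol(x$loadings), x$n_obs,
              100 * x$variance[1] / sum(x$variance)))
  invisible(x)
}

#' Number of available components
#' @param model An `erp_pca`.
#' @return Integer.
#' @export
n_components <- function(model) nrow(model$loadings)

#' Project onto the leading principal components
#'
#' @param model An `erp_pca`.
#' @param x A `feature_matrix` or matrix with matching feature dimension.
#' @param n_pcs Number of leading components (1 .. available).
#' @return If `x` is a `feature_matrix`, a `feature_matrix` of kind
#'   `"pc"`; otherwise a scores matrix.
#' @export
project_pca <- function(model, x, n_pcs) {
  stopifnot(inherits(model, "erp_pca"))
  if (n_pcs < 1 || n_pcs > n_components(model))
    stop("n_pcs out of range [1, ", n_components(model), "]")
  X <- if (inherits(x, "feature_matrix")) x$X else as.matrix(x)
  if (ncol(X) != ncol(model$loadings))
    stop("feature dimension mismatch")
  S <- sweep(X, 2, model$center) %*% t(model$loadings[seq_len(n_pcs), , drop = FALSE])
  colnames(S) <- paste0("PC", seq_len(n_pcs))
  if (inherits(x, "feature_matrix"))
    feature_matrix(S, x$animal_id, x$genotype, "pc", x$channels,
                   x$window_ms, n_pcs = as.integer(n_pcs))
  else S
}
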