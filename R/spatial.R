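#' Plane spanned by three grand-average waveforms
#'
#' The 2-D affine subspace determined by three channel grand averages
#' (canonically FR, PR, OR): the origin is their centroid and the two
#' spanning waveforms are the Gram-Schmidt orthonormalization of
#' (first - centroid, second - centroid). Because the origin is the
#' centroid, the third waveform lies in the plane by construction.
#'
#' @param ga_fr,ga_pr,ga_or Equal-length waveform vectors.
#' @return A `projection_plane`: `origin`, `basis` (2 x length,
#'   orthonormal rows).
#' @export
spanning_plane <- function(ga_fr, ga_pr, ga_or) {
  stopifnot(length(ga_fr) == length(ga_pr), length(ga_pr) == length(ga_or))
  origin <- (ga_fr + ga_pr + ga_or) / 3
  v1 <- ga_fr - origin
  v2 <- ga_pr - origin
  n1 <- sqrt(sum(v1^2))
  if (n1 <= 1e-12 * (1 + sqrt(sum(origin^2))))
    stop("degenerate spanning waveforms: plane undefined")
  e1 <- v1 / n1
  u2 <- v2 - sum(v2 * e1) * e1
  n2 <- sqrt(sum(u2^2))
  if (n2 <= 1e-10 * sqrt(sum(v2^2)))
    stop("collinear grand averages: plane undefined")
  e2 <- u2 / n2
  structure(list(origin = origin, basis = rbind(e1, e2)),
            class = "projection_plane")
}

#' Project waveforms onto a spanning plane
#'
#' Coordinates are inner products with the two spanning waveforms after
#' centering on the plane origin; on the plane itself this projection is
#' an isometry.
#'
#' @param plane A `projection_plane`.
#' @param waveforms A vector or a matrix with waveforms in rows.
#' @return An n x 2 coordinate matrix.
#' @export
project_onto_plane <- function(plane, waveforms) {
  W <- if (is.matrix(waveforms)) waveforms else matrix(waveforms, nrow = 1)
  if (ncol(W) != length(plane$origin))
    stop("waveform length does not match the plane")
  sweep(W, 2, plane$origin) %*% t(plane$basis)
}

#' Covariance ellipse of a 2-D point cloud
#'
#' @param points n x 2 matrix (n >= 2).
#' @param nsigma Contour multiplier; at `nsigma = 1` the ellipse is the
#'   1 SD contour of the sample covariance.
#' @return An `ellipse_params` list: `center`, `semi_axes` (major,
#'   minor), `angle_rad` (orientation of the major axis), `nsigma`.
#'   Collinear points give a zero minor semi-axis.
#' @export
covariance_ellipse <- function(points, nsigma = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  stopifnot(ncol(points) == 2)
  center <- colMeans(points)
  C <- cov(points)
  ee <- eigen(C, symmetric = TRUE)
  semi <- nsigma * sqrt(pmax(ee$values, 0))
  structure(list(center = center, semi_axes = semi,
                 angle_rad = atan2(ee$vectors[2, 1], ee$vectors[1, 1]),
                 nsigma = nsigma),
            class = "ellipse_params")
}

#' Ellipse boundary coordinates (for plotting)
#' @param ellipse An `ellipse_params`.
#' @param n Number of polygon vertices.
#' @return n x 2 matrix.
#' @export
ellipse_coords <- function(ellipse, n = 100) {
  th <- seq(0, 2 * pi, length.out = n)
  u <- rbind(ellipse$semi_axes[1] * cos(th), ellipse$semi_axes[2] * sin(th))
  R <- matrix(c(cos(ellipse$angle_rad), sin(ellipse$angle_rad),
                -sin(ellipse$angle_rad), cos(ellipse$angle_rad)), 2, 2)
  t(R %*% u + ellipse$center)
}

#' Factor the discriminant into a temporal profile and spatial weights
#'
#' The PC-space Fisher weight vector is mapped back to waveform space
#' through the PCA loadings, reshaped to channels x time, and factored by
#' singular value decomposition. The leading right-singular vector (unit
#' norm, sign fixed so its largest-magnitude sample is positive) is the
#' temporal discriminant; the leading left-singular vector scaled by the
#' leading singular value gives the per-channel spatial weights.
#'
#' @param classifier An `erp_fisher` trained on PC scores of concatenated
#'   channel waveforms.
#' @param pca The `erp_pca` those scores came from.
#' @param channels Channel labels, in the concatenation order.
#' @param n_time Samples per channel; `length(channels) * n_time` must
#'   equal the waveform feature dimension.
#' @return A `temporal_discriminant`: `temporal` (unit vector, length
#'   `n_time`), `spatial` (named per-channel weights), `singular_values`,
#'   and the waveform-space weight matrix `w_matrix`.
#' @export
extract_temporal_discriminant <- function(classifier, pca, channels, n_time) {
  stopifnot(inherits(classifier, "erp_fisher"), inherits(pca, "erp_pca"))
  j <- length(classifier$w)
  if (j > n_components(pca)) stop("classifier uses more PCs than the model has")
  d <- ncol(pca$loadings)
  if (length(channels) * n_time != d)
    stop("channels x time (", length(channels) * n_time,
         ") does not match the waveform feature dimension (", d, ")")
  w_wave <- drop(crossprod(pca$loadings[seq_len(j), , drop = FALSE],
                           classifier$w))
  M <- t(matrix(w_wave, nrow = n_time, ncol = length(channels)))
  rownames(M) <- channels
  sv <- svd(M)
  tau <- sv$v[, 1]
  sgn <- sign(tau[which.max(abs(tau))])
  if (sgn < 0) tau <- -tau
  spatial <- sv$u[, 1] * sv$d[1] * sgn
  names(spatial) <- channels
  structure(list(temporal = tau, spatial = spatial,
                 singular_values = sv$d, w_matrix = M),
            class = "temporal_discriminant")
}

# Thin-plate RBF kernel phi(r) = r^2 log r (0 at r = 0).
tps_phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)

# Exact thin-plate spline interpolation through scattered 2-D points.
tps_fit <- function(xy, v) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  K <- tps_phi(D)
  P <- cbind(1, xy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(A, c(v, 0, 0, 0))
  list(xy = xy, w = coef[seq_len(n)], a = coef[n + 1:3])
}

tps_eval <- function(fit, grid_xy) {
  D <- sqrt(outer(grid_xy[, 1], fit$xy[, 1], "-")^2 +
              outer(grid_xy[, 2], fit$xy[, 2], "-")^2)
  drop(tps_phi(D) %*% fit$w) + fit$a[1] + fit$a[2] * grid_xy[, 1] +
    fit$a[3] * grid_xy[, 2]
}

#' Interpolated cortical map of discriminant projections
#'
#' Each channel's animal-mean waveform over the analysis window is
#' projected onto the temporal discriminant (inner product), and the
#' per-channel scalars are interpolated over a stereotaxic grid by exact
#' thin-plate radial-basis interpolation through the montage's EEG
#' electrode coordinates.
#'
#' @param erp Channels x time matrix of mean waveforms (rownames are
#'   channel labels) over the analysis window.
#' @param temporal Temporal discriminant vector (length = time samples).
#' @param mont A [montage()]; every EEG electrode in it must have a row
#'   in `erp`.
#' @param ap_range,ml_range Grid extents in mm.
#' @param grid_step Grid spacing in mm.
#' @param animal_id Carried into the result.
#' @return A `spatial_map`: `channel_values` (named), `ap`, `ml`,
#'   `values` (length(ap) x length(ml) matrix), `animal_id`.
#' @export
channel_projection_map <- function(erp, temporal, mont = default_montage(),
                                   ap_range = c(-6, 3), ml_range = c(-4, 4),
                                   grid_step = 0.1,
                                   animal_id = NA_character_) {
  stopifnot(ncol(erp) == length(temporal))
  eeg <- mont[mont$kind == "eeg", , drop = FALSE]
  missing_ch <- setdiff(eeg$label, rownames(erp))
  if (length(missing_ch))
    stop("montage channel(s) missing a value: ",
         paste(missing_ch, collapse = ", "))
  vals <- drop(erp[eeg$label, , drop = FALSE] %*% temporal)
  names(vals) <- eeg$label
  xy <- cbind(eeg$ap_mm, eeg$ml_mm)
  fit <- tps_fit(xy, vals)
  ap <- seq(ap_range[1], ap_range[2], by = grid_step)
  ml <- seq(ml_range[1], ml_range[2], by = grid_step)
  grid_xy <- cbind(rep(ap, times = length(ml)), rep(ml, each = length(ap)))
  z <- matrix(tps_eval(fit, grid_xy), nrow = length(ap))
  structure(list(channel_values = vals, ap = ap, ml = ml, values = z,
                 animal_id = animal_id),
            class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("<spatial_map> %s: %d electrodes, grid %d x %d\n",
              x$animal_id, length(x$channel_values), length(x$ap),
              length(x$ml)))
  invisible(x)
}

#' Plot an interpolated cortical map
#' @param x A `spatial_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.spatial_map <- function(x, ...) {
  image(x$ap, x$ml, x$values, xlab = "AP (mm)", ylab = "ML (mm)",
        col = hcl.colors(64, "RdBu", rev = TRUE), ...)
  contour(x$ap, x$ml, x$values, add = TRUE, drawlabels = FALSE)
  invisible(x)
}

#' Write a spatial map (grid TSV + per-channel JSON)
#' @param map A `spatial_map`.
#' @param tsv_path Grid TSV output (`ap`, `ml`, `value` long format).
#' @param json_path Per-channel values JSON.
#' @return `tsv_path`, invisibly.
#' @export
write_spatial_map <- function(map, tsv_path, json_path = NULL) {
  df <- data.frame(ap_mm = rep(map$ap, times = length(map$ml)),
                   ml_mm = rep(map$ml, each = length(map$ap)),
                   value = as.vector(map$values))
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(list(animal_id = map$animal_id,
                                     channel_values = as.list(map$channel_values)),
                                auto_unbox = TRUE, digits = NA, na = "null",
                                pretty = TRUE), json_path)
  invisible(tsv_path)
}
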