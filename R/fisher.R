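#' Fisher linear discriminant classifier
#'
#' Two-class Fisher LDA: the weight vector is
#' `w ~ (Sw + lambda I)^-1 (mu_WT - mu_HYPO)` with pooled within-class
#' scatter `Sw` and a small conditioning ridge
#' `lambda = 1e-6 * trace(Sw) / d`; `w` is normalized to unit length. The
#' decision threshold is chosen by scanning the midpoints of consecutive
#' sorted training projections and taking the value minimizing the
#' class-balanced training misclassification (the mean of the two
#' per-class error rates, i.e. equal class priors — cohort genotype
#' frequencies are a design artifact, and the balanced objective keeps
#' the threshold centered when cross-validation folds are imbalanced);
#' ties are broken in favor of the widest margin
#' between the flanking projections (then the smallest threshold). If the
#' class means coincide (no direction to separate), the classifier is
#' flagged degenerate and predicts the majority class (ties go to WT).
#'
#' @param x A `feature_matrix` or numeric matrix (complete, no `NA`).
#' @param labels Per-row class labels (`WT`/`HYPO`); taken from the
#'   `feature_matrix` genotype when omitted.
#' @param ridge_scale Scale of the conditioning ridge.
#' @return An `erp_fisher`: `w`, `b`, `orientation` (the class predicted
#'   above the threshold), `ridge`, `training_error`, `degenerate`,
#'   `majority`.
#' @export
fit_fisher <- function(x, labels = NULL, ridge_scale = 1e-6) {
  X <- if (inherits(x, "feature_matrix")) x$X else as.matrix(x)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$genotype
  y <- as.character(labels)
  if (anyNA(X)) stop("fit_fisher requires a complete matrix (impute first)")
  classes <- unique(y)
  if (length(classes) < 2) stop("both classes must be present")
  if (!all(sort(classes) == sort(GENOTYPES)))
    stop("labels must be WT and HYPO")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  d <- ncol(X)
  mu_wt <- colMeans(X[y == "WT", , drop = FALSE])
  mu_hy <- colMeans(X[y == "HYPO", , drop = FALSE])
  dmu <- mu_wt - mu_hy
  Xw <- X
  Xw[y == "WT", ] <- sweep(X[y == "WT", , drop = FALSE], 2, mu_wt)
  Xw[y == "HYPO", ] <- sweep(X[y == "HYPO", , drop = FALSE], 2, mu_hy)
  Sw <- crossprod(Xw)
  lambda <- ridge_scale * sum(diag(Sw)) / d
  majority <- names(sort(table(factor(y, levels = GENOTYPES)),
                         decreasing = TRUE))[1]
  if (sum(y == "WT") == sum(y == "HYPO")) majority <- "WT"   # tie rule
  scale_ref <- 1 + sqrt(sum(mu_wt^2)) + sqrt(sum(mu_hy^2))
  if (sqrt(sum(dmu^2)) <= 1e-12 * scale_ref) {
    cls <- structure(list(w = rep(0, d), b = 0, orientation = majority,
                          ridge = lambda, training_error = mean(y != majority),
                          degenerate = TRUE, majority = majority),
                     class = "erp_fisher")
    return(cls)
  }
  w <- solve(Sw + diag(lambda, d), dmu)
  w <- w / sqrt(sum(w^2))
  p <- drop(X %*% w)
  orientation <- if (mean(p[y == "WT"]) >= mean(p[y == "HYPO"])) "WT" else "HYPO"
  other <- setdiff(GENOTYPES, orientation)
  o <- order(p)
  ps <- p[o]; ys <- y[o]
  n <- length(ps)
  # threshold after position i: rows 1..i predicted `other`, rest `orientation`
  cum_orient <- cumsum(ys == orientation)
  cum_other <- cumsum(ys == other)
  n_orient <- sum(ys == orientation); n_other <- n - n_orient
  i <- seq_len(n - 1)
  errs <- (cum_orient[i] / n_orient +
             (n_other - cum_other[i]) / n_other) / 2
  gaps <- ps[i + 1] - ps[i]
  cand <- (ps[i] + ps[i + 1]) / 2
  best <- order(errs, -gaps, cand)[1]
  b <- cand[best]
  pooled_err <- (cum_orient[best] + (n_other - cum_other[best])) / n
  structure(list(w = w, b = b, orientation = orientation, ridge = lambda,
                 training_error = pooled_err, balanced_error = errs[best],
                 degenerate = FALSE, majority = majority),
            class = "erp_fisher")
}

#' @export
print.erp_fisher <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("<erp_fisher> degenerate; predicts majority class %s\n", x$majority))
  else
    cat(sprintf("<erp_fisher> d=%d, b=%.4g, %s above threshold, training error %.3f\n",
                length(x$w), x$b, x$orientation, x$training_error))
  invisible(x)
}

#' Predict genotype labels
#'
#' Samples are labeled by the side of the threshold their projection
#' falls on; points exactly on the boundary go to the orientation class.
#' Predictions are invariant under joint positive rescaling of `(w, b)`.
#'
#' @param object An `erp_fisher`.
#' @param newdata A `feature_matrix` or matrix with matching dimension.
#' @param ... Unused.
#' @return Character vector of `"WT"`/`"HYPO"`.
#' @export
predict.erp_fisher <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else as.matrix(newdata)
  if (object$degenerate) return(rep(object$majority, nrow(X)))
  if (ncol(X) != length(object$w))
    stop("feature dimension mismatch: classifier has ", length(object$w),
         ", data has ", ncol(X))
  p <- drop(X %*% object$w)
  other <- setdiff(GENOTYPES, object$orientation)
  ifelse(p >= object$b, object$orientation, other)
}
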