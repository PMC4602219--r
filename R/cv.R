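#' Default grid of candidate PC counts
#'
#' Candidate numbers of leading principal components for the nested
#' selection; spans the single-trial optimum scale (tens of PCs) down to
#' the heavy-averaging optimum (a few PCs).
#'
#' @return Integer vector.
#' @export
default_pc_grid <- function() c(1L, 2L, 3L, 5L, 7L, 10L, 15L, 20L, 30L,
                                50L, 75L, 100L)

FEATURE_KINDS <- c("peaks_single", "peaks_multi", "pc_multi")

kind_channels <- function(kind, channels) {
  switch(kind,
         peaks_single = "FR",
         peaks_multi = channels,
         pc_multi = channels,
         stop("unknown feature kind: ", kind))
}

# Block-average each animal's epochs at k and build the raw per-kind
# feature matrix (NA-coded invalid peaks; no imputation/PCA here - those
# are fitted per fold). Animals with zero samples at this k are excluded
# with a warning.
cohort_features <- function(ep_list, kind, k, channels = CLASSIFY_CHANNELS,
                            window_ms = c(0, 250)) {
  use_ch <- kind_channels(kind, channels)
  fms <- list()
  for (ep in ep_list) {
    ba <- suppressWarnings(block_average(ep, k))
    if (dim(ba$data)[1] == 0) {
      warning("animal ", ep$animal_id, " has no complete block at k = ", k,
              "; excluded")
      next
    }
    fm <- if (kind == "pc_multi")
      build_waveform_feature_matrix(ba, use_ch, window_ms)
    else build_peak_feature_matrix(ba, use_ch, window_ms)
    fms[[length(fms) + 1L]] <- fm
  }
  if (length(fms) == 0) stop("no animal has a complete block at k = ", k)
  rbind_features(fms)
}

# Fit-and-score helper for the PC family: given training/validation score
# matrices, returns per-grid-value validation error counts.
fisher_grid_errors <- function(S_tr, y_tr, S_va, y_va, grid) {
  errs <- rep(NA_real_, length(grid))
  for (gi in seq_along(grid)) {
    j <- grid[gi]
    if (j > ncol(S_tr)) next
    cls <- fit_fisher(S_tr[, seq_len(j), drop = FALSE], y_tr)
    pred <- predict(cls, S_va[, seq_len(j), drop = FALSE])
    errs[gi] <- sum(pred != y_va)
  }
  errs
}

#' Leave-one-animal-out genotype cross-validation (one grid cell)
#'
#' For each held-out animal, the full feature pipeline is fitted on the
#' remaining animals only: peak-imputation column means for the peak
#' families, PCA plus nested selection of the number of components for
#' the waveform-PC family. The number of PCs is chosen by an inner
#' leave-one-animal-out loop over the training animals: the smallest
#' candidate whose pooled inner prediction error is within one standard
#' error of the minimum, the standard error being taken across inner
#' animals (the cluster unit) because plain argmin selection over so few
#' animal folds is dominated by cluster-level noise (exact ties likewise
#' go to the smallest count). The
#' final fold model is trained on all training animals and applied to
#' every held-out sample; the aggregate error pools misclassified
#' held-out samples over all folds. Per-animal majority-vote genotype
#' calls are also reported (vote ties go to WT).
#'
#' @param ep_list List of artifact-rejected single-trial `epoch_set`s,
#'   one per animal, with genotype metadata set.
#' @param kind `"peaks_single"`, `"peaks_multi"` or `"pc_multi"`.
#' @param k Trial-average block size.
#' @param pc_grid Candidate PC counts (PC family only).
#' @param channels Multi-channel set.
#' @param window_ms Analysis window.
#' @return A list (class `cv_cell`): `kind`, `k`, `error` (pooled,
#'   in [0, 1]), `n_samples`, `chosen_pcs` (per-fold), `n_pcs` (modal
#'   choice), `predictions` (data frame), `votes` (per-animal calls),
#'   `folds` (per-fold classifier summaries).
#' @export
loo_genotype_cv <- function(ep_list, kind, k, pc_grid = default_pc_grid(),
                            channels = CLASSIFY_CHANNELS,
                            window_ms = c(0, 250)) {
  kind <- match.arg(kind, FEATURE_KINDS)
  fm <- cohort_features(ep_list, kind, k, channels, window_ms)
  cv_cell(fm, kind, k, pc_grid)
}

# Core CV on a prepared feature matrix.
cv_cell <- function(fm, kind, k, pc_grid = default_pc_grid()) {
  X <- fm$X; anim <- fm$animal_id; y <- fm$genotype
  animals <- unique(anim)
  geno_by_animal <- vapply(animals, function(a) unique(y[anim == a]), "")
  if (min(table(factor(geno_by_animal, levels = GENOTYPES))) < 2)
    stop("leave-one-animal-out CV needs at least 2 animals per genotype")
  preds <- character(length(y))
  folds <- vector("list", length(animals))
  names(folds) <- animals
  for (a in animals) {
    test_rows <- anim == a
    tr_rows <- !test_rows
    if (kind == "pc_multi") {
      tr_animals <- setdiff(animals, a)
      rmax <- max(pc_grid)
      # inner leave-one-animal-out over the training animals
      B <- length(tr_animals)
      err_counts <- matrix(NA_real_, B, length(pc_grid))
      fold_n <- numeric(B)
      for (bi in seq_len(B)) {
        b <- tr_animals[bi]
        fit_rows <- tr_rows & anim != b
        val_rows <- anim == b
        if (length(unique(y[fit_rows])) < 2) next   # single-class inner fit
        pca_in <- fit_pca(X[fit_rows, , drop = FALSE], rank. = rmax)
        r <- n_components(pca_in)
        S_fit <- project_pca(pca_in, X[fit_rows, , drop = FALSE], min(r, rmax))
        S_val <- project_pca(pca_in, X[val_rows, , drop = FALSE], min(r, rmax))
        err_counts[bi, ] <- fisher_grid_errors(S_fit, y[fit_rows],
                                               S_val, y[val_rows], pc_grid)
        fold_n[bi] <- sum(val_rows)
      }
      usable <- fold_n > 0                          # inner folds with a 2-class fit
      if (!any(usable))
        stop("no usable inner fold: too few animals per genotype")
      err_counts <- err_counts[usable, , drop = FALSE]
      fold_n <- fold_n[usable]
      valid <- !apply(is.na(err_counts), 2, any)
      if (!any(valid)) stop("no PC-count candidate feasible in every inner fold")
      pooled <- colSums(err_counts) / sum(fold_n)
      inner_err <- ifelse(valid, pooled, Inf)
      j_star <- which(inner_err == min(inner_err))[1]
      # one-SE rule, with the SE taken across inner animals (cluster unit)
      rates <- err_counts[, j_star] / fold_n
      se <- if (length(rates) > 1) stats::sd(rates) / sqrt(length(rates)) else 0
      ok <- valid & pooled <= inner_err[j_star] + se
      chosen <- min(pc_grid[ok])
      pca <- fit_pca(X[tr_rows, , drop = FALSE], rank. = chosen)
      S_tr <- project_pca(pca, X[tr_rows, , drop = FALSE], chosen)
      S_te <- project_pca(pca, X[test_rows, , drop = FALSE], chosen)
      cls <- fit_fisher(S_tr, y[tr_rows])
      preds[test_rows] <- predict(cls, S_te)
      folds[[a]] <- list(chosen_pcs = chosen, w = cls$w, b = cls$b,
                         orientation = cls$orientation,
                         inner_error = inner_err)
    } else {
      imp_tr <- impute_features(X[tr_rows, , drop = FALSE])
      imp_te <- impute_features(X[test_rows, , drop = FALSE], imp_tr$stats)
      cls <- fit_fisher(imp_tr$X, y[tr_rows])
      preds[test_rows] <- predict(cls, imp_te$X)
      folds[[a]] <- list(chosen_pcs = NA_integer_, w = cls$w, b = cls$b,
                         orientation = cls$orientation,
                         impute_stats = imp_tr$stats)
    }
  }
  votes <- vapply(animals, function(a) {
    p <- preds[anim == a]
    n_hy <- sum(p == "HYPO")
    if (n_hy > length(p) / 2) "HYPO" else if (n_hy < length(p) / 2) "WT"
    else "WT"                                  # vote tie -> WT
  }, "")
  chosen_pcs <- vapply(folds, function(f) as.integer(f$chosen_pcs %||% NA), 1L)
  modal_pcs <- if (all(is.na(chosen_pcs))) NA_integer_ else {
    tab <- table(chosen_pcs)
    as.integer(names(tab)[order(-tab, as.integer(names(tab)))[1]])
  }
  structure(list(kind = kind, k = k, error = mean(preds != y),
                 n_samples = length(y), chosen_pcs = chosen_pcs,
                 n_pcs = modal_pcs,
                 predictions = data.frame(animal_id = anim, genotype = y,
                                          predicted = preds,
                                          stringsAsFactors = FALSE),
                 votes = data.frame(animal_id = animals,
                                    genotype = geno_by_animal,
                                    vote = votes, stringsAsFactors = FALSE),
                 folds = folds),
            class = "cv_cell")
}

#' @export
print.cv_cell <- function(x, ...) {
  cat(sprintf("<cv_cell> %s, k=%d: aggregate error %.1f%% (%d samples)%s\n",
              x$kind, x$k, 100 * x$error, x$n_samples,
              if (!is.na(x$n_pcs)) sprintf(", modal n_pcs %d", x$n_pcs) else ""))
  invisible(x)
}

#' Classification error across trial-averaging levels and feature families
#'
#' Runs [loo_genotype_cv()] over the full grid of block sizes and feature
#' kinds, mirroring the error-versus-averaging comparison of peak features
#' (single channel and multi channel) against waveform principal
#' components.
#'
#' @param ep_list List of artifact-rejected single-trial `epoch_set`s.
#' @param kinds Feature families to evaluate.
#' @param k_grid Trial-average block sizes.
#' @param pc_grid Candidate PC counts for the PC family.
#' @param channels Multi-channel set.
#' @param window_ms Analysis window.
#' @return A `cv_report`: a data frame with columns `k`, `feature_kind`,
#'   `n_pcs`, `n_samples`, `error`, carrying the per-cell details in
#'   `attr(, "cells")`.
#' @export
error_vs_averaging <- function(ep_list, kinds = FEATURE_KINDS,
                               k_grid = c(1, 2, 4, 8, 16, 32),
                               pc_grid = default_pc_grid(),
                               channels = CLASSIFY_CHANNELS,
                               window_ms = c(0, 250)) {
  cells <- list()
  rows <- list()
  for (k in k_grid) for (kind in kinds) {
    cell <- loo_genotype_cv(ep_list, kind, k, pc_grid, channels, window_ms)
    cells[[paste(kind, k, sep = "_")]] <- cell
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, feature_kind = kind, n_pcs = cell$n_pcs,
      n_samples = cell$n_samples, error = cell$error,
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  attr(rep, "cells") <- cells
  class(rep) <- c("cv_report", "data.frame")
  rep
}

#' Write a cross-validation report
#'
#' The grid table goes to CSV; per-animal votes and chosen PC counts to a
#' JSON summary alongside.
#'
#' @param report A `cv_report`.
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON summary path.
#' @return `csv_path`, invisibly.
#' @export
write_cv_report <- function(report, csv_path, json_path = NULL) {
  write.table(as.data.frame(report), csv_path, sep = ",", quote = FALSE,
              row.names = FALSE)
  if (!is.null(json_path)) {
    cells <- attr(report, "cells")
    summ <- lapply(cells, function(cell)
      list(kind = cell$kind, k = cell$k, error = cell$error,
           n_samples = cell$n_samples, n_pcs = cell$n_pcs,
           chosen_pcs = as.list(cell$chosen_pcs),
           votes = cell$votes))
    writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA,
                                na = "null", pretty = TRUE), json_path)
  }
  invisible(csv_path)
}
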