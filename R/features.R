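#' Feature matrix container
#'
#' Rows are samples (single trials or k-trial block averages), columns are
#' features; row-parallel animal and genotype labels make the matrix
#' directly consumable by the classifier and cross-validation.
#'
#' @param X Numeric matrix (may contain `NA` for invalid peak components
#'   before imputation).
#' @param animal_id,genotype Per-row labels.
#' @param kind One of `"peaks_single"`, `"peaks_multi"`, `"waveform"`,
#'   `"pc"`.
#' @param channels Channel order defining the columns.
#' @param window_ms Analysis window.
#' @param n_pcs For `kind = "pc"`, the number of components.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(X, animal_id, genotype, kind, channels,
                           window_ms = c(0, 250), n_pcs = NA_integer_) {
  stopifnot(nrow(X) == length(animal_id), nrow(X) == length(genotype))
  structure(list(X = X, animal_id = animal_id, genotype = genotype,
                 kind = kind, channels = channels, window_ms = window_ms,
                 n_pcs = n_pcs),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> kind=%s: %d samples x %d features (%d animals)\n",
              x$kind, nrow(x$X), ncol(x$X), length(unique(x$animal_id))))
  invisible(x)
}

#' Bind feature matrices of several animals
#' @param fms List of `feature_matrix` objects with identical descriptors.
#' @return A single `feature_matrix`.
#' @export
rbind_features <- function(fms) {
  stopifnot(length(fms) >= 1)
  kinds <- unique(vapply(fms, `[[`, "", "kind"))
  stopifnot(length(kinds) == 1)
  feature_matrix(do.call(rbind, lapply(fms, `[[`, "X")),
                 unlist(lapply(fms, `[[`, "animal_id")),
                 unlist(lapply(fms, `[[`, "genotype")),
                 kinds, fms[[1]]$channels, fms[[1]]$window_ms,
                 fms[[1]]$n_pcs)
}

# Indices of the (0,250)-style half-open analysis window on a time axis.
window_index <- function(time_ms, window_ms) {
  sel <- which(time_ms >= window_ms[1] & time_ms < window_ms[2])
  if (length(sel) == 0) stop("analysis window outside the epoch extent")
  sel
}

#' Detect the first three ERP peak components (N1, P1, N2)
#'
#' The waveform is smoothed with a centered moving average (default 5 ms)
#' and its local extrema located in time order; extrema alternate between
#' minima and maxima by construction, and the first three fill the
#' canonical N1 (negative), P1 (positive), N2 (negative) slots: a first
#' extremum that is a minimum starts at N1, a first maximum starts at P1.
#' The reported amplitude is the signed raw (unsmoothed) value at the
#' extremum sample and the latency its time; a slot is flagged invalid if
#' no extremum fills it or if the raw amplitude contradicts the slot's
#' polarity.
#'
#' @param x Single-channel waveform over the analysis window.
#' @param fs_hz Sampling rate.
#' @param time_ms Time axis (defaults to `0, 1, ...` ms at `fs_hz`).
#' @param smooth_ms Moving-average width in ms.
#' @return A `data.frame` with rows N1, P1, N2 and columns `label`,
#'   `latency_ms`, `amplitude_uV`, `valid`.
#' @export
detect_peak_components <- function(x, fs_hz, time_ms = NULL, smooth_ms = 5) {
  w <- max(1L, as.integer(round(smooth_ms * fs_hz / 1000)))
  if (length(x) < w)
    stop("waveform shorter than the smoothing width")
  if (is.null(time_ms)) time_ms <- (seq_along(x) - 1) * 1000 / fs_hz
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  peaks_from_smoothed(x, s, time_ms)
}

# Shared extremum-selection core (x raw, s smoothed with NA edges).
peaks_from_smoothed <- function(x, s, time_ms) {
  out <- data.frame(label = c("N1", "P1", "N2"),
                    latency_ms = NA_real_, amplitude_uV = NA_real_,
                    valid = FALSE, stringsAsFactors = FALSE)
  ok <- which(!is.na(s))
  if (length(ok) < 3) return(out)
  sv <- s[ok]
  d <- sign(diff(sv))
  ks <- which(d != 0)                     # drop flat steps (plateaus)
  if (length(ks) < 2) return(out)
  dd <- d[ks]
  turns <- which(dd[-length(dd)] != dd[-1])
  if (length(turns) == 0) return(out)
  ext_idx <- ok[ks[turns] + 1L]           # sample at the end of the last rising/falling step
  ext_type <- ifelse(dd[turns] > 0, "max", "min")
  slots <- if (ext_type[1] == "min") c("N1", "P1", "N2") else c("P1", "N2")
  for (i in seq_len(min(length(slots), length(ext_idx)))) {
    slot <- slots[i]
    j <- match(slot, out$label)
    amp <- x[ext_idx[i]]
    sign_ok <- if (startsWith(slot, "N")) amp <= 0 else amp >= 0
    # slot/extremum type must agree too (N = minimum, P = maximum)
    type_ok <- (startsWith(slot, "N") && ext_type[i] == "min") ||
      (startsWith(slot, "P") && ext_type[i] == "max")
    if (type_ok) {
      out$latency_ms[j] <- time_ms[ext_idx[i]]
      out$amplitude_uV[j] <- amp
      out$valid[j] <- sign_ok
      if (!sign_ok) {
        out$latency_ms[j] <- NA_real_
        out$amplitude_uV[j] <- NA_real_
      }
    }
  }
  out
}

# Vectorized peak features for many waveforms: X is time x m; returns a
# 6 x m matrix (N1.lat, N1.amp, P1.lat, P1.amp, N2.lat, N2.amp) with NA
# for invalid components.
detect_peaks_many <- function(X, fs_hz, time_ms, smooth_ms = 5) {
  w <- max(1L, as.integer(round(smooth_ms * fs_hz / 1000)))
  if (nrow(X) < w) stop("waveform shorter than the smoothing width")
  S <- stats::filter(X, rep(1 / w, w), sides = 2)
  out <- matrix(NA_real_, nrow = 6, ncol = ncol(X))
  for (m in seq_len(ncol(X))) {
    p <- peaks_from_smoothed(X[, m], S[, m], time_ms)
    out[, m] <- c(p$latency_ms[1], p$amplitude_uV[1],
                  p$latency_ms[2], p$amplitude_uV[2],
                  p$latency_ms[3], p$amplitude_uV[3])
  }
  out
}

#' Peak-component feature matrix
#'
#' Six features per channel — latency and signed amplitude of N1, P1 and
#' N2 detected within the analysis window — for every retained epoch.
#' Invalid components are left `NA`; impute with [impute_features()]
#' (inside cross-validation the imputation statistics come from the
#' training partition only).
#'
#' @param epochs An `epoch_set`.
#' @param channels Channel labels to use (subset of the epoch channels).
#' @param window_ms Analysis window (half-open).
#' @param smooth_ms Moving-average width for peak detection.
#' @return A `feature_matrix` of kind `peaks_single` (one channel) or
#'   `peaks_multi`.
#' @export
build_peak_feature_matrix <- function(epochs, channels,
                                      window_ms = c(0, 250), smooth_ms = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(channels) == 0) stop("empty channel list")
  missing_ch <- setdiff(channels, epochs$channels)
  if (length(missing_ch))
    stop("channel(s) not in epochs: ", paste(missing_ch, collapse = ", "))
  sel <- window_index(epochs$time_ms, window_ms)
  t_win <- epochs$time_ms[sel]
  idx <- which(epochs$mask)
  ne <- length(idx)
  blocks <- lapply(channels, function(ch) {
    ci <- match(ch, epochs$channels)
    W <- t(epochs$data[idx, ci, sel, drop = FALSE][, 1, ])  # time x epochs
    if (ne == 1) W <- matrix(epochs$data[idx, ci, sel], ncol = 1)
    F6 <- detect_peaks_many(W, epochs$fs_hz, t_win, smooth_ms)
    B <- t(F6)
    colnames(B) <- paste0(ch, ".", c("N1.lat", "N1.amp", "P1.lat",
                                     "P1.amp", "N2.lat", "N2.amp"))
    B
  })
  X <- do.call(cbind, blocks)
  kind <- if (length(channels) == 1) "peaks_single" else "peaks_multi"
  feature_matrix(X, rep(epochs$animal_id, ne), rep(epochs$genotype, ne),
                 kind, channels, window_ms)
}

#' Impute invalid peak features by column means
#'
#' `NA` cells are filled with the per-column mean over valid entries,
#' computed either from the matrix itself or from supplied training-
#' partition statistics. Rows are never dropped.
#'
#' @param fm A `feature_matrix` (or plain matrix).
#' @param stats Optional column means from a training partition; when
#'   `NULL` they are computed from `fm` and returned.
#' @return List with `X` (complete matrix) and `stats` (column means
#'   used).
#' @export
impute_features <- function(fm, stats = NULL) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else fm
  if (is.null(stats)) {
    stats <- colMeans(X, na.rm = TRUE)
    stats[!is.finite(stats)] <- 0       # column with no valid entry at all
  }
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- stats[nas[, 2]]
  list(X = X, stats = stats)
}

#' Concatenated multi-channel waveform feature matrix
#'
#' Each retained epoch becomes one row: the channel waveforms cropped to
#' the half-open analysis window and concatenated in the declared channel
#' order (independent of storage order). At 1 kHz, 5 channels and
#' (0, 250) ms this gives 1250 columns.
#'
#' @inheritParams build_peak_feature_matrix
#' @return A `feature_matrix` of kind `waveform`.
#' @export
build_waveform_feature_matrix <- function(epochs, channels,
                                          window_ms = c(0, 250)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(channels) == 0) stop("empty channel list")
  missing_ch <- setdiff(channels, epochs$channels)
  if (length(missing_ch))
    stop("channel(s) not in epochs: ", paste(missing_ch, collapse = ", "))
  sel <- window_index(epochs$time_ms, window_ms)
  idx <- which(epochs$mask)
  blocks <- lapply(channels, function(ch) {
    ci <- match(ch, epochs$channels)
    M <- epochs$data[idx, ci, sel, drop = FALSE]
    dim(M) <- c(length(idx), length(sel))
    colnames(M) <- paste0(ch, ".t", seq_along(sel))
    M
  })
  X <- do.call(cbind, blocks)
  feature_matrix(X, rep(epochs$animal_id, length(idx)),
                 rep(epochs$genotype, length(idx)),
                 "waveform", channels, window_ms)
}
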