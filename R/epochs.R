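#' Stimulus-locked epoch stack
#'
#' @param data 3-D numeric array, epochs x channels x time (microvolts).
#' @param time_ms Time axis in ms relative to stimulus onset.
#' @param channels Channel labels.
#' @param trial_index Original event index of each epoch.
#' @param mask Logical retention mask (length = n epochs).
#' @param fs_hz Sampling rate.
#' @param animal_id,genotype Metadata.
#' @param window_ms The extraction window.
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, channels, trial_index, mask, fs_hz,
                      animal_id = NA_character_, genotype = NA_character_,
                      window_ms = range(time_ms)) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channels),
            dim(data)[3] == length(time_ms),
            length(mask) == dim(data)[1],
            length(trial_index) == dim(data)[1])
  structure(list(data = data, time_ms = time_ms, channels = channels,
                 trial_index = as.integer(trial_index), mask = mask,
                 fs_hz = fs_hz, animal_id = animal_id, genotype = genotype,
                 window_ms = window_ms),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s (%s): %d epochs (%d retained) x %d ch x %d samples, [%g, %g) ms\n",
              x$animal_id, x$genotype, dim(x$data)[1], sum(x$mask),
              length(x$channels), length(x$time_ms),
              x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Number of retained epochs
#' @param epochs An `epoch_set`.
#' @return Integer count.
#' @export
n_retained <- function(epochs) sum(epochs$mask)

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per event using the half-open sample convention
#' `[start, end)`: at 1 kHz a (-500, 500) ms window yields exactly 1000
#' samples with t = 0 included. Events whose full window does not fit in
#' the recording are dropped (and reported via a message).
#'
#' @param rec An `erp_recording`.
#' @param window_ms `c(start, end)` in ms relative to onset, start < end.
#' @param baseline If `TRUE`, subtract each epoch's per-channel mean over
#'   the pre-stimulus samples (t < 0). Off by default.
#' @return An `epoch_set` with all epochs retained. Zero usable events
#'   produce an empty set with a warning.
#' @export
extract_epochs <- function(rec, window_ms = c(-500, 500), baseline = FALSE) {
  stopifnot(inherits(rec, "erp_recording"), window_ms[1] < window_ms[2])
  fs <- rec$fs_hz
  s0 <- as.integer(round(window_ms[1] * fs / 1000))
  s1 <- as.integer(round(window_ms[2] * fs / 1000))
  rel <- s0:(s1 - 1L)
  time_ms <- rel * 1000 / fs
  n <- nrow(rec$signals)
  ok <- (rec$onsets + s0 >= 1L) & (rec$onsets + s1 - 1L <= n)
  dropped <- sum(!ok)
  if (dropped > 0)
    message(dropped, " event(s) dropped: window truncated by recording bounds")
  onsets <- rec$onsets[ok]
  nc <- ncol(rec$signals)
  if (length(onsets) == 0) {
    warning("no events with a complete epoch window")
    dat <- array(0, dim = c(0, nc, length(rel)))
    return(epoch_set(dat, time_ms, colnames(rec$signals), integer(),
                     logical(), fs, rec$animal_id, rec$genotype, window_ms))
  }
  idx <- outer(onsets, rel, "+")          # epochs x time sample indices
  dat <- array(0, dim = c(length(onsets), nc, length(rel)))
  for (c in seq_len(nc)) dat[, c, ] <- rec$signals[, c][idx]
  if (baseline) {
    pre <- time_ms < 0
    if (any(pre)) {
      bl <- apply(dat[, , pre, drop = FALSE], c(1, 2), mean)
      dat <- dat - array(bl, dim = dim(dat))
    }
  }
  ep <- epoch_set(dat, time_ms, colnames(rec$signals), which(ok),
                  rep(TRUE, length(onsets)), fs, rec$animal_id,
                  rec$genotype, window_ms)
  attr(ep, "n_dropped") <- dropped
  ep
}

#' Reject epochs with extreme amplitudes
#'
#' Masks out every epoch containing any sample whose absolute value is
#' strictly greater than the threshold (default 1000 uV, i.e. the 1 mV
#' rule; an excursion of exactly 1000 uV is retained). The mask is
#' monotone: already-rejected epochs are never unmasked.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uV Positive rejection threshold.
#' @return The `epoch_set` with an updated mask.
#' @export
reject_artifacts <- function(epochs, threshold_uV = 1000) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uV > 0)
  if (dim(epochs$data)[1] == 0) return(epochs)
  peak <- apply(abs(epochs$data), 1, max)
  epochs$mask <- epochs$mask & (peak <= threshold_uV)
  epochs
}

#' Average consecutive blocks of k retained epochs
#'
#' Retained epochs are grouped, in trial order, into consecutive
#' non-overlapping blocks of `k`; each output epoch is the sample-wise
#' block mean; a trailing remainder of fewer than `k` epochs is discarded.
#'
#' @param epochs An artifact-rejected `epoch_set`.
#' @param k Block size (>= 1); `k = 1` returns the retained epochs
#'   unchanged.
#' @return An `epoch_set` of block averages (all retained). If fewer than
#'   `k` epochs are retained the result is empty, with a warning.
#' @export
block_average <- function(epochs, k) {
  stopifnot(inherits(epochs, "epoch_set"), k >= 1)
  k <- as.integer(k)
  idx <- which(epochs$mask)
  nb <- length(idx) %/% k
  d <- dim(epochs$data)
  if (nb == 0) {
    if (k > 1 || length(idx) == 0)
      warning("fewer retained epochs (", length(idx), ") than block size ", k)
    dat <- array(0, dim = c(0, d[2], d[3]))
    return(epoch_set(dat, epochs$time_ms, epochs$channels, integer(),
                     logical(), epochs$fs_hz, epochs$animal_id,
                     epochs$genotype, epochs$window_ms))
  }
  use <- idx[seq_len(nb * k)]
  arr <- epochs$data[use, , , drop = FALSE]
  dim(arr) <- c(k, nb, d[2], d[3])
  avg <- colMeans(arr, dims = 1)          # nb x channels x time
  epoch_set(avg, epochs$time_ms, epochs$channels,
            epochs$trial_index[idx[seq(1, nb * k, by = k)]],
            rep(TRUE, nb), epochs$fs_hz, epochs$animal_id,
            epochs$genotype, epochs$window_ms)
}

#' Grand-average waveform
#'
#' Sample-wise mean over all retained epochs, per channel.
#'
#' @param epochs An `epoch_set` with at least one retained epoch.
#' @return Numeric matrix, channels x time, with channel labels as
#'   rownames.
#' @export
grand_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$mask)
  if (length(idx) == 0) stop("grand_average: no retained epochs")
  ga <- colMeans(epochs$data[idx, , , drop = FALSE], dims = 1)
  rownames(ga) <- epochs$channels
  ga
}
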