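# Minimal EDF (European Data Format) continuous-signal container support:
# 16-bit samples, identical sampling rate across signals, 1-second data
# records, physical units microvolts. This covers exactly what the
# acquisition model needs; it is not a general-purpose EDF library.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = width, flag = "-")
}

# Physical range giving an exact 0.1 uV quantization step on the 16-bit
# digital range [-32768, 32767].
EDF_PHYS_MIN <- -3276.8
EDF_PHYS_MAX <- 3276.7

#' Write a multi-channel signal matrix as EDF
#'
#' 16-bit EDF with 1-second data records; the final record is zero-padded
#' (readers should truncate using externally stored sample counts, as
#' [save_recording()] / [load_recording()] do). The fixed physical range
#' (-3276.8, 3276.7) uV gives a quantization step of exactly 0.1 uV.
#'
#' @param signals Numeric matrix, samples x channels, microvolts.
#' @param fs_hz Sampling rate (integer Hz).
#' @param path Output file.
#' @param patient,recording_id Free-text header fields.
#' @return `path`, invisibly. Errors if any sample exceeds the physical
#'   range (no silent clipping).
#' @export
write_edf <- function(signals, fs_hz, path, patient = "X", recording_id = "X") {
  signals <- as.matrix(signals)
  labels <- colnames(signals)
  if (is.null(labels)) stop("signal matrix must have channel labels as colnames")
  if (min(signals) < EDF_PHYS_MIN || max(signals) > EDF_PHYS_MAX)
    stop("signal exceeds the EDF physical range [", EDF_PHYS_MIN, ", ",
         EDF_PHYS_MAX, "] uV; refusing to clip")
  fs <- as.integer(fs_hz)
  if (fs != fs_hz) stop("write_edf requires an integer sampling rate")
  n <- nrow(signals); nc <- ncol(signals)
  n_rec <- as.integer(ceiling(n / fs))
  dig <- matrix(0L, nrow = n_rec * fs, ncol = nc)
  dig[seq_len(n), ] <- as.integer(round((signals - EDF_PHYS_MIN) /
                                          ADC_STEP_UV)) - 32768L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.01", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (nc + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(nc, 4),
    paste(vapply(labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), nc), collapse = ""),
    paste(rep(edf_pad("uV", 8), nc), collapse = ""),
    paste(rep(edf_pad(EDF_PHYS_MIN, 8), nc), collapse = ""),
    paste(rep(edf_pad(EDF_PHYS_MAX, 8), nc), collapse = ""),
    paste(rep(edf_pad(-32768L, 8), nc), collapse = ""),
    paste(rep(edf_pad(32767L, 8), nc), collapse = ""),
    paste(rep(edf_pad("HP:0.1Hz", 80), nc), collapse = ""),
    paste(rep(edf_pad(fs, 8), nc), collapse = ""),
    paste(rep(edf_pad("", 32), nc), collapse = ""))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  # record-major layout: for each record, each signal's fs samples
  dim(dig) <- NULL
  arr <- array(dig, dim = c(fs, n_rec, nc))
  arr <- aperm(arr, c(1, 3, 2))
  writeBin(as.integer(arr), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any single-rate 16-bit EDF)
#'
#' @param path EDF file path.
#' @return List with `signals` (samples x channels matrix, physical units),
#'   `fs_hz`, `labels`, `n_records`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)                     # transducer
  dims <- vapply(seq_len(nc), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(80)                     # prefiltering
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1)
    stop("EDF with mixed per-signal sampling rates is not supported")
  fs <- spr[1] / rec_dur
  if (fs != round(fs)) stop("non-integer sampling rate in EDF")
  raw <- readBin(con, integer(), n = n_rec * nc * spr[1], size = 2,
                 endian = "little")
  arr <- array(raw, dim = c(spr[1], nc, n_rec))
  arr <- aperm(arr, c(1, 3, 2))
  dim(arr) <- c(spr[1] * n_rec, nc)
  step <- (pmax - pmin) / (dmax - dmin)
  sig <- sweep(sweep(arr, 2, dmin, "-"), 2, step, "*")
  sig <- sweep(sig, 2, pmin, "+")
  colnames(sig) <- labels
  list(signals = sig, fs_hz = as.integer(fs), labels = labels,
       n_records = n_rec)
}
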