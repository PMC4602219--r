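#' Electrode montage
#'
#' Stereotaxic electrode layout: coordinates in mm relative to bregma,
#' anterior-positive AP, right-positive ML.
#'
#' @param label Channel labels (unique).
#' @param ap_mm,ml_mm Coordinates in mm.
#' @param kind One of `"eeg"`, `"reference"`, `"emg"` per entry.
#' @return A `data.frame` of class `montage`.
#' @export
montage <- function(label, ap_mm, ml_mm, kind = "eeg") {
  if (anyDuplicated(label)) stop("montage labels must be unique")
  kind <- rep_len(kind, length(label))
  if (!all(kind %in% c("eeg", "reference", "emg")))
    stop("montage kind must be eeg, reference or emg")
  df <- data.frame(label = as.character(label), ap_mm = as.numeric(ap_mm),
                   ml_mm = as.numeric(ml_mm), kind = kind,
                   stringsAsFactors = FALSE)
  class(df) <- c("montage", "data.frame")
  df
}

#' Default epidural montage
#'
#' Six bilateral EEG electrodes (frontal +/-1.0 ML at +1.0 AP; parietal
#' +/-1.5 ML at -1.0 AP; occipital +/-2.0 ML at -3.5 AP) and a midline
#' reference over the cerebellum (0.0 ML, -6.0 AP). Left hemisphere is
#' negative ML.
#'
#' @return A [montage()].
#' @export
default_montage <- function() {
  montage(label = c("FL", "FR", "PL", "PR", "OL", "OR", "REF"),
          ap_mm = c(1, 1, -1, -1, -3.5, -3.5, -6),
          ml_mm = c(-1, 1, -1.5, 1.5, -2, 2, 0),
          kind = c(rep("eeg", 6), "reference"))
}

#' Write / read a montage as JSON
#'
#' @param m A [montage()].
#' @param path File path.
#' @return `write_montage` returns `path` invisibly; `read_montage` the
#'   `montage`.
#' @export
write_montage <- function(m, path) {
  json <- jsonlite::toJSON(as.data.frame(unclass(m)), dataframe = "rows",
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  d <- jsonlite::fromJSON(path)
  montage(d$label, d$ap_mm, d$ml_mm, d$kind)
}
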