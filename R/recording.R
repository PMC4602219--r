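#' Continuous recording container
#'
#' A continuous multi-channel signal (microvolts end-to-end), stimulus
#' event onsets in samples (1-based, authoritative; seconds are always
#' derived), and animal metadata.
#'
#' @param fs_hz Sampling rate in Hz.
#' @param signals Numeric matrix, samples x channels, with channel labels
#'   as `colnames`.
#' @param onsets Integer vector of stimulus onset samples, strictly
#'   increasing, within the signal bounds.
#' @param animal_id,genotype,sex,session Metadata; `genotype` must be
#'   `"WT"`, `"HYPO"` or `NA`.
#' @return An `erp_recording`.
#' @export
recording <- function(fs_hz, signals, onsets, animal_id = NA_character_,
                      genotype = NA_character_, sex = NA_character_,
                      session = NA_character_) {
  signals <- as.matrix(signals)
  if (is.null(colnames(signals))) stop("signals must carry channel labels")
  onsets <- as.integer(onsets)
  if (length(onsets) && any(diff(onsets) <= 0))
    stop("event onsets must be strictly increasing")
  if (length(onsets) && (min(onsets) < 1 || max(onsets) > nrow(signals)))
    stop("event onsets fall outside the recorded signal")
  if (!is.na(genotype) && !genotype %in% GENOTYPES)
    stop("unknown genotype: ", genotype)
  structure(list(fs_hz = fs_hz, signals = signals, onsets = onsets,
                 animal_id = animal_id, genotype = genotype, sex = sex,
                 session = session),
            class = "erp_recording")
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf("<erp_recording> %s (%s), %d ch x %d samples @ %g Hz, %d events\n",
              x$animal_id, x$genotype, ncol(x$signals), nrow(x$signals),
              x$fs_hz, length(x$onsets)))
  invisible(x)
}

#' File layout for one saved recording
#'
#' @param dir Directory.
#' @param basename Stem, typically the animal id.
#' @return Named list of paths: `edf`, `events`, `montage`, `meta`.
#' @export
recording_paths <- function(dir, basename) {
  list(edf = file.path(dir, paste0(basename, ".edf")),
       events = file.path(dir, paste0(basename, "_events.tsv")),
       montage = file.path(dir, paste0(basename, "_montage.json")),
       meta = file.path(dir, paste0(basename, "_meta.json")))
}

write_events_tsv <- function(onsets, fs_hz, path, label = "click") {
  df <- data.frame(onset_sample = as.integer(onsets),
                   onset_s = sprintf("%.6f", (as.integer(onsets) - 1) / fs_hz),
                   label = rep_len(label, length(onsets)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_sample", "onset_s", "label") %in% names(df)))
    stop("events TSV must have columns onset_sample, onset_s, label")
  if (nrow(df) && any(diff(df$onset_sample) <= 0))
    stop("event onsets in ", path, " are not strictly increasing")
  df
}

#' Save a recording to disk
#'
#' Signals go to 16-bit EDF (fixed physical range giving a 0.1 uV step),
#' events to TSV (`onset_sample` authoritative, `onset_s` derived,
#' `label`), the montage to JSON, and metadata (animal id, genotype, sex,
#' exact sample count for un-padding the final EDF record) to JSON.
#'
#' @param rec An `erp_recording`.
#' @param paths A [recording_paths()] list (or any list with `edf`,
#'   `events`, `montage`, `meta` entries).
#' @param mont The [montage()] to store; every channel label in the
#'   recording must appear in it.
#' @return `paths`, invisibly.
#' @export
save_recording <- function(rec, paths, mont = default_montage()) {
  stopifnot(inherits(rec, "erp_recording"))
  missing_ch <- setdiff(colnames(rec$signals), mont$label)
  if (length(missing_ch))
    stop("channel(s) absent from montage: ", paste(missing_ch, collapse = ", "))
  write_edf(rec$signals, rec$fs_hz, paths$edf,
            patient = paste(rec$animal_id, rec$genotype, rec$sex))
  write_events_tsv(rec$onsets, rec$fs_hz, paths$events)
  write_montage(mont, paths$montage)
  meta <- list(animal_id = rec$animal_id, genotype = rec$genotype,
               sex = rec$sex, session = rec$session,
               n_samples = nrow(rec$signals), fs_hz = rec$fs_hz)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), paths$meta)
  invisible(paths)
}

#' Load a recording saved by [save_recording()]
#'
#' Validates mutual consistency: the events and montage sidecars must
#' exist, every EDF channel label must appear in the montage, and onsets
#' must be strictly increasing and inside the signal.
#'
#' @param paths A [recording_paths()] list.
#' @return An `erp_recording`, with the montage attached as attribute
#'   `"montage"`.
#' @export
load_recording <- function(paths) {
  edf <- read_edf(paths$edf)
  mont <- read_montage(paths$montage)
  ev <- read_events_tsv(paths$events)
  unknown <- setdiff(edf$labels, mont$label)
  if (length(unknown))
    stop("EDF channel label(s) not in montage: ", paste(unknown, collapse = ", "))
  meta <- if (file.exists(paths$meta)) jsonlite::fromJSON(paths$meta) else list()
  sig <- edf$signals
  if (!is.null(meta$n_samples) && meta$n_samples <= nrow(sig))
    sig <- sig[seq_len(meta$n_samples), , drop = FALSE]
  rec <- recording(fs_hz = edf$fs_hz, signals = sig,
                   onsets = ev$onset_sample,
                   animal_id = meta$animal_id %||% NA_character_,
                   genotype = meta$genotype %||% NA_character_,
                   sex = meta$sex %||% NA_character_,
                   session = meta$session %||% NA_character_)
  attr(rec, "montage") <- mont
  rec
}

#' Save a cohort (recordings + manifest TSV)
#'
#' @param cohort A [simulate_cohort()] result (or compatible list).
#' @param dir Output directory (created if needed).
#' @param mont Montage stored with every recording.
#' @return The manifest path, invisibly.
#' @export
save_cohort <- function(cohort, dir, mont = default_montage()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- cohort$manifest
  rows <- lapply(seq_len(nrow(mf)), function(i) {
    rec <- cohort$recordings[[mf$animal_id[i]]]
    p <- recording_paths(dir, mf$animal_id[i])
    save_recording(rec, p, mont)
    data.frame(animal_id = mf$animal_id[i], genotype = mf$genotype[i],
               sex = mf$sex[i], edf_path = basename(p$edf),
               events_path = basename(p$events), stringsAsFactors = FALSE)
  })
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}

#' Load a cohort from a manifest TSV
#'
#' Paths in the manifest are resolved relative to the manifest's
#' directory. Genotype strings must be `WT` or `HYPO`; duplicate animal
#' ids are an error; an empty manifest yields an empty list with a
#' warning.
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @return List of `erp_recording` in manifest order.
#' @export
load_cohort <- function(manifest_path) {
  mf <- read.delim(manifest_path, stringsAsFactors = FALSE)
  if (nrow(mf) == 0) {
    warning("empty cohort manifest: ", manifest_path)
    return(list())
  }
  if (anyDuplicated(mf$animal_id))
    stop("duplicate animal_id in manifest: ",
         paste(unique(mf$animal_id[duplicated(mf$animal_id)]), collapse = ", "))
  bad <- setdiff(unique(mf$genotype), GENOTYPES)
  if (length(bad))
    stop("unknown genotype in manifest: ", paste(bad, collapse = ", "))
  dir <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(mf)), function(i) {
    base <- sub("\\.edf$", "", mf$edf_path[i])
    load_recording(recording_paths(dir, base))
  })
  names(recs) <- mf$animal_id
  recs
}
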