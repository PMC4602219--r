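# EDF/ADC quantization step used throughout (uV); see save_recording().
ADC_STEP_UV <- 0.1

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Pink (1/f^beta) background noise
#'
#' White Gaussian noise spectrally shaped to a 1/f^beta power spectrum with
#' content below `lowcut_hz` zeroed (emulating the acquisition low-cut
#' filter), then rescaled so the realized sample SD equals `sd_uV`.
#'
#' @param n Number of samples.
#' @param fs_hz Sampling rate.
#' @param sd_uV Target sample SD in microvolts.
#' @param beta Spectral exponent (power ~ 1/f^beta); 0 gives white noise.
#' @param lowcut_hz High-pass corner below which spectral content is zeroed.
#' @return Numeric vector of length `n`. Draws from the current RNG stream.
#' @export
pink_noise <- function(n, fs_hz, sd_uV = 1, beta = 1, lowcut_hz = 0.1) {
  if (sd_uV == 0 || n < 2) return(numeric(n))
  # pad to a 2-3-5-smooth length for the FFT, then truncate
  np <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(np)
  f <- seq(0, np - 1) * fs_hz / np
  f <- pmin(f, fs_hz - f)           # two-sided frequency magnitude
  gain <- numeric(np)
  keep <- f >= lowcut_hz
  gain[keep] <- f[keep]^(-beta / 2)
  x <- Re(fft(fft(w) * gain, inverse = TRUE)) / np
  x <- x[seq_len(n)]
  x * (sd_uV / sd(x))
}

# Deterministic per-animal seed derived from the cohort seed (kept < 2^31).
animal_seed <- function(cohort_seed, index) {
  s <- (as.numeric(cohort_seed) %% 2147483647) + 1
  as.integer((1103515245 * (s + 7919 * index) + 12345) %% 2147483647)
}

#' Cohort layout implied by a configuration
#'
#' @param config A [default_config()]-style `synth_config`.
#' @return A `data.frame` with one row per animal: `animal_id`, `genotype`
#'   (`WT`/`HYPO`), `sex` (alternating F/M within genotype, so 9 animals per
#'   group give 5 female and 4 male), and the derived per-animal `seed`.
#' @export
cohort_manifest <- function(config) {
  n <- config$n_per_genotype
  if (n < 1) stop("n_per_genotype must be >= 1")
  geno <- rep(GENOTYPES, each = n)
  within_idx <- rep(seq_len(n), times = 2)
  data.frame(
    animal_id = c(sprintf("wt%02d", seq_len(n)), sprintf("hypo%02d", seq_len(n))),
    genotype = geno,
    sex = c("F", "M")[(within_idx + 1) %% 2 + 1],
    seed = animal_seed(config$seed, seq_len(2 * n)),
    stringsAsFactors = FALSE)
}

#' Simulate one animal's recording session
#'
#' Generates a continuous multi-channel epidural EEG record: per trial the
#' channel's evoked template (sum of Gaussian deflections, with the
#' genotype effect applied for hypomorphs) is added at the stimulus onset,
#' on top of 1/f^beta background noise; a per-animal multiplicative
#' amplitude factor (drawn once) models inter-animal variability, and a
#' random `artifact_prob` fraction of trials receives a large spike so the
#' amplitude rejection rule can be exercised. The result is quantized to
#' the 0.1 uV ADC step of the 16-bit acquisition model.
#'
#' @param config A `synth_config`.
#' @param genotype `"WT"` or `"HYPO"`.
#' @param animal_id Identifier string.
#' @param seed Integer seed for this animal's private RNG stream.
#' @param sex Optional `"F"`/`"M"` recorded in the metadata.
#' @return An `erp_recording` (see [recording()]).
#' @export
simulate_animal <- function(config, genotype, animal_id, seed = config$seed,
                            sex = NA_character_) {
  validate_synth_config(config)
  if (!genotype %in% GENOTYPES)
    stop("invalid genotype label: ", genotype, " (expected WT or HYPO)")
  fs <- config$sampling_rate_hz
  n_trials <- config$n_trials
  duration_s <- ceiling(n_trials * config$isi_s + 2)
  n <- as.integer(duration_s * fs)
  onsets <- as.integer(round((1 + (seq_len(n_trials) - 1) * config$isi_s) * fs)) + 1L
  channels <- names(config$channel_templates)
  # evoked kernel support: 0 .. 400 ms after onset covers all templates
  klen <- as.integer(round(0.4 * fs))
  kt_ms <- (seq_len(klen) - 1) * 1000 / fs

  with_local_seed(seed, {
    jitter <- 1 + rnorm(1, 0, config$animal_jitter_frac)
    trial_shift <- if (config$trial_jitter_sd_ms > 0)
      rnorm(n_trials, 0, config$trial_jitter_sd_ms) else numeric(n_trials)
    sig <- matrix(0, nrow = n, ncol = length(channels),
                  dimnames = list(NULL, channels))
    for (ci in seq_along(channels)) {
      tpl <- effective_templates(config, channels[ci], genotype)
      tpl$amplitude_uV <- tpl$amplitude_uV * jitter
      x <- pink_noise(n, fs, config$noise_sd_uV, config$noise_exponent,
                      config$lowcut_hz)
      if (config$trial_jitter_sd_ms > 0) {
        for (tr in seq_len(n_trials)) {
          kern <- template_waveform(tpl, kt_ms - trial_shift[tr])
          idx <- onsets[tr] + seq_len(klen) - 1L
          x[idx] <- x[idx] + kern
        }
      } else {
        kern <- template_waveform(tpl, kt_ms)
        for (tr in seq_len(n_trials)) {
          idx <- onsets[tr] + seq_len(klen) - 1L
          x[idx] <- x[idx] + kern
        }
      }
      sig[, ci] <- x
    }
    if (config$artifact_prob > 0) {
      hit <- runif(n_trials) < config$artifact_prob
      for (tr in which(hit)) {
        ch <- sample(length(channels), 1)
        off <- sample(seq(-400, 390) * fs / 1000, 1)   # inside (-500,500) ms
        amp <- config$artifact_amp_uV * sample(c(-1, 1), 1)
        idx <- onsets[tr] + as.integer(off) + 0:9
        sig[idx, ch] <- sig[idx, ch] + amp
      }
    }
    sig <- round(sig / ADC_STEP_UV) * ADC_STEP_UV
    recording(fs_hz = fs, signals = sig, onsets = onsets,
              animal_id = animal_id, genotype = genotype, sex = sex)
  })
}

#' Simulate a full cohort
#'
#' One recording per animal laid out by [cohort_manifest()], each generated
#' with its own deterministically derived seed.
#'
#' @param config A `synth_config`.
#' @return A list with `recordings` (list of `erp_recording`) and
#'   `manifest` (the [cohort_manifest()] data frame).
#' @export
simulate_cohort <- function(config) {
  mf <- cohort_manifest(config)
  recs <- lapply(seq_len(nrow(mf)), function(i)
    simulate_animal(config, mf$genotype[i], mf$animal_id[i],
                    seed = mf$seed[i], sex = mf$sex[i]))
  names(recs) <- mf$animal_id
  list(recordings = recs, manifest = mf)
}

#' Ground-truth per-channel effect pattern
#'
#' The signed integral over the (0, 250) ms analysis window of
#' (wild-type template - hypomorph template) for each channel, in uV*ms.
#' Channels whose templates are unaffected by the configured effect are
#' exactly zero. Serves as the validation oracle for discriminant spatial
#' maps.
#'
#' @param config A `synth_config`.
#' @param dt_ms Integration step (ms).
#' @return Named numeric vector, one entry per configured channel.
#' @export
true_effect_pattern <- function(config, dt_ms = 0.1) {
  t_ms <- seq(0, 250 - dt_ms, by = dt_ms)
  vapply(names(config$channel_templates), function(ch) {
    wt <- template_waveform(effective_templates(config, ch, "WT"), t_ms)
    hy <- template_waveform(effective_templates(config, ch, "HYPO"), t_ms)
    if (identical(effective_templates(config, ch, "WT"),
                  effective_templates(config, ch, "HYPO"))) return(0)
    sum(wt - hy) * dt_ms
  }, numeric(1))
}
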