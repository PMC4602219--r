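#' ERP component template
#'
#' One deflection of the evoked waveform, modeled as a Gaussian bump
#' `amplitude_uV * exp(-(t - latency_ms)^2 / (2 * width_ms^2))`.
#'
#' @param label One of `"N1"`, `"P1"`, `"N2"`.
#' @param latency_ms Time of the extremum, ms after stimulus onset, in
#'   `[0, 250)`.
#' @param width_ms Gaussian temporal SD in ms (> 0).
#' @param amplitude_uV Signed extremum amplitude in microvolts; negative for
#'   N components, positive for P components.
#' @return A one-row `data.frame` with the four fields.
#' @export
component_template <- function(label, latency_ms, width_ms, amplitude_uV) {
  label <- match.arg(label, c("N1", "P1", "N2"))
  stopifnot(width_ms > 0, latency_ms >= 0, latency_ms < 250)
  if (startsWith(label, "N") && amplitude_uV > 0)
    stop("N components must have non-positive amplitude in the template")
  if (startsWith(label, "P") && amplitude_uV < 0)
    stop("P components must have non-negative amplitude in the template")
  data.frame(label = label, latency_ms = latency_ms, width_ms = width_ms,
             amplitude_uV = amplitude_uV, stringsAsFactors = FALSE)
}

#' Genotype effect table
#'
#' Per (channel, component) alteration of the evoked template in the
#' hypomorph group: a unitless amplitude multiplier (negative values flip
#' polarity) and an additive latency shift in ms. Channels/components not
#' listed are unaffected (scale 1, shift 0).
#'
#' @param channel,component Character vectors (recycled to common length).
#' @param amplitude_scale,latency_shift_ms Numeric vectors.
#' @return A `data.frame` of class `genotype_effect`.
#' @export
genotype_effect <- function(channel = character(), component = character(),
                            amplitude_scale = numeric(),
                            latency_shift_ms = numeric()) {
  df <- data.frame(channel = as.character(channel),
                   component = as.character(component),
                   amplitude_scale = as.numeric(amplitude_scale),
                   latency_shift_ms = as.numeric(latency_shift_ms),
                   stringsAsFactors = FALSE)
  class(df) <- c("genotype_effect", "data.frame")
  df
}

#' Null (zero) genotype effect
#'
#' @return An empty effect table: all scales 1, all shifts 0.
#' @export
zero_genotype_effect <- function() genotype_effect()

#' Is a genotype effect the null effect?
#' @param effect A [genotype_effect()] table.
#' @return Logical.
#' @export
is_zero_effect <- function(effect) {
  nrow(effect) == 0L ||
    all(effect$amplitude_scale == 1 & effect$latency_shift_ms == 0)
}

scale_templates <- function(templates, amp_factor, latency_shift) {
  templates$amplitude_uV <- templates$amplitude_uV * amp_factor
  templates$latency_ms <- templates$latency_ms + latency_shift
  templates
}

#' Default simulation configuration
#'
#' The study-scale cohort: 18 animals (9 wild type, 9 hypomorphic), click
#' stimuli at 2.5 s inter-stimulus interval, 1100 trials per session,
#' 1 kHz sampling. Evoked templates are bilaterally symmetric with an
#' antero-posterior amplitude/latency gradient: frontal N1 (-30 uV, 25 ms,
#' 8 ms SD), P1 (+40 uV, 60 ms, 15 ms), N2 (-20 uV, 120 ms, 30 ms);
#' parietal = frontal x 0.7 shifted +5 ms; occipital = frontal x 0.5
#' shifted +10 ms. The planted hypomorph effect flips occipital N1
#' polarity (scale -0.8), attenuates frontal P1 (scale 0.7) and delays
#' frontal N1 by 10 ms. Background noise is 1/f pink noise (20 uV SD per
#' sample) with a 0.1 Hz low-cut; 2% of trials carry a 1500 uV artifact
#' spike so they trip the 1 mV rejection rule.
#'
#' @param ... Named fields overriding the defaults (e.g. `n_trials = 256`,
#'   `effect = zero_genotype_effect()`, `seed = 7`).
#' @return A `synth_config` list; see the fields in the source or the
#'   methods vignette.
#' @export
default_config <- function(...) {
  frontal <- rbind(component_template("N1", 25, 8, -30),
                   component_template("P1", 60, 15, 40),
                   component_template("N2", 120, 30, -20))
  parietal <- scale_templates(frontal, 0.7, 5)
  occipital <- scale_templates(frontal, 0.5, 10)
  templates <- list(FL = frontal, FR = frontal,
                    PL = parietal, PR = parietal,
                    OL = occipital, OR = occipital)
  effect <- genotype_effect(
    channel = c("OL", "OR", "FL", "FR", "FL", "FR"),
    component = c("N1", "N1", "P1", "P1", "N1", "N1"),
    amplitude_scale = c(-0.8, -0.8, 0.7, 0.7, 1, 1),
    latency_shift_ms = c(0, 0, 0, 0, 10, 10))
  cfg <- list(
    n_per_genotype = 9L,
    channel_templates = templates,
    effect = effect,
    sampling_rate_hz = 1000,
    isi_s = 2.5,
    n_trials = 1100L,
    noise_sd_uV = 20,
    noise_exponent = 1,
    lowcut_hz = 0.1,
    animal_jitter_frac = 0.1,
    trial_jitter_sd_ms = 0,
    artifact_prob = 0.02,
    artifact_amp_uV = 1500,
    seed = 0L)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A `synth_config`.
#' @return The config, invisibly; errors on violated invariants.
#' @export
validate_synth_config <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with(config, {
    stopifnot(n_per_genotype >= 1, n_trials >= 1, sampling_rate_hz > 0,
              isi_s > 0, noise_sd_uV >= 0, animal_jitter_frac >= 0,
              artifact_prob >= 0, artifact_prob <= 1)
    if (artifact_amp_uV <= 1000)
      stop("artifact_amp_uV must exceed 1000 uV so artifacts trip the 1 mV rejection rule")
  })
  for (ch in names(config$channel_templates)) {
    tpl <- config$channel_templates[[ch]]
    stopifnot(all(tpl$width_ms > 0), all(tpl$latency_ms >= 0),
              all(tpl$latency_ms < 250))
  }
  invisible(config)
}

#' Write / read a simulation configuration as YAML
#'
#' All fields round-trip, including the per-channel templates and the
#' effect table.
#'
#' @param config A `synth_config`.
#' @param path File path.
#' @return `write_synth_config` returns `path` invisibly;
#'   `read_synth_config` returns the `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  x <- unclass(config)
  x$channel_templates <- lapply(x$channel_templates, function(d)
    as.list(as.data.frame(d)))
  x$effect <- as.list(as.data.frame(unclass(x$effect)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$channel_templates <- lapply(x$channel_templates, function(d)
    data.frame(label = unlist(d$label), latency_ms = unlist(d$latency_ms),
               width_ms = unlist(d$width_ms),
               amplitude_uV = unlist(d$amplitude_uV),
               stringsAsFactors = FALSE))
  eff <- x$effect
  x$effect <- genotype_effect(unlist(eff$channel) %||% character(),
                              unlist(eff$component) %||% character(),
                              unlist(eff$amplitude_scale) %||% numeric(),
                              unlist(eff$latency_shift_ms) %||% numeric())
  x$n_per_genotype <- as.integer(x$n_per_genotype)
  x$n_trials <- as.integer(x$n_trials)
  x$seed <- as.integer(x$seed)
  class(x) <- "synth_config"
  validate_synth_config(x)
  x
}

# Templates for one channel after applying the genotype effect.
effective_templates <- function(config, channel, genotype) {
  tpl <- config$channel_templates[[channel]]
  if (is.null(tpl)) stop("no template for channel ", channel)
  if (genotype == "HYPO" && nrow(config$effect)) {
    eff <- config$effect
    for (i in seq_len(nrow(eff))) {
      if (eff$channel[i] != channel) next
      j <- match(eff$component[i], tpl$label)
      if (is.na(j)) next
      tpl$amplitude_uV[j] <- tpl$amplitude_uV[j] * eff$amplitude_scale[i]
      tpl$latency_ms[j] <- tpl$latency_ms[j] + eff$latency_shift_ms[i]
    }
  }
  tpl
}

# Evaluate a template mixture at times t_ms (vectorized sum of Gaussians).
template_waveform <- function(templates, t_ms) {
  out <- numeric(length(t_ms))
  for (i in seq_len(nrow(templates))) {
    out <- out + templates$amplitude_uV[i] *
      exp(-(t_ms - templates$latency_ms[i])^2 / (2 * templates$width_ms[i]^2))
  }
  out
}
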