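# Shared fixture builders (everything generated in code; no stored data).

# Epoch set built directly from a 3-D array.
make_epochs <- function(data, fs = 1000, animal = "a01", genotype = "WT",
                        time_ms = NULL) {
  d <- dim(data)
  if (is.null(time_ms)) time_ms <- seq(-500, 499, length.out = d[3])
  epoch_set(data, time_ms, dimnames(data)[[2]] %||%
              paste0("ch", seq_len(d[2])),
            seq_len(d[1]), rep(TRUE, d[1]), fs, animal, genotype,
            range(time_ms) + c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form evoked mixture used in the generator defaults (frontal).
mixture_frontal <- function(t_ms) {
  -30 * exp(-(t_ms - 25)^2 / (2 * 8^2)) +
    40 * exp(-(t_ms - 60)^2 / (2 * 15^2)) -
    20 * exp(-(t_ms - 120)^2 / (2 * 30^2))
}

# Dense-grid local-extremum oracle on a closed-form waveform.
dense_extrema <- function(f, from = 0, to = 250, dt = 0.01) {
  t <- seq(from, to, by = dt)
  v <- f(t)
  d <- sign(diff(v))
  ks <- which(d != 0)
  dd <- d[ks]
  turns <- which(dd[-length(dd)] != dd[-1])
  idx <- ks[turns] + 1L
  data.frame(latency_ms = t[idx], value = v[idx],
             type = ifelse(dd[turns] > 0, "max", "min"))
}

# Small simulated cohort as rejected single-trial epoch sets.
cohort_eps <- function(config) {
  mf <- cohort_manifest(config)
  eps <- lapply(seq_len(nrow(mf)), function(i) {
    rec <- simulate_animal(config, mf$genotype[i], mf$animal_id[i],
                           seed = mf$seed[i], sex = mf$sex[i])
    reject_artifacts(suppressMessages(extract_epochs(rec)))
  })
  names(eps) <- mf$animal_id
  eps
}

# Random orthonormal matrix (rows).
random_orthonormal <- function(r, d) {
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  t(Q[, seq_len(r), drop = FALSE])
}
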