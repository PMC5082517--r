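# Shared fixtures: small deterministic objects built in code.

# A bare network list usable by dnm(): n isolated nodes unless edges given.
bare_net <- function(n, edges = NULL, lags = NULL, labels = NULL) {
  A <- matrix(0L, n, n)
  L <- matrix(0, n, n)
  if (!is.null(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1L]
      j <- edges[e, 2L]
      A[i, j] <- A[j, i] <- 1L
      lag <- if (is.null(lags)) 0 else lags[e]
      L[i, j] <- lag
      L[j, i] <- -lag
    }
  }
  if (is.null(labels)) labels <- paste0("N", seq_len(n))
  list(adjacency = A, lag = L, labels = labels)
}

# Erdos-Renyi symmetric binary network with uniform lags, for model tests.
er_net <- function(n, p, seed = 1, lag_range = c(0.3, 0.8)) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  L <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (runif(1) < p) {
      A[i, j] <- A[j, i] <- 1L
      lag <- sample(c(-1, 1), 1) * runif(1, lag_range[1L], lag_range[2L])
      L[i, j] <- lag
      L[j, i] <- -lag
    }
  }
  list(adjacency = A, lag = L, labels = paste0("N", seq_len(n)))
}

# Multichannel segment of pure tones (one frequency per channel).
tone_segment <- function(freqs, fs = 256, duration = 20, amp = 50,
                         band = "raw") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  data <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), t))
  eeg_segment(data, fs, paste0("CH", seq_along(freqs)), band = band)
}

# Small quick source spec used across generator tests.
quick_spec <- function(n = 6, duration = 10, seed = 1, ...) {
  source_spec(n_channels = n, duration = duration, seed = seed,
              variance_profile = rep(50, n), ...)
}

# A spec whose oscillators sit inside the low-alpha band with chosen coupled
# pairs, for network ground-truth recovery tests.
coupled_spec <- function(n = 8, pairs, strength = 8, lag = 0.6,
                         duration = 20, seed = 1) {
  C <- matrix(0, n, n)
  L <- matrix(0, n, n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]
    j <- pairs[r, 2L]
    C[i, j] <- C[j, i] <- strength
    L[i, j] <- lag
    L[j, i] <- -lag
  }
  source_spec(n_channels = n, duration = duration,
              coupling_matrix = C, phase_lag_matrix = L,
              variance_profile = rep(50, n), seed = seed)
}

# Low-alpha filtered segment from a spec.
low_alpha_of <- function(spec) {
  band_filter(broadband_filter(generate_segment(spec)), "low_alpha")
}
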