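#' Specification of one synthetic resting-state EEG source
#'
#' Defines a multichannel surrogate eyes-closed resting EEG built from three
#' separately controllable ingredients, one per cohort-level effect the
#' generator emulates:
#'
#' * a posterior-dominant alpha rhythm at `alpha_peak` Hz (independent phase
#'   per channel), carrying the spectral-peak effect;
#' * a coupled phase-oscillator system at `coupling_freq` Hz (inside the
#'   low-alpha band) whose pairwise sine coupling (`coupling_matrix`, rad/s)
#'   and preferred phase offsets (`phase_lag_matrix`, antisymmetric radians)
#'   define the ground-truth functional network; only channels that
#'   participate in at least one coupling edge carry this component;
#' * 1/f^beta background noise.
#'
#' Per-channel frequency jitter and phase diffusion decorrelate uncoupled
#' oscillators over seconds, as real rhythms do. Each channel is finally
#' rescaled exactly to its target variance.
#'
#' @param n_channels number of channels (default 19, the 10-20 montage).
#' @param sample_rate sampling rate in Hz; `duration * sample_rate` must be a
#'   whole number of samples >= 2.
#' @param duration segment length in seconds (default 20).
#' @param alpha_peak centre frequency of the alpha rhythm in Hz (6-13).
#' @param alpha_power RMS amplitude of the alpha component relative to the
#'   unit-RMS background noise (>= 0), scaled per channel by
#'   `alpha_topography`.
#' @param noise_exponent spectral slope beta >= 0 of the 1/f^beta noise.
#' @param noise_amp noise amplitude relative to alpha_power's unit; 0 disables
#'   the background noise entirely.
#' @param coupling_matrix n x n nonnegative coupling strengths (rad/s), zero
#'   diagonal; default all zero.
#' @param phase_lag_matrix n x n antisymmetric preferred phase offsets
#'   (radians); default all zero.
#' @param coupling_freq centre frequency (Hz) of the coupled oscillator
#'   system; default 7.5, the low-alpha centre.
#' @param coupling_power RMS amplitude of the coupled component on
#'   participating channels.
#' @param variance_profile per-channel target variance (uV^2, > 0); each
#'   generated channel is rescaled to this variance exactly.
#' @param alpha_topography per-channel multiplier of the alpha amplitude;
#'   default posterior-weighted for the 19-channel montage (eyes-closed alpha
#'   is occipitally dominant), uniform otherwise.
#' @param channel_labels optional channel names.
#' @param freq_jitter sd (Hz) of per-channel oscillator frequency offsets.
#' @param phase_noise phase diffusion coefficient (rad/sqrt(s)).
#' @param mixing_matrix optional n x n instantaneous linear mixing matrix
#'   (volume-conduction confound); `NULL` (default) disables mixing.
#' @param seed integer seed; the segment is deterministic given the spec.
#' @return An object of class `source_spec`.
#' @seealso [generate_segment()], [cohort_spec()]
#' @export
source_spec <- function(n_channels = 19, sample_rate = 256, duration = 20,
                        alpha_peak = 10, alpha_power = 1.2,
                        noise_exponent = 1, noise_amp = 1,
                        coupling_matrix = NULL, phase_lag_matrix = NULL,
                        coupling_freq = 7.5, coupling_power = 1.0,
                        variance_profile = NULL, alpha_topography = NULL,
                        channel_labels = NULL,
                        freq_jitter = 0.15, phase_noise = 1.5,
                        mixing_matrix = NULL, seed = 1L) {
  n <- as.integer(n_channels)
  if (is.na(n) || n < 2L) stop("n_channels: must be an integer >= 2")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate: must be positive")
  n_samp <- duration * sample_rate
  if (abs(n_samp - round(n_samp)) > 1e-9 || round(n_samp) < 2)
    stop("duration: duration * sample_rate must be an integer >= 2")
  if (!is.numeric(alpha_peak) || alpha_peak < 6 || alpha_peak > 13)
    stop("alpha_peak: must lie in [6, 13] Hz")
  if (alpha_power < 0) stop("alpha_power: must be >= 0")
  if (noise_exponent < 0) stop("noise_exponent: must be >= 0")
  if (noise_amp < 0) stop("noise_amp: must be >= 0")
  if (is.null(coupling_matrix)) coupling_matrix <- matrix(0, n, n)
  coupling_matrix <- as.matrix(coupling_matrix)
  if (!all(dim(coupling_matrix) == n))
    stop("coupling_matrix: must be n_channels x n_channels")
  if (any(coupling_matrix < 0))
    stop("coupling_matrix: entries must be nonnegative")
  if (any(diag(coupling_matrix) != 0))
    stop("coupling_matrix: diagonal must be zero")
  if (is.null(phase_lag_matrix)) phase_lag_matrix <- matrix(0, n, n)
  phase_lag_matrix <- as.matrix(phase_lag_matrix)
  if (!all(dim(phase_lag_matrix) == n))
    stop("phase_lag_matrix: must be n_channels x n_channels")
  if (max(abs(phase_lag_matrix + t(phase_lag_matrix))) > 1e-9)
    stop("phase_lag_matrix: must be antisymmetric")
  if (coupling_freq < 6 || coupling_freq > 9)
    stop("coupling_freq: must lie in the low-alpha band [6, 9] Hz")
  if (coupling_power < 0) stop("coupling_power: must be >= 0")
  if (is.null(variance_profile)) variance_profile <- default_variance_profile(n)
  if (length(variance_profile) != n || any(variance_profile <= 0))
    stop("variance_profile: need one positive variance per channel")
  if (is.null(alpha_topography)) alpha_topography <- default_alpha_topography(n)
  if (length(alpha_topography) != n || any(alpha_topography < 0))
    stop("alpha_topography: need one nonnegative weight per channel")
  if (!is.null(mixing_matrix)) {
    mixing_matrix <- as.matrix(mixing_matrix)
    if (!all(dim(mixing_matrix) == n))
      stop("mixing_matrix: must be n_channels x n_channels")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (n == 19L) montage_1020() else paste0("CH", seq_len(n))
  }
  structure(list(n_channels = n, sample_rate = sample_rate,
                 duration = duration, alpha_peak = alpha_peak,
                 alpha_power = alpha_power, noise_exponent = noise_exponent,
                 noise_amp = noise_amp, coupling_matrix = coupling_matrix,
                 phase_lag_matrix = phase_lag_matrix,
                 coupling_freq = coupling_freq,
                 coupling_power = coupling_power,
                 variance_profile = variance_profile,
                 alpha_topography = alpha_topography,
                 channel_labels = toupper(channel_labels),
                 freq_jitter = freq_jitter, phase_noise = phase_noise,
                 mixing_matrix = mixing_matrix, seed = as.integer(seed)),
            class = "source_spec")
}

# Posterior-weighted alpha topography for the 10-20 montage: occipital
# channels strongest, parietal/posterior-temporal intermediate, the rest
# weak. Uniform for non-standard montages.
default_alpha_topography <- function(n) {
  if (n != 19L) return(rep(1, n))
  w <- stats::setNames(rep(0.4, 19L), montage_1020())
  w[c("P3", "PZ", "P4", "T5", "T6")] <- 1.0
  w[c("O1", "O2")] <- 1.5
  w
}

# Mildly heterogeneous resting-EEG variance profile (uV^2): posterior channels
# carry more alpha power than frontal ones, as in eyes-closed recordings.
default_variance_profile <- function(n) {
  base <- 60 * exp(seq(-0.4, 0.4, length.out = n))
  if (n == 19L) names(base) <- montage_1020()
  base
}

#' Generate one synthetic EEG segment
#'
#' Integrates the coupled phase-oscillator sources of a [source_spec()],
#' superimposes 1/f^beta background noise, optionally applies an instantaneous
#' mixing matrix, and rescales every channel exactly to its target variance.
#' Bit-reproducible given the spec (including its seed).
#'
#' @param spec a [source_spec()].
#' @return An [eeg_segment()] (band `"raw"`) with the source phases attached as
#'   attribute `"source_phase"` (channels x samples, radians).
#' @export
generate_segment <- function(spec) {
  stopifnot(inherits(spec, "source_spec"))
  n <- spec$n_channels
  fs <- spec$sample_rate
  T <- as.integer(round(spec$duration * fs))
  with_seed(spec$seed, function() {
    # coupled low-alpha oscillator system: the ground-truth network
    omega_net <- 2 * pi *
      (spec$coupling_freq + stats::rnorm(n, 0, spec$freq_jitter))
    theta0_net <- stats::runif(n, 0, 2 * pi)
    W <- spec$coupling_matrix * exp(1i * spec$phase_lag_matrix)
    theta <- kuramoto_phases(omega_net, W, theta0_net, spec$phase_noise,
                             1 / fs, T)
    in_graph <- rowSums(spec$coupling_matrix) > 0
    # posterior-dominant alpha rhythm, independent phase per channel
    omega_a <- 2 * pi * (spec$alpha_peak + stats::rnorm(n, 0, spec$freq_jitter))
    theta_a <- kuramoto_phases(omega_a, matrix(0i, n, n),
                               stats::runif(n, 0, 2 * pi), spec$phase_noise,
                               1 / fs, T)
    x <- spec$alpha_power * spec$alpha_topography * sqrt(2) * cos(theta_a) +
      spec$coupling_power * in_graph * sqrt(2) * cos(theta)
    if (spec$noise_amp > 0)
      x <- x + spec$noise_amp * one_over_f_noise(n, T, spec$noise_exponent, fs)
    if (!is.null(spec$mixing_matrix)) x <- spec$mixing_matrix %*% x
    x <- x - rowMeans(x)
    v <- apply(x, 1L, stats::var)
    if (any(v <= 0))
      stop("generated channel has zero variance; cannot rescale")
    x <- x * sqrt(spec$variance_profile / v)
    seg <- eeg_segment(x, fs, spec$channel_labels, band = "raw")
    attr(seg, "source_phase") <- theta
    seg
  })
}

# 1/f^beta Gaussian noise via spectral shaping; each channel has unit variance
# in expectation before the generator's exact rescaling. DC is excluded.
one_over_f_noise <- function(n_channels, n_samples, beta, fs) {
  freqs <- seq(0, fs / 2, length.out = floor(n_samples / 2) + 1L)
  shape <- c(0, freqs[-1L]^(-beta / 2))
  out <- matrix(0, n_channels, n_samples)
  for (c in seq_len(n_channels)) {
    half <- length(shape)
    amp <- shape * (stats::rnorm(half) + 1i * stats::rnorm(half)) / sqrt(2)
    amp[1L] <- 0
    if (n_samples %% 2L == 0L) {
      amp[half] <- Re(amp[half])
      full <- c(amp, Conj(rev(amp[2:(half - 1L)])))
    } else {
      full <- c(amp, Conj(rev(amp[2:half])))
    }
    x <- Re(stats::fft(full, inverse = TRUE))
    out[c, ] <- x / stats::sd(x)
  }
  out
}

#' Cohort-level effects applied to patient subjects
#'
#' The three group-level alterations the surrogate cohorts emulate: an
#' alpha-peak shift toward lower frequencies, denser low-alpha coupling, and
#' elevated signal variance (hence elevated model local coupling).
#'
#' @param alpha_peak_shift additive shift of the subject alpha peak (Hz).
#' @param coupling_density multiplier on the probability that a channel pair
#'   is coupled.
#' @param variance_mult multiplier on the whole variance profile.
#' @return A named list of class `cohort_effect`.
#' @export
cohort_effect <- function(alpha_peak_shift = 0, coupling_density = 1,
                          variance_mult = 1) {
  if (coupling_density < 0 || variance_mult <= 0)
    stop("cohort_effect: coupling_density must be >= 0, variance_mult > 0")
  structure(list(alpha_peak_shift = alpha_peak_shift,
                 coupling_density = coupling_density,
                 variance_mult = variance_mult),
            class = "cohort_effect")
}

#' Default patient-cohort effect
#'
#' The study-condition deltas for the synthetic "patient" arm: alpha peak
#' shifted down by 1 Hz, coupled-pair density multiplied by 1.25, variance
#' profile multiplied by 1.6. The shifts are deliberately small relative to
#' the subject-level heterogeneity of [cohort_spec()]: the spectral and
#' network comparator biomarkers show clear group-level differences but
#' overlap substantially between individuals, while the variance effect that
#' drives the model's local coupling is the strongest individual-level
#' signal.
#'
#' @return A [cohort_effect()].
#' @export
patient_effect <- function() {
  cohort_effect(alpha_peak_shift = -1.0, coupling_density = 1.25,
                variance_mult = 1.6)
}

#' Specification of a synthetic cohort
#'
#' One arm of a simulated study: `n_subjects` subjects generated from a shared
#' base [source_spec()] with subject-level heterogeneity (alpha-peak jitter,
#' lognormal variance scaling, an individually drawn random coupling graph)
#' and, for a patient arm, the systematic deltas of a [cohort_effect()].
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base a [source_spec()] giving the shared defaults.
#' @param label `"control"` or `"patient"`.
#' @param effect a [cohort_effect()]; ignored deltas default to none.
#' @param edge_prob baseline probability that an (unordered) channel pair is
#'   coupled in a subject's source graph.
#' @param coupling_strength coupling strength (rad/s) of coupled pairs.
#' @param lag_range magnitudes (radians) between which pairwise phase lags are
#'   drawn uniformly (sign random); kept away from 0 and pi so true edges
#'   survive the zero-lag exclusion that guards against volume conduction.
#' @param alpha_sd subject-level sd of the alpha-peak frequency (Hz).
#' @param variance_sd subject-level sd of log variance scaling.
#' @param seed integer cohort seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, base = source_spec(),
                        label = c("control", "patient"),
                        effect = cohort_effect(),
                        edge_prob = 0.06, coupling_strength = 5,
                        lag_range = c(0.25, 1.0),
                        alpha_sd = 1.25, variance_sd = 0.2,
                        seed = 1L) {
  label <- match.arg(label)
  if (!inherits(base, "source_spec")) stop("base: must be a source_spec")
  if (!inherits(effect, "cohort_effect"))
    stop("effect: must be a cohort_effect")
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("n_subjects: must be an integer >= 1")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob: must lie in [0, 1]")
  structure(list(n_subjects = n_subjects, base = base, label = label,
                 effect = effect, edge_prob = edge_prob,
                 coupling_strength = coupling_strength,
                 lag_range = lag_range, alpha_sd = alpha_sd,
                 variance_sd = variance_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic per-subject seed derived from the cohort seed, the subject
# index and the arm label; stays well below 2^31.
subject_seed <- function(cohort_seed, index, label) {
  base <- (abs(as.integer(cohort_seed)) %% 500009L) * 2011L
  base + index * 7919L + if (label == "patient") 104729L else 0L
}

# Draw one subject's source_spec from a cohort_spec.
draw_subject_spec <- function(cs, index) {
  sseed <- subject_seed(cs$seed, index, cs$label)
  base <- cs$base
  n <- base$n_channels
  eff <- cs$effect
  with_seed(sseed, function() {
    peak <- base$alpha_peak + eff$alpha_peak_shift +
      stats::rnorm(1, 0, cs$alpha_sd)
    peak <- min(max(peak, 6), 13)
    vmult <- eff$variance_mult *
      exp(stats::rnorm(1, 0, cs$variance_sd) - cs$variance_sd^2 / 2)
    p <- min(1, cs$edge_prob * eff$coupling_density)
    C <- matrix(0, n, n)
    L <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (stats::runif(1) < p) {
          C[i, j] <- C[j, i] <- cs$coupling_strength
          lag <- sample(c(-1, 1), 1L) *
            stats::runif(1, cs$lag_range[1L], cs$lag_range[2L])
          L[i, j] <- lag
          L[j, i] <- -lag
        }
      }
    }
    source_spec(n_channels = n, sample_rate = base$sample_rate,
                duration = base$duration, alpha_peak = peak,
                alpha_power = base$alpha_power,
                noise_exponent = base$noise_exponent,
                noise_amp = base$noise_amp,
                coupling_matrix = C, phase_lag_matrix = L,
                variance_profile = base$variance_profile * vmult,
                channel_labels = base$channel_labels,
                freq_jitter = base$freq_jitter,
                phase_noise = base$phase_noise,
                mixing_matrix = base$mixing_matrix, seed = sseed)
  })
}

#' Generate a labelled two-arm cohort
#'
#' Generates every subject of a patient arm and a control arm. Per-subject
#' seeds are derived deterministically from the cohort seeds, so a cohort is
#' reproduced exactly from its specs. Subjects are ordered controls first,
#' then patients, unless shuffled.
#'
#' @param patients a [cohort_spec()] with label `"patient"`.
#' @param controls a [cohort_spec()] with label `"control"`.
#' @param shuffle permute subject order (seeded by the control-arm seed)?
#' @return A list of class `cohort` whose elements each hold `segment`
#'   ([eeg_segment()]), `label`, `subject_id` and the drawn `spec`.
#' @export
generate_cohort <- function(patients, controls, shuffle = FALSE) {
  stopifnot(inherits(patients, "cohort_spec"), inherits(controls, "cohort_spec"))
  if (patients$label != "patient" || controls$label != "control")
    stop("generate_cohort: arms must be labelled patient and control")
  one_arm <- function(cs) {
    lapply(seq_len(cs$n_subjects), function(i) {
      sp <- draw_subject_spec(cs, i)
      list(segment = generate_segment(sp), label = cs$label,
           subject_id = sprintf("%s%02d", toupper(substr(cs$label, 1, 1)), i),
           spec = sp)
    })
  }
  out <- c(one_arm(controls), one_arm(patients))
  if (shuffle)
    out <- with_seed(controls$seed + 31L,
                     function() out[sample.int(length(out))])
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("Synthetic EEG cohort: %d subjects (%d patient, %d control)\n",
              length(x), sum(labs == "patient"), sum(labs == "control")))
  invisible(x)
}

#' Subject labels of a cohort
#' @param cohort a `cohort` from [generate_cohort()].
#' @return Character vector of `"patient"` / `"control"` labels.
#' @export
cohort_labels <- function(cohort) vapply(cohort, `[[`, "", "label")
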