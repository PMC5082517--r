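#' Broadband filtering of raw EEG
#'
#' Zero-phase Butterworth band-pass between 0.5 and 70 Hz followed by a
#' zero-phase Butterworth band-stop between 48 and 52 Hz (power-line removal).
#' Filters are order 4 applied forward and backward (`signal::filtfilt`), so
#' the effective magnitude order is 8 and the phase response is zero --
#' essential because instantaneous phase estimates are derived downstream.
#'
#' @param seg an [eeg_segment()].
#' @return The filtered [eeg_segment()] with band tag `"broadband"`.
#' @export
broadband_filter <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  fs <- seg$sample_rate
  if (fs <= 140)
    stop("sample_rate must exceed 140 Hz for a 70 Hz band edge")
  bp <- signal::butter(4, c(0.5, 70) / (fs / 2), type = "pass")
  bs <- signal::butter(4, c(48, 52) / (fs / 2), type = "stop")
  x <- t(apply(seg$data, 1L, function(ch) {
    filtfilt_pad(bs, filtfilt_pad(bp, ch, fs), fs)
  }))
  eeg_segment(x, fs, seg$channel_labels, band = "broadband")
}

# Zero-phase filtering: forward and backward passes of a direct-form-II
# transposed filter with matched initial conditions and odd-reflection end
# padding (the standard filtfilt algorithm), which suppresses the edge
# transients plain zero-state filtering leaves.
filtfilt_pad <- function(filt, x, fs = NULL) {
  b <- filt$b
  a <- filt$a
  m <- max(length(a), length(b))
  b <- c(b, rep(0, m - length(b))) / a[1L]
  a <- c(a, rep(0, m - length(a))) / a[1L]
  # pad must outlast the filter ringdown; the narrow band-stop rings longest
  nfact <- 3L * (m - 1L)
  if (!is.null(fs)) nfact <- max(nfact, as.integer(round(3 * fs)))
  n <- length(x)
  nfact <- min(nfact, n - 1L)
  if (n <= 3L * (m - 1L)) stop("signal too short for zero-phase filtering")
  # even (mirror) reflection: value-continuous and free of the spurious DC
  # offset an odd reflection introduces when an endpoint is far from zero --
  # that offset would excite the slow 0.5 Hz high-pass modes
  ext <- c(x[(nfact + 1L):2L], x, x[(n - 1L):(n - nfact)])
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, ext, zi * ext[1L])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + n)]
}

# Steady-state filter state for a unit-step input (per unit of input level):
# solves (I - A') zi = B for the companion-form state matrix.
lfilter_zi <- function(b, a) {
  m <- length(a)
  A <- matrix(0, m - 1L, m - 1L)
  A[1L, ] <- -a[2:m]
  if (m > 2L) A[cbind(2:(m - 1L), 1:(m - 2L))] <- 1
  B <- b[2:m] - a[2:m] * b[1L]
  solve(diag(m - 1L) - t(A), B)
}

#' Narrowband filtering into the alpha or low-alpha band
#'
#' Zero-phase Butterworth band-pass at 8-13 Hz (`"alpha"`) or 6-9 Hz
#' (`"low_alpha"`). The input is expected to be broadband-filtered first.
#'
#' @param seg a broadband [eeg_segment()].
#' @param band `"alpha"` or `"low_alpha"`.
#' @return The filtered [eeg_segment()] with the band tag set.
#' @export
band_filter <- function(seg, band = c("alpha", "low_alpha")) {
  stopifnot(inherits(seg, "eeg_segment"))
  band <- match.arg(band)
  corners <- switch(band, alpha = c(8, 13), low_alpha = c(6, 9))
  fs <- seg$sample_rate
  if (fs / 2 <= corners[2L])
    stop("sample_rate too low for the requested band")
  if (seg$band != "broadband")
    warning("band_filter: input is not broadband-filtered")
  bp <- signal::butter(4, corners / (fs / 2), type = "pass")
  x <- t(apply(seg$data, 1L, function(ch) filtfilt_pad(bp, ch, fs)))
  eeg_segment(x, fs, seg$channel_labels, band = band)
}

#' Welch power spectral density of one channel
#'
#' Hann-tapered Welch estimate with (by default) 2-s windows and 50% overlap,
#' giving a 0.5 Hz frequency grid at any whole-number sampling rate.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_sec window length in seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @return List with `freqs` (Hz) and `power` (density per Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  L <- as.integer(round(window_sec * fs))
  if (L < 8L) stop("welch_psd: window too short")
  if (length(x) < L) stop("welch_psd: signal shorter than one window")
  hop <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, length(x) - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)  # periodic Hann
  norm <- fs * sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / norm
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[nf] <- 1
  list(freqs = seq(0, fs / 2, length.out = nf), power = p * dbl)
}

#' Cohort-normalized power spectrum
#'
#' Per-channel Welch spectra divided by a single constant: the total
#' (frequency-summed) power averaged across all channels of the segment. The
#' normalization makes the mean channel total equal to 1 while preserving
#' relative power differences between channels, and removes global amplitude
#' differences between subjects (e.g. from cranium anatomy).
#'
#' @param seg a broadband [eeg_segment()].
#' @param window_sec,overlap Welch parameters, see [welch_psd()].
#' @return An object of class `normalized_spectrum` with `freqs`, `power`
#'   (channels x freqs), `norm_constant` (uV^2) and `labels`.
#' @export
normalized_spectrum <- function(seg, window_sec = 2, overlap = 0.5) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (all(seg$data == 0))
    stop("normalized_spectrum: all-zero input, normalization undefined")
  per <- apply(seg$data, 1L, function(ch)
    welch_psd(ch, seg$sample_rate, window_sec, overlap)$power)
  power <- t(per)  # channels x freqs
  freqs <- welch_psd(seg$data[1L, ], seg$sample_rate, window_sec,
                     overlap)$freqs
  norm_constant <- mean(rowSums(power))
  if (norm_constant <= 0)
    stop("normalized_spectrum: nonpositive total power")
  power <- power / norm_constant
  rownames(power) <- seg$channel_labels
  structure(list(freqs = freqs, power = power,
                 norm_constant = norm_constant,
                 labels = seg$channel_labels),
            class = "normalized_spectrum")
}

#' @export
print.normalized_spectrum <- function(x, ...) {
  cat(sprintf("Normalized spectrum: %d channels x %d frequencies (0-%g Hz, step %g Hz)\n",
              nrow(x$power), length(x$freqs), max(x$freqs),
              x$freqs[2L] - x$freqs[1L]))
  cat(sprintf("normalization constant: %.4g uV^2 (mean channel total = %.6f)\n",
              x$norm_constant, mean(rowSums(x$power))))
  invisible(x)
}

#' @export
plot.normalized_spectrum <- function(x, channels = NULL, xlim = c(0, 30), ...) {
  sel <- if (is.null(channels)) x$labels else toupper(channels)
  graphics::matplot(x$freqs, t(x$power[sel, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "frequency (Hz)",
                    ylab = "normalized power", xlim = xlim, ...)
  graphics::legend("topright", legend = sel, lty = 1, cex = 0.6,
                   col = seq_along(sel))
  invisible(x)
}
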