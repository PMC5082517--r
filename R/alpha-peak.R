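#' Occipital alpha-peak frequency
#'
#' Candidate biomarker 1: the frequency of maximal normalized power over a set
#' of occipital channels, searched between 6 and 14 Hz (covering both the
#' alpha and low-alpha bands). The alpha peak is known to shift toward lower
#' frequencies in generalized epilepsy, so *lower* values are the
#' epilepsy-like direction. Exact ties are broken toward the lower frequency.
#'
#' @param nspec a [normalized_spectrum()].
#' @param channels channel labels to average over; default `O1`, `O2`.
#' @param window numeric length-2 search window in Hz.
#' @return An object of class `alpha_peak` with `peak_freq` (Hz),
#'   `peak_power`, `channel_set` and a `flat` flag set when the averaged
#'   spectrum carries no structure in the window.
#' @export
alpha_peak <- function(nspec, channels = c("O1", "O2"), window = c(6, 14)) {
  stopifnot(inherits(nspec, "normalized_spectrum"))
  channels <- toupper(channels)
  if (length(channels) == 0L) stop("alpha_peak: empty channel set")
  missing <- setdiff(channels, nspec$labels)
  if (length(missing) > 0L)
    stop(sprintf("alpha_peak: channel(s) not in spectrum: %s",
                 paste(missing, collapse = ", ")))
  avg <- colMeans(nspec$power[channels, , drop = FALSE])
  in_win <- nspec$freqs >= window[1L] & nspec$freqs <= window[2L]
  if (!any(in_win)) stop("alpha_peak: search window outside frequency grid")
  f <- nspec$freqs[in_win]
  p <- avg[in_win]
  flat <- diff(range(p)) <= .Machine$double.eps * max(abs(p), 1)
  if (flat) warning("alpha_peak: flat spectrum in search window")
  i <- which.max(p)  # which.max returns the first (lowest-frequency) maximum
  structure(list(peak_freq = f[i], peak_power = p[i],
                 channel_set = channels, flat = flat),
            class = "alpha_peak")
}

#' @export
print.alpha_peak <- function(x, ...) {
  cat(sprintf("Alpha peak: %.2f Hz (normalized power %.4g) over %s%s\n",
              x$peak_freq, x$peak_power,
              paste(x$channel_set, collapse = "+"),
              if (x$flat) " [flat]" else ""))
  invisible(x)
}
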