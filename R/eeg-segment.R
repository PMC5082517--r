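#' EEG segment container
#'
#' A light container for a multichannel EEG segment: a channels x samples
#' numeric matrix in microvolts, its sampling rate, 10-20 channel labels and a
#' band tag recording which filter has been applied.
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param channel_labels character vector of unique channel names; defaults to
#'   the standard 10-20 montage when `nrow(data)` is 19, else `CH1...CHn`.
#' @param band one of `"raw"`, `"broadband"`, `"alpha"`, `"low_alpha"`.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, sample_rate, channel_labels = NULL,
                        band = "raw") {
  data <- as.matrix(data)
  if (!is.numeric(data))
    stop("data: must be a numeric matrix")
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("data: non-finite value in channel %d at sample %d",
                 bad[1L], bad[2L]))
  }
  if (nrow(data) < 2L)
    stop("data: need at least 2 channels")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate: must be a positive scalar (Hz)")
  if (ncol(data) < 2 * sample_rate)
    stop("data: need at least 2 s of samples")
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 19L) montage_1020()
                      else paste0("CH", seq_len(nrow(data)))
  }
  channel_labels <- toupper(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("channel_labels: length must equal the number of channels")
  if (anyDuplicated(channel_labels))
    stop("channel_labels: duplicate channel labels")
  band <- match.arg(band, c("raw", "broadband", "alpha", "low_alpha"))
  rownames(data) <- channel_labels
  structure(list(data = data, sample_rate = sample_rate,
                 channel_labels = channel_labels, band = band),
            class = "eeg_segment")
}

#' Standard 19-channel 10-20 montage labels
#'
#' @return Character vector of 19 upper-case 10-20 electrode names.
#' @export
montage_1020 <- function() {
  c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
    "T3", "C3", "CZ", "C4", "T4",
    "T5", "P3", "PZ", "P4", "T6", "O1", "O2")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("EEG segment: %d channels x %d samples (%.1f s at %g Hz), band = %s\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$sample_rate,
              x$sample_rate, x$band))
  cat("channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_segment <- function(x) dim(x$data)

n_samples <- function(seg) ncol(seg$data)

duration_s <- function(seg) ncol(seg$data) / seg$sample_rate

#' Per-channel signal variance
#'
#' Sample variance of each channel, the quantity that scales the node-local
#' coupling constants of the dynamic network model (`k_i = K * sigma2_i`).
#' By package convention it is computed on the broadband-filtered segment.
#'
#' @param seg an [eeg_segment()].
#' @return Named numeric vector of per-channel variances (uV^2).
#' @export
channel_variances <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  apply(seg$data, 1L, stats::var)
}

# Run fn with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}
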