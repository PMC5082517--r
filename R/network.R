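#' Instantaneous phase via the analytic signal
#'
#' Per-channel Hilbert phase (argument of the analytic signal, computed by
#' FFT). Meaningful only for narrowband input; a warning is raised for
#' broadband segments. Edge samples are distorted by the transform's
#' periodicity, so downstream phase statistics discard a fraction of each end
#' (see [plf_matrix()]).
#'
#' @param seg a band-filtered [eeg_segment()].
#' @return channels x samples matrix of phases in (-pi, pi], with the sampling
#'   rate attached as attribute `sample_rate`.
#' @export
instantaneous_phase <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (!seg$band %in% c("alpha", "low_alpha"))
    warning("instantaneous_phase: input is not narrowband; phase ill-defined")
  v <- apply(seg$data, 1L, stats::var)
  if (any(v == 0))
    stop(sprintf("instantaneous_phase: channel %s is constant, phase undefined",
                 seg$channel_labels[which(v == 0)[1L]]))
  ph <- t(apply(seg$data, 1L, function(x) Arg(analytic_signal(x))))
  rownames(ph) <- seg$channel_labels
  attr(ph, "sample_rate") <- seg$sample_rate
  ph
}

# Analytic signal by zeroing negative frequencies in the DFT.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-locking factor of two phase series
#'
#' PLF = `|mean(exp(1i * (phi_a - phi_b)))|`: 1 for perfect locking, near 0
#' for independent phases (noise floor `(sqrt(pi)/2)/sqrt(T)` for T
#' independent uniform phase differences). Also returns the circular mean
#' phase difference, the lag.
#'
#' @param phi_a,phi_b phase series (radians) of equal length >= 100.
#' @return List with `plf` in `[0, 1]` and `lag` in `(-pi, pi]`.
#' @export
plf_pair <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b))
    stop("plf_pair: phase series lengths differ")
  if (length(phi_a) < 100L)
    stop("plf_pair: need at least 100 samples")
  m <- mean(exp(1i * (phi_a - phi_b)))
  list(plf = Mod(m), lag = Arg(m))
}

#' All-pairs phase-locking factors and lags
#'
#' Computes the full PLF and lag matrices from a phase matrix, after
#' discarding an edge fraction of samples at each end (analytic-signal end
#' effects). The PLF matrix is symmetric with unit diagonal; the lag matrix is
#' antisymmetric.
#'
#' @param phases channels x samples phase matrix from [instantaneous_phase()].
#' @param edge_trim fraction of samples dropped at each end (default 0.05).
#' @return List with `plf`, `lag`, and `n_used` (samples entering the mean).
#' @export
plf_matrix <- function(phases, edge_trim = 0.05) {
  idx <- trim_index(ncol(phases), edge_trim)
  U <- exp(1i * phases[, idx, drop = FALSE])
  M <- (U %*% Conj(t(U))) / length(idx)
  plf <- Mod(M)
  lag <- Arg(M)
  diag(plf) <- 1
  diag(lag) <- 0
  dimnames(plf) <- dimnames(lag) <- list(rownames(phases), rownames(phases))
  list(plf = plf, lag = lag, n_used = length(idx))
}

trim_index <- function(n, edge_trim) {
  drop <- floor(n * edge_trim)
  if (2L * drop >= n - 1L) stop("edge_trim leaves no samples")
  seq.int(drop + 1L, n - drop)
}

#' Surrogate significance thresholds for PLF
#'
#' Per-pair PLF thresholds under the null hypothesis of no inter-channel phase
#' locking. Surrogates circularly time-shift one channel's phase series by a
#' random offset of at least `min_shift` seconds, preserving each channel's
#' marginal dynamics and spectrum while destroying temporal phase relations.
#' The threshold is the rank-based (1 - alpha_level) point of the surrogate
#' PLF ensemble, so exceeding it has false-positive probability `alpha_level`
#' under exchangeability. PLF at every circular shift is obtained at once via
#' FFT cross-correlation of the unit phasors.
#'
#' @param phases channels x samples phase matrix (with `sample_rate`
#'   attribute) from [instantaneous_phase()].
#' @param n_surrogates ensemble size; `(n_surrogates + 1) * alpha_level` must
#'   be >= 1 (e.g. >= 19 surrogates at the 0.05 level).
#' @param alpha_level significance level per pair.
#' @param min_shift minimum circular shift in seconds.
#' @param edge_trim fraction trimmed per end before PLF (must match the
#'   estimate the threshold is compared to).
#' @param mode `"per_pair"` thresholds, or a single `"global"` threshold from
#'   the pooled surrogate ensemble of all pairs.
#' @param seed integer seed; thresholds are deterministic given it.
#' @return n x n symmetric matrix of thresholds (zero diagonal).
#' @export
surrogate_threshold <- function(phases, n_surrogates = 99, alpha_level = 0.05,
                                min_shift = 1, edge_trim = 0.05,
                                mode = c("per_pair", "global"), seed = 1L) {
  mode <- match.arg(mode)
  if ((n_surrogates + 1) * alpha_level < 1)
    stop(sprintf("too few surrogates (%d) for alpha_level %g", n_surrogates,
                 alpha_level))
  fs <- attr(phases, "sample_rate")
  if (is.null(fs)) stop("phases must carry a sample_rate attribute")
  idx <- trim_index(ncol(phases), edge_trim)
  U <- exp(1i * phases[, idx, drop = FALSE])
  T <- length(idx)
  lo <- as.integer(ceiling(min_shift * fs))
  hi <- as.integer(T - ceiling(min_shift * fs))
  if (hi < lo) stop("segment too short for the requested minimum shift")
  n <- nrow(phases)
  fu <- t(apply(U, 1L, stats::fft))
  thr <- matrix(0, n, n, dimnames = list(rownames(phases), rownames(phases)))
  rank_cut <- function(v) {
    k <- ceiling((1 - alpha_level) * (length(v) + 1))
    sort(v)[min(k, length(v))]
  }
  pooled <- NULL
  with_seed(seed, function() {
    for (a in seq_len(n - 1L)) {
      for (b in seq.int(a + 1L, n)) {
        # |cross-correlation| of unit phasors at shift s = PLF of the
        # surrogate in which channel b's phases are rotated by s samples
        cc <- Mod(stats::fft(fu[a, ] * Conj(fu[b, ]), inverse = TRUE)) / T^2
        shifts <- sample(seq.int(lo, hi), n_surrogates,
                         replace = hi - lo + 1L < n_surrogates)
        ens <- cc[shifts + 1L]
        if (mode == "per_pair") {
          thr[a, b] <<- thr[b, a] <<- rank_cut(ens)
        } else {
          pooled <<- c(pooled, ens)
        }
      }
    }
  })
  if (mode == "global") {
    g <- rank_cut(pooled)
    thr[] <- g
    diag(thr) <- 0
  }
  thr
}

#' Infer the functional network of a band-filtered segment
#'
#' Builds the binary functional network: an edge joins two channels when their
#' PLF exceeds the surrogate significance threshold *and* the phase lag is
#' away from both 0 and pi by more than `zero_lag_eps` radians. The lag guard
#' excludes the near-instantaneous coupling that volume conduction (one
#' cortical source seen by two electrodes) produces.
#'
#' @param seg a narrowband (low-alpha, by convention) [eeg_segment()].
#' @param n_surrogates,alpha_level,min_shift,mode,seed see
#'   [surrogate_threshold()].
#' @param zero_lag_eps half-width (radians) of the exclusion zones around lag
#'   0 and pi.
#' @param edge_trim fraction of samples trimmed per end before PLF.
#' @return An object of class `functional_network` with `plf`, `lag`,
#'   `sig_threshold`, binary `adjacency`, `labels` and `band`.
#' @export
build_network <- function(seg, n_surrogates = 99, alpha_level = 0.05,
                          zero_lag_eps = 0.1, edge_trim = 0.05,
                          min_shift = 1, mode = c("per_pair", "global"),
                          seed = 1L) {
  stopifnot(inherits(seg, "eeg_segment"))
  mode <- match.arg(mode)
  phases <- instantaneous_phase(seg)
  pm <- plf_matrix(phases, edge_trim)
  thr <- surrogate_threshold(phases, n_surrogates, alpha_level, min_shift,
                             edge_trim, mode, seed)
  dist_to_zero_or_pi <- pmin(abs(pm$lag), pi - abs(pm$lag))
  adjacency <- (pm$plf > thr) & (dist_to_zero_or_pi > zero_lag_eps)
  diag(adjacency) <- FALSE
  adjacency <- adjacency & t(adjacency)  # numeric symmetry guard
  storage.mode(adjacency) <- "integer"
  structure(list(plf = pm$plf, lag = pm$lag, sig_threshold = thr,
                 adjacency = adjacency, labels = seg$channel_labels,
                 band = seg$band,
                 params = list(n_surrogates = n_surrogates,
                               alpha_level = alpha_level,
                               zero_lag_eps = zero_lag_eps,
                               edge_trim = edge_trim, mode = mode,
                               seed = seed)),
            class = "functional_network")
}

#' Mean degree of a functional network
#'
#' Candidate biomarker 2: the average over nodes of the number of incident
#' edges, elevated at the group level in generalized epilepsy.
#'
#' @param net a [build_network()] result.
#' @return Scalar mean degree.
#' @export
mean_degree <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  mean(rowSums(net$adjacency))
}

#' @export
print.functional_network <- function(x, ...) {
  n_edges <- sum(x$adjacency) / 2
  cat(sprintf("Functional network (%s band): %d nodes, %d edges, mean degree %.2f\n",
              x$band, nrow(x$adjacency), n_edges, mean_degree(x)))
  cat(sprintf("PLF threshold: %s at alpha %.3g with %d surrogates\n",
              x$params$mode, x$params$alpha_level, x$params$n_surrogates))
  invisible(x)
}

#' @export
plot.functional_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  ang <- 2 * pi * seq_len(n) / n
  px <- cos(ang)
  py <- sin(ang)
  graphics::plot(px, py, asp = 1, axes = FALSE, xlab = "", ylab = "",
                 pch = 21, bg = "grey85", cex = 2.4, ...)
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      if (x$adjacency[i, j] == 1L)
        graphics::segments(px[i], py[i], px[j], py[j],
                           lwd = 0.5 + 3 * x$plf[i, j], col = "steelblue")
  graphics::text(1.12 * px, 1.12 * py, x$labels, cex = 0.7)
  invisible(x)
}

#' Write a functional network as an edge-list TSV
#'
#' Columns `node_a`, `node_b`, `plf`, `lag_rad`, one row per (significant)
#' edge.
#'
#' @param net a `functional_network`.
#' @param path output path.
#' @param all write all pairs rather than only edges?
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path, all = FALSE) {
  stopifnot(inherits(net, "functional_network"))
  rows <- list()
  n <- nrow(net$adjacency)
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      if (all || net$adjacency[i, j] == 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          node_a = net$labels[i], node_b = net$labels[j],
          plf = net$plf[i, j], lag_rad = net$lag[i, j])
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(node_a = character(), node_b = character(),
                        plf = numeric(), lag_rad = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
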