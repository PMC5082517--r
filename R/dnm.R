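#' Subject-specific dynamic network model
#'
#' Embeds an inferred functional network in a mean-field phase-oscillator
#' model. Each node is the order parameter `z_i` of a within-node oscillator
#' population with Lorentzian frequency spread `delta` around `omega0`,
#' intra-node coupling `k_i`, and inter-node input along the network's edges
#' at the inferred phase lags:
#'
#' \deqn{dz_i/dt = (i\omega_0 - \Delta) z_i + (H_i - \bar H_i z_i^2)/2,
#'   \quad H_i = k_i z_i + g \sum_j A_{ji} e^{i \mathrm{lag}(j,i)} z_j}
#'
#' The node-local coupling is tied to the data: `k_i = K * sigma2_i`, the
#' per-channel signal variance scaled by a uniform parameter `K`. An isolated
#' node synchronizes (|z| > 0) exactly when `k_i` exceeds the critical value
#' `k_c = 2 * delta`, with steady state `|z*| = sqrt(1 - 2*delta/k)`.
#'
#' @param net a [build_network()] result (or a list with binary `adjacency`
#'   and antisymmetric `lag` matrices plus `labels`).
#' @param sigma2 per-node signal variances (uV^2), ordered as `net$labels`.
#' @param K uniform local-coupling scale; `k_local = K * sigma2`.
#' @param g global inter-node coupling gain.
#' @param delta within-node frequency half-width (rad/s), > 0.
#' @param omega0 centre frequency (rad/s); default the 7.5 Hz low-alpha
#'   centre. A common rotation, it does not affect `|z|`.
#' @param dt integration step (s).
#' @param t_burn,t_sim burn-in and scoring durations (model seconds);
#'   `t_sim` must cover at least 10 intrinsic periods.
#' @param noise_amp additive complex white-noise amplitude (0 = deterministic).
#' @param theta_sync order-parameter level above which a node counts as
#'   synchronized ("seizure-like").
#' @param k_drive clamped coupling of the driven node; must exceed `k_c`.
#'   Default `2 * k_c`.
#' @param sample_every interval (s) between synchrony samples after burn-in.
#' @param exclude_driven drop the clamped node from the network average? The
#'   score then measures *emergent* spread only.
#' @param z0 initial order parameter (real) for every node.
#' @param seed integer seed (used only when `noise_amp > 0`).
#' @return An object of class `dnm`.
#' @seealso [seizure_likelihood()], [biomarker_profile()]
#' @export
dnm <- function(net, sigma2, K, g = 3, delta = 0.5, omega0 = 2 * pi * 7.5,
                dt = 1e-3, t_burn = 5, t_sim = 30, noise_amp = 0,
                theta_sync = 0.8, k_drive = NULL, sample_every = 0.01,
                exclude_driven = TRUE, z0 = 0.05, seed = 1L) {
  A <- net$adjacency
  lag <- net$lag
  n <- nrow(A)
  if (is.null(n) || ncol(A) != n) stop("adjacency must be square")
  if (!all(A %in% c(0L, 1L))) stop("adjacency must be binary")
  if (max(abs(A - t(A))) != 0) stop("adjacency must be symmetric")
  if (max(abs(lag + t(lag))) > 1e-9) stop("lag must be antisymmetric")
  if (length(sigma2) != n) stop("sigma2 length must match the network")
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  if (delta <= 0) stop("delta must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (t_sim < 10 * 2 * pi / omega0)
    stop("t_sim must cover at least 10 intrinsic periods")
  k_c <- 2 * delta
  if (is.null(k_drive)) k_drive <- 2 * k_c
  if (k_drive <= k_c)
    stop(sprintf("k_drive (%.3g) must exceed the synchrony threshold k_c = %.3g",
                 k_drive, k_c))
  labels <- if (!is.null(net$labels)) net$labels else rownames(A)
  if (is.null(labels)) labels <- paste0("N", seq_len(n))
  # input weight from node j into node i: g * A(j,i) * exp(i * lag(j,i))
  W <- g * A * exp(-1i * lag)
  structure(list(adjacency = A, lag = lag, W = W, sigma2 = sigma2, K = K,
                 k_local = K * sigma2, g = g, delta = delta, k_c = k_c,
                 omega0 = omega0, dt = dt, t_burn = t_burn, t_sim = t_sim,
                 noise_amp = noise_amp, theta_sync = theta_sync,
                 k_drive = k_drive, sample_every = sample_every,
                 exclude_driven = exclude_driven, z0 = z0,
                 seed = as.integer(seed), labels = labels),
            class = "dnm")
}

#' @export
print.dnm <- function(x, ...) {
  cat(sprintf("Dynamic network model: %d nodes, %d edges\n",
              nrow(x$adjacency), sum(x$adjacency) / 2))
  cat(sprintf("K = %.3g, g = %.3g, delta = %.3g (k_c = %.3g), k_drive = %.3g\n",
              x$K, x$g, x$delta, x$k_c, x$k_drive))
  cat(sprintf("k_local range: [%.3g, %.3g]; %s mode\n",
              min(x$k_local), max(x$k_local),
              if (x$noise_amp > 0) "stochastic" else "deterministic"))
  invisible(x)
}

#' Simulate a dynamic network model
#'
#' Integrates the model (fixed-step Heun) and returns the sampled
#' order-parameter magnitudes `|z_i(t)|` after burn-in.
#'
#' @param object a [dnm()].
#' @param nsim unused (one trajectory per call).
#' @param seed optional integer overriding the model's seed.
#' @param driven_node optional node label or index to clamp at `k_drive`.
#' @param ... unused.
#' @return nodes x samples matrix of `|z|`, with the sampling times (s after
#'   burn-in) as attribute `"time"`.
#' @export
simulate.dnm <- function(object, nsim = 1, seed = NULL, driven_node = NULL,
                         ...) {
  m <- object
  drv <- if (is.null(driven_node)) 0L else node_index(m, driven_node)
  s <- if (is.null(seed)) m$seed else as.integer(seed)
  traj <- with_seed(s, function()
    dnm_traj_cpp(m$W, m$k_local, drv, m$k_drive, m$delta, m$omega0, m$dt,
                 m$t_burn, m$t_sim, m$theta_sync, m$noise_amp,
                 m$sample_every, m$z0))
  rownames(traj) <- m$labels
  attr(traj, "time") <- seq(0, by = max(m$sample_every, m$dt),
                            length.out = ncol(traj))
  traj
}

node_index <- function(model, node) {
  if (is.character(node)) {
    i <- match(toupper(node), toupper(model$labels))
    if (is.na(i)) stop(sprintf("unknown node label: %s", node))
    i
  } else {
    i <- as.integer(node)
    if (i < 1L || i > length(model$labels)) stop("driven node index out of range")
    i
  }
}

#' Node-driving seizure likelihood
#'
#' Clamps the intra-node coupling of each driven node above the synchrony
#' threshold (`k_drive > k_c`), integrates the model, and scores the emergent
#' whole-network synchrony: the mean over the other nodes of the fraction of
#' sampled times their order parameter exceeds `theta_sync`. This is the
#' model's proxy for the seizure-generating capability of each region.
#'
#' @param model a [dnm()].
#' @param driven_node node label(s) or index(es); default all nodes.
#' @return Named numeric vector `S` in `[0, 1]`, one entry per driven node.
#' @export
seizure_likelihood <- function(model, driven_node = NULL) {
  stopifnot(inherits(model, "dnm"))
  m <- model
  idx <- if (is.null(driven_node)) seq_along(m$labels)
         else vapply(driven_node, function(d) node_index(m, d), 1L)
  S <- with_seed(m$seed, function()
    dnm_profile_cpp(m$W, m$k_local, as.integer(idx), m$k_drive, m$delta,
                    m$omega0, m$dt, m$t_burn, m$t_sim, m$theta_sync,
                    m$noise_amp, m$sample_every, m$z0, m$exclude_driven))
  names(S) <- m$labels[idx]
  S
}

#' Local-coupling biomarker profile of one subject
#'
#' Candidate biomarker 3. Computes per-channel variances from the segment
#' (broadband-filtered, by package convention), builds the subject's dynamic
#' network model with `k_i = K * sigma2_i`, evaluates the seizure likelihood
#' `S_m` for every driven node, and reads the biomarker off at one channel.
#'
#' @param seg the [eeg_segment()] whose per-channel variances set the local
#'   couplings; channels must match the network's nodes.
#' @param net the subject's [build_network()] result.
#' @param K uniform local-coupling scale.
#' @param channel biomarker channel label (default `"O1"`).
#' @param ... further arguments passed to [dnm()].
#' @return An object of class `node_drive_profile`: `S` (named vector),
#'   `biomarker_channel`, `biomarker_value`, `K`, `k_drive`, `theta_sync`.
#' @export
biomarker_profile <- function(seg, net, K, channel = "O1", ...) {
  stopifnot(inherits(seg, "eeg_segment"), inherits(net, "functional_network"))
  if (!identical(toupper(seg$channel_labels), toupper(net$labels)))
    stop("segment channels and network nodes do not match")
  sigma2 <- channel_variances(seg)
  model <- dnm(net, sigma2, K, ...)
  S <- seizure_likelihood(model)
  channel <- toupper(channel)
  if (!channel %in% toupper(model$labels))
    stop(sprintf("unknown biomarker channel: %s", channel))
  structure(list(S = S, biomarker_channel = channel,
                 biomarker_value = unname(S[match(channel,
                                                  toupper(model$labels))]),
                 K = K, k_drive = model$k_drive,
                 theta_sync = model$theta_sync),
            class = "node_drive_profile")
}

#' @export
print.node_drive_profile <- function(x, ...) {
  cat(sprintf("Node-drive seizure-likelihood profile (K = %.3g):\n", x$K))
  print(round(x$S, 3))
  cat(sprintf("biomarker channel %s: S = %.3f\n", x$biomarker_channel,
              x$biomarker_value))
  invisible(x)
}

#' Local-coupling search grid for K
#'
#' Log-spaced grid spanning `[0.1 * k_c / max(sigma2), 10 * k_c /
#' mean(sigma2)]`, i.e. from every node far subcritical to the mean node far
#' supracritical.
#'
#' @param sigma2 pooled per-channel variances (all subjects).
#' @param n grid size.
#' @param delta within-node frequency spread (sets `k_c = 2 * delta`).
#' @return Numeric vector of K values.
#' @export
k_grid <- function(sigma2, n = 20, delta = 0.5) {
  k_c <- 2 * delta
  lo <- 0.1 * k_c / max(sigma2)
  hi <- 10 * k_c / mean(sigma2)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Precompute the local-coupling biomarker over (subject, channel, K)
#'
#' Evaluates the seizure likelihood of every node at every K of the grid for
#' each subject, so leave-one-out optimization over `(channel, K)` is a table
#' lookup. The cached and direct paths give identical values.
#'
#' @param segs list of band-filtered [eeg_segment()]s (one per subject).
#' @param nets list of matching [build_network()] results.
#' @param Kgrid numeric vector of K values (see [k_grid()]).
#' @param ... further arguments passed to [dnm()].
#' @return Array `subjects x channels x K` with dimnames, of class
#'   `local_coupling_table`.
#' @export
local_coupling_table <- function(segs, nets, Kgrid, ...) {
  stopifnot(length(segs) == length(nets), length(segs) >= 1L)
  labels <- nets[[1L]]$labels
  out <- array(NA_real_,
               dim = c(length(segs), length(labels), length(Kgrid)),
               dimnames = list(NULL, labels, sprintf("K%g", Kgrid)))
  for (s in seq_along(segs)) {
    sigma2 <- channel_variances(segs[[s]])
    m <- dnm(nets[[s]], sigma2, K = Kgrid[1L], ...)
    grid <- with_seed(m$seed, function()
      dnm_grid_cpp(m$W, sigma2, Kgrid, m$k_drive, m$delta, m$omega0, m$dt,
                   m$t_burn, m$t_sim, m$theta_sync, m$noise_amp,
                   m$sample_every, m$z0, m$exclude_driven))
    out[s, , ] <- t(grid)  # grid is nK x nodes
  }
  attr(out, "Kgrid") <- Kgrid
  class(out) <- "local_coupling_table"
  out
}

#' Calibrate the global coupling gain g
#'
#' Sweeps `g` over a grid and returns the smallest value for which the mean
#' seizure likelihood across a set of reference (control-like) subjects falls
#' in the target band, by default `[0.1, 0.3]`. Uses `K = k_c /
#' mean(sigma2)` (the mean node at criticality) as the reference scale.
#'
#' @param segs,nets reference subjects (segments and networks).
#' @param g_grid candidate gains.
#' @param target length-2 band for the mean S.
#' @param ... further arguments passed to [dnm()].
#' @return The selected `g` (with the sweep as attribute `"sweep"`).
#' @export
calibrate_g <- function(segs, nets, g_grid = c(0.5, 1, 1.5, 2, 3, 4, 6, 8),
                        target = c(0.1, 0.3), delta = 0.5, ...) {
  sig_all <- unlist(lapply(segs, channel_variances))
  means <- vapply(g_grid, function(g) {
    Sm <- vapply(seq_along(segs), function(s) {
      sigma2 <- channel_variances(segs[[s]])
      K <- 2 * delta / mean(sig_all)  # mean node at criticality
      m <- dnm(nets[[s]], sigma2, K = K, g = g, delta = delta, ...)
      mean(seizure_likelihood(m))
    }, 1)
    mean(Sm)
  }, 1)
  ok <- which(means >= target[1L] & means <= target[2L])
  g <- if (length(ok)) g_grid[ok[1L]]
       else g_grid[which.min(abs(means - mean(target)))]
  attr(g, "sweep") <- data.frame(g = g_grid, mean_S = means)
  g
}
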