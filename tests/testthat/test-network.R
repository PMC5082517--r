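test_that("instantaneous phase advances linearly for a pure tone", {
  fs <- 256
  seg <- tone_segment(c(10, 10), fs = fs, duration = 10, band = "alpha")
  ph <- instantaneous_phase(seg)
  inner <- 200:2300
  d <- diff(ph[1, ])
  d <- (d + pi) %% (2 * pi) - pi  # unwrap steps
  expect_equal(mean(d[inner]), 2 * pi * 10 / fs, tolerance = 1e-4)
  expect_lt(max(abs(d[inner] - 2 * pi * 10 / fs)), 1e-3)
})

test_that("a known time shift appears as the expected phase difference", {
  fs <- 256
  delay <- 10 / fs  # 10 samples
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  y <- sin(2 * pi * 10 * (t - delay))
  seg <- eeg_segment(rbind(x, y) * 50, fs, c("A", "B"), band = "alpha")
  ph <- instantaneous_phase(seg)
  r <- plf_pair(ph[1, 300:2200], ph[2, 300:2200])
  expect_equal(r$lag, 2 * pi * 10 * delay, tolerance = 1e-2)
  expect_gt(r$plf, 0.999)
})

test_that("degenerate inputs are rejected", {
  seg <- eeg_segment(rbind(rep(0, 600), rnorm(600)), 256, c("A", "B"),
                     band = "alpha")
  expect_error(instantaneous_phase(seg), "constant")
  expect_warning(instantaneous_phase(
    eeg_segment(matrix(rnorm(1200), 2), 256)), "narrowband")
  expect_error(plf_pair(1:200, 1:100), "length")
  expect_error(plf_pair(1:50, 1:50), "100")
})

test_that("plf_pair identities hold", {
  phi <- cumsum(rnorm(2000, 0.2, 0.1))
  same <- plf_pair(phi, phi)
  expect_equal(same$plf, 1, tolerance = 1e-12)
  expect_equal(same$lag, 0, tolerance = 1e-12)
  off <- plf_pair(phi + 0.7, phi)
  expect_equal(off$plf, 1, tolerance = 1e-12)
  expect_equal(off$lag, 0.7, tolerance = 1e-12)
})

test_that("independent uniform phases give the Rayleigh noise floor", {
  # E[PLF] for T iid uniform phase differences ~ sqrt(pi)/2 / sqrt(T)
  T <- 2500
  set.seed(31)
  v <- vapply(1:400, function(i)
    plf_pair(runif(T, -pi, pi), runif(T, -pi, pi))$plf, 1)
  oracle <- sqrt(pi) / 2 / sqrt(T)
  expect_equal(mean(v), oracle, tolerance = 0.05)
})

test_that("PLF matrix is symmetric with unit diagonal; lags antisymmetric", {
  seg <- low_alpha_of(coupled_spec(n = 5, pairs = cbind(1, 2), seed = 3))
  pm <- plf_matrix(instantaneous_phase(seg))
  expect_equal(pm$plf, t(pm$plf), tolerance = 1e-14)
  expect_equal(unname(diag(pm$plf)), rep(1, 5))
  expect_equal(pm$lag, -t(pm$lag), tolerance = 1e-14)
  expect_true(all(pm$plf >= 0 & pm$plf <= 1))
})

test_that("surrogate ensembles via FFT equal directly shifted PLFs", {
  seg <- low_alpha_of(quick_spec(n = 3, seed = 9))
  ph <- instantaneous_phase(seg)
  idx <- ictomark:::trim_index(ncol(ph), 0.05)
  U <- exp(1i * ph[, idx])
  T <- length(idx)
  fu <- stats::fft(U[1, ])
  fv <- stats::fft(U[2, ])
  cc <- Mod(stats::fft(fu * Conj(fv), inverse = TRUE)) / T^2
  for (s in c(300, 1111, 2048)) {
    direct <- Mod(mean(U[1, ] * Conj(U[2, c((T - s + 1):T, 1:(T - s))])))
    expect_equal(cc[s + 1], direct, tolerance = 1e-10)
  }
})

test_that("too few surrogates for the requested level is an error", {
  seg <- low_alpha_of(quick_spec(n = 3, seed = 10))
  ph <- instantaneous_phase(seg)
  expect_error(surrogate_threshold(ph, n_surrogates = 5, alpha_level = 0.05),
               "surrogates")
  thr <- surrogate_threshold(ph, n_surrogates = 19, alpha_level = 0.05,
                             seed = 4)
  expect_true(isSymmetric(thr))
  thr2 <- surrogate_threshold(ph, n_surrogates = 19, alpha_level = 0.05,
                              seed = 4)
  expect_identical(thr, thr2)  # deterministic given seed
})

test_that("strongly coupled pairs always exceed their surrogate threshold", {
  hits <- vapply(1:10, function(seed) {
    seg <- low_alpha_of(coupled_spec(n = 4, pairs = cbind(1, 2), seed = seed))
    ph <- instantaneous_phase(seg)
    pm <- plf_matrix(ph)
    thr <- surrogate_threshold(ph, seed = seed)
    pm$plf[1, 2] > thr[1, 2]
  }, NA)
  expect_true(all(hits))
})

test_that("build_network recovers true lag-coupled pairs with few false edges", {
  pairs <- rbind(c(1, 2), c(3, 4), c(5, 6))
  hits <- 0
  false_edges <- 0
  null_pairs <- 0
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    seg <- low_alpha_of(coupled_spec(n = 8, pairs = pairs, seed = seed))
    net <- build_network(seg, seed = seed + 50)
    for (r in seq_len(nrow(pairs)))
      hits <- hits + net$adjacency[pairs[r, 1], pairs[r, 2]]
    A <- net$adjacency
    for (r in seq_len(nrow(pairs)))
      A[pairs[r, 1], pairs[r, 2]] <- A[pairs[r, 2], pairs[r, 1]] <- 0L
    false_edges <- false_edges + sum(A) / 2
    null_pairs <- null_pairs + (8 * 7 / 2 - 3)
  }
  expect_gte(hits / (3 * n_seeds), 0.9)
  # false-edge rate comparable to the nominal level (allow locking through
  # indirect paths and finite-sample slack)
  expect_lt(false_edges / null_pairs, 0.15)
})

test_that("instantaneous mixing without true coupling yields almost no edges", {
  # heavy cross-talk: every channel dominated by the same mixture, so pairs
  # lock at (near-)zero lag and the volume-conduction guard must reject them
  n <- 6
  M <- matrix(0.8, n, n)
  diag(M) <- 1
  edges <- vapply(1:5, function(seed) {
    sp <- source_spec(n_channels = n, duration = 20, alpha_peak = 7.5,
                      variance_profile = rep(50, n), mixing_matrix = M,
                      seed = seed)
    net <- build_network(low_alpha_of(sp), seed = seed)
    sum(net$adjacency) / 2
  }, 1)
  expect_lt(mean(edges), 1)
})

test_that("mean degree matches hand counts and is relabelling-invariant", {
  comp <- bare_net(5)
  comp$adjacency <- matrix(1L, 5, 5); diag(comp$adjacency) <- 0L
  net <- structure(c(comp, list(plf = NULL, sig_threshold = NULL)),
                   class = "functional_network")
  expect_equal(mean_degree(net), 4)
  empty <- structure(bare_net(4), class = "functional_network")
  expect_equal(mean_degree(empty), 0)
  star <- structure(bare_net(4, edges = rbind(c(1, 2), c(1, 3), c(1, 4))),
                    class = "functional_network")
  expect_equal(mean_degree(star), 1.5)
  perm <- sample(4)
  starp <- star
  starp$adjacency <- star$adjacency[perm, perm]
  expect_equal(mean_degree(starp), mean_degree(star))
})
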