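test_that("isolated-node steady state matches the closed-form fixed point", {
  # dz/dt = (i w0 - delta) z + (k z - k conj(z) z^2)/2 has |z*| =
  # sqrt(1 - 2 delta / k) for k > k_c = 2 delta and |z*| = 0 below
  net <- bare_net(2)
  for (k in c(0.5, 0.9, 1.5, 2, 4)) {
    m <- dnm(net, sigma2 = c(k, k), K = 1, g = 0, delta = 0.5, t_burn = 0,
             t_sim = 100, k_drive = 1.01)
    tr <- simulate(m)
    target <- if (k > 1) sqrt(1 - 1 / k) else 0
    expect_equal(unname(tr[1, ncol(tr)]), target, tolerance = 1e-3)
  }
})

test_that("model construction validates its inputs", {
  net <- bare_net(3)
  expect_error(dnm(net, sigma2 = c(1, 1), K = 1), "sigma2")
  expect_error(dnm(net, sigma2 = rep(1, 3), K = 1, delta = 0), "delta")
  expect_error(dnm(net, sigma2 = rep(1, 3), K = 1, k_drive = 0.5), "k_drive")
  badlag <- net
  badlag$lag[1, 2] <- 0.3  # not antisymmetric
  expect_error(dnm(badlag, sigma2 = rep(1, 3), K = 1), "antisymmetric")
})

test_that("two identical symmetrically coupled nodes stay identical", {
  net <- bare_net(2, edges = cbind(1, 2))
  m <- dnm(net, sigma2 = c(1.2, 1.2), K = 1, g = 0.8, t_burn = 0, t_sim = 10)
  tr <- simulate(m)
  expect_equal(tr[1, ], tr[2, ], tolerance = 1e-12)
})

test_that("empty adjacency cannot propagate the driven synchrony", {
  net <- bare_net(5)
  m <- dnm(net, sigma2 = rep(1, 5), K = 0.5, g = 2, t_burn = 2, t_sim = 10)
  S <- seizure_likelihood(m)
  expect_equal(unname(S), rep(0, 5))
})

test_that("complete symmetric graph gives equal S that saturates as g grows", {
  n <- 5
  A <- matrix(1L, n, n); diag(A) <- 0L
  net <- list(adjacency = A, lag = matrix(0, n, n),
              labels = paste0("N", 1:n))
  S_of_g <- vapply(c(0.2, 1, 4), function(g) {
    m <- dnm(net, sigma2 = rep(1, n), K = 0.6, g = g, t_burn = 3, t_sim = 10)
    S <- seizure_likelihood(m)
    expect_lt(diff(range(S)), 1e-9)  # symmetry: equal across driven nodes
    mean(S)
  }, 1)
  expect_true(all(diff(S_of_g) >= 0))
  expect_equal(S_of_g[3], 1, tolerance = 1e-9)
})

test_that("seizure likelihood is nondecreasing in K on a fixed network", {
  net <- er_net(8, 0.3, seed = 5)
  sigma2 <- runif(8, 0.5, 2)
  S_by_K <- vapply(c(0.2, 0.6, 1.8), function(K) {
    m <- dnm(net, sigma2, K = K, g = 0.5, t_burn = 3, t_sim = 10)
    seizure_likelihood(m)
  }, numeric(8))
  expect_true(all(S_by_K[, 2] >= S_by_K[, 1] - 1e-12))
  expect_true(all(S_by_K[, 3] >= S_by_K[, 2] - 1e-12))
  expect_true(all(S_by_K >= 0 & S_by_K <= 1))
})

test_that("deterministic runs are bit-reproducible; noise changes them", {
  net <- er_net(5, 0.4, seed = 2)
  m <- dnm(net, sigma2 = rep(1, 5), K = 0.7, g = 0.6, t_burn = 2, t_sim = 10)
  expect_identical(seizure_likelihood(m), seizure_likelihood(m))
  mn <- dnm(net, sigma2 = rep(1, 5), K = 0.7, g = 0.6, t_burn = 2,
            t_sim = 10, noise_amp = 0.05, seed = 4)
  mn2 <- dnm(net, sigma2 = rep(1, 5), K = 0.7, g = 0.6, t_burn = 2,
             t_sim = 10, noise_amp = 0.05, seed = 4)
  expect_identical(seizure_likelihood(mn), seizure_likelihood(mn2))
})

test_that("halving the integration step barely changes S", {
  net <- er_net(6, 0.35, seed = 7)
  sigma2 <- runif(6, 0.5, 2)
  S1 <- seizure_likelihood(dnm(net, sigma2, K = 0.8, g = 0.5, t_burn = 3,
                               t_sim = 10, dt = 1e-3))
  S2 <- seizure_likelihood(dnm(net, sigma2, K = 0.8, g = 0.5, t_burn = 3,
                               t_sim = 10, dt = 5e-4))
  expect_lt(max(abs(S1 - S2)), 0.01)
})

test_that("k_local is definitionally K times the channel variance", {
  net <- bare_net(3, labels = c("A", "B", "C"))
  m <- dnm(net, sigma2 = c(1, 2, 3), K = 0.4)
  expect_equal(m$k_local, 0.4 * c(1, 2, 3))
  m2 <- dnm(net, sigma2 = c(1, 4, 3), K = 0.4)  # one variance doubled
  expect_equal(m2$k_local[2], 2 * m$k_local[2])
  expect_equal(m2$k_local[c(1, 3)], m$k_local[c(1, 3)])
})

test_that("K = 0 is the minimal-coupling baseline", {
  net <- er_net(6, 0.4, seed = 9)
  sigma2 <- runif(6, 0.5, 2)
  S0 <- seizure_likelihood(dnm(net, sigma2, K = 0, g = 0.5, t_burn = 3,
                               t_sim = 10))
  S1 <- seizure_likelihood(dnm(net, sigma2, K = 1, g = 0.5, t_burn = 3,
                               t_sim = 10))
  expect_true(all(S0 <= S1 + 1e-12))
})

test_that("S is invariant under simultaneous node relabelling", {
  net <- er_net(6, 0.4, seed = 11)
  sigma2 <- seq(0.5, 1.5, length.out = 6)
  S <- seizure_likelihood(dnm(net, sigma2, K = 0.9, g = 0.5, t_burn = 2,
                              t_sim = 10))
  perm <- c(3, 1, 6, 2, 5, 4)
  netp <- list(adjacency = net$adjacency[perm, perm],
               lag = net$lag[perm, perm], labels = net$labels[perm])
  Sp <- seizure_likelihood(dnm(netp, sigma2[perm], K = 0.9, g = 0.5,
                               t_burn = 2, t_sim = 10))
  expect_equal(unname(Sp), unname(S[perm]), tolerance = 1e-10)
})

test_that("biomarker profile reads S at the requested channel", {
  sp <- coupled_spec(n = 5, pairs = rbind(c(1, 2), c(2, 3)), seed = 21)
  seg_bb <- broadband_filter(generate_segment(sp))
  net <- build_network(band_filter(seg_bb, "low_alpha"), seed = 3)
  pr <- biomarker_profile(seg_bb, net, K = 0.02, channel = "CH2",
                          g = 0.5, t_burn = 2, t_sim = 10)
  expect_equal(pr$biomarker_value, unname(pr$S["CH2"]))
  expect_true(all(pr$S >= 0 & pr$S <= 1))
  expect_error(biomarker_profile(seg_bb, net, K = 0.02, channel = "XX",
                                 g = 0.5, t_burn = 2, t_sim = 10), "XX")
})

test_that("patient subjects score higher local coupling than paired controls", {
  n_pairs <- 8
  wins <- 0
  for (seed in seq_len(n_pairs)) {
    pat <- cohort_spec(1, label = "patient", effect = patient_effect(),
                       seed = seed + 400)
    ctl <- cohort_spec(1, label = "control", seed = seed + 400)
    coh <- generate_cohort(pat, ctl)
    val <- vapply(coh, function(s) {
      bb <- broadband_filter(s$segment)
      net <- build_network(band_filter(bb, "low_alpha"), seed = seed)
      sig_all <- channel_variances(bb)
      K <- 1 / mean(sig_all)  # mean node at criticality
      pr <- biomarker_profile(bb, net, K = K, channel = "O1", g = 0.5,
                              t_burn = 3, t_sim = 6)
      mean(pr$S)
    }, 1)
    lab <- cohort_labels(coh)
    wins <- wins + (val[lab == "patient"] >= val[lab == "control"])
  }
  expect_gte(wins / n_pairs, 0.7)
})
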