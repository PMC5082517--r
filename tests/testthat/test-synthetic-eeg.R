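test_that("spec validation names the offending field", {
  expect_error(source_spec(n_channels = 1), "n_channels")
  expect_error(source_spec(alpha_peak = 5), "alpha_peak")
  expect_error(source_spec(duration = 1/3, sample_rate = 256), "duration")
  expect_error(source_spec(n_channels = 3, coupling_matrix = matrix(1, 3, 3)),
               "coupling_matrix")
  expect_error(source_spec(n_channels = 3,
                           phase_lag_matrix = matrix(0.2, 3, 3)),
               "phase_lag_matrix")
  expect_error(source_spec(n_channels = 3, variance_profile = c(1, -1, 1)),
               "variance_profile")
})

test_that("no-coupling no-noise source is a pure oscillation at alpha_peak", {
  sp <- quick_spec(n = 3, alpha_peak = 10, noise_amp = 0, freq_jitter = 0,
                   phase_noise = 0)
  seg <- generate_segment(sp)
  for (ch in 1:3) {
    w <- welch_psd(seg$data[ch, ], seg$sample_rate)
    expect_equal(w$freqs[which.max(w$power)], 10, tolerance = 1e-9)
  }
})

test_that("generation is deterministic given the spec and seed", {
  a <- generate_segment(quick_spec(seed = 42))
  b <- generate_segment(quick_spec(seed = 42))
  expect_identical(a$data, b$data)
  c <- generate_segment(quick_spec(seed = 43))
  expect_false(identical(a$data, c$data))
})

test_that("channel variances match the variance profile exactly", {
  prof <- c(10, 25, 80, 200)
  sp <- source_spec(n_channels = 4, duration = 10, variance_profile = prof,
                    seed = 5)
  seg <- generate_segment(sp)
  expect_equal(unname(apply(seg$data, 1, var)), prof, tolerance = 1e-10)
})

test_that("noise component recovers its spectral slope on a log-log fit", {
  for (beta in c(0.5, 1, 1.5)) {
    sp <- source_spec(n_channels = 2, duration = 20, alpha_power = 0,
                      noise_exponent = beta, variance_profile = c(50, 50),
                      seed = 8)
    seg <- generate_segment(sp)
    w <- welch_psd(seg$data[1, ], 256, window_sec = 4)
    sel <- w$freqs >= 1 & w$freqs <= 40
    fit <- lm(log(w$power[sel]) ~ log(w$freqs[sel]))
    expect_equal(unname(coef(fit)[2]), -beta, tolerance = 0.3)
  }
})

test_that("strong zero-lag coupling locks sources; no coupling leaves them unlocked", {
  n <- 5
  Cs <- matrix(20, n, n); diag(Cs) <- 0
  plf_of <- function(C, seed) {
    sp <- source_spec(n_channels = n, duration = 10, coupling_matrix = C,
                      variance_profile = rep(50, n), seed = seed)
    ph <- attr(generate_segment(sp), "source_phase")
    U <- exp(1i * ph)
    M <- Mod(U %*% Conj(t(U))) / ncol(ph)
    mean(M[upper.tri(M)])
  }
  coupled <- vapply(1:10, function(s) plf_of(Cs, s), 1)
  uncoupled <- vapply(1:10, function(s) plf_of(matrix(0, n, n), s + 100), 1)
  expect_true(all(coupled > 0.9))
  # uncoupled pairs decorrelate towards the finite-sample noise floor
  expect_true(mean(uncoupled) < 0.3)
  expect_true(mean(coupled) > mean(uncoupled) + 0.5)
})

test_that("expected pairwise locking never decreases with coupling strength", {
  n <- 4
  strengths <- c(0, 4, 20)
  mean_plf <- vapply(strengths, function(s) {
    C <- matrix(s, n, n); diag(C) <- 0
    v <- vapply(1:25, function(seed) {
      sp <- source_spec(n_channels = n, duration = 5, coupling_matrix = C,
                        variance_profile = rep(50, n), seed = seed)
      ph <- attr(generate_segment(sp), "source_phase")
      U <- exp(1i * ph)
      M <- Mod(U %*% Conj(t(U))) / ncol(ph)
      mean(M[upper.tri(M)])
    }, 1)
    mean(v)
  }, 1)
  expect_true(all(diff(mean_plf) >= 0))
})

test_that("generate_cohort conserves counts, labels and determinism", {
  pat <- cohort_spec(3, base = quick_spec(n = 4), label = "patient",
                     effect = patient_effect(), seed = 9)
  ctl <- cohort_spec(3, base = quick_spec(n = 4), label = "control", seed = 9)
  coh <- generate_cohort(pat, ctl)
  expect_length(coh, 6L)
  expect_equal(sum(cohort_labels(coh) == "patient"), 3L)
  expect_equal(sum(cohort_labels(coh) == "control"), 3L)
  # controls first by default
  expect_equal(cohort_labels(coh)[1:3], rep("control", 3))
  coh2 <- generate_cohort(pat, ctl)
  expect_identical(coh[[1]]$segment$data, coh2[[1]]$segment$data)
  expect_identical(coh[[6]]$segment$data, coh2[[6]]$segment$data)
  # different arms / subjects differ
  expect_false(identical(coh[[1]]$segment$data, coh[[2]]$segment$data))
})

test_that("patient alpha-peak shift lowers the cohort mean peak frequency", {
  diffs <- vapply(1:5, function(seed) {
    pat <- cohort_spec(6, label = "patient", effect = patient_effect(),
                       seed = seed)
    ctl <- cohort_spec(6, label = "control", seed = seed)
    coh <- generate_cohort(pat, ctl)
    pk <- vapply(coh, function(s) {
      sp <- normalized_spectrum(broadband_filter(s$segment))
      alpha_peak(sp)$peak_freq
    }, 1)
    lab <- cohort_labels(coh)
    mean(pk[lab == "patient"]) - mean(pk[lab == "control"])
  }, 1)
  expect_true(mean(diffs) < 0)
})
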