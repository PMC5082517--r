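# Independent brute-force oracles, deliberately written from first principles
# so they share no code with the package paths they check.

# Scan every candidate cut (midpoints between consecutive sorted values plus
# points beyond the extremes) and report the best sensitivity achievable at
# 100% specificity and the best specificity at 100% sensitivity
# (higher-is-positive orientation).
scan_oracle <- function(values, is_ige) {
  vs <- sort(unique(values))
  cuts <- c(vs[1] - 1, (vs[-1] + vs[-length(vs)]) / 2, vs[length(vs)] + 1)
  best_sens <- 0
  best_spec <- 0
  for (cut in cuts) {
    sens <- mean(values[is_ige] > cut)
    spec <- mean(values[!is_ige] <= cut)
    if (spec == 1) best_sens <- max(best_sens, sens)
    sens2 <- mean(values[is_ige] >= cut)
    spec2 <- mean(values[!is_ige] < cut)
    if (sens2 == 1) best_spec <- max(best_spec, spec2)
  }
  list(sens_at_spec1 = best_sens, spec_at_sens1 = best_spec)
}

# Mid-ranks by explicit counting, then the rank-ANOVA form of the tie-corrected
# Friedman statistic: chi2 = (k-1) * sum_j (R_j - n(k+1)/2)^2 /
# (sum_ij r_ij^2 - n k (k+1)^2 / 4).
friedman_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- m
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      less <- sum(m[i, ] < m[i, j])
      equal <- sum(m[i, ] == m[i, j])
      r[i, j] <- less + (equal + 1) / 2
    }
  }
  Rj <- colSums(r)
  num <- sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  (k - 1) * num / den
}
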