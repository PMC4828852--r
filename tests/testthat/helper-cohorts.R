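# Shared helpers for building small cohorts and independent oracles.

tiny_config <- function(n = 30, effect = 1, miss_rest = 0, miss_stress = 0,
                        seed = 1, group = "test", prevalence = 0.5) {
  cohort_config(
    n_patients = n, prevalence_any = prevalence, effect_size = effect,
    missing_rate_rest = miss_rest, missing_rate_stress = miss_stress,
    group = group, seed = seed
  )
}

# Independent brute-force Youden threshold: scans every midpoint between
# consecutive distinct fitted probabilities, counting the confusion table
# directly; first maximizer wins.
brute_force_threshold <- function(p, y) {
  u <- sort(unique(p))
  cand <- (u[-length(u)] + u[-1]) / 2
  best_j <- -Inf
  best_t <- NA
  for (t in cand) {
    tp <- sum(p >= t & y == 1); fn <- sum(p < t & y == 1)
    tn <- sum(p < t & y == 0); fp <- sum(p >= t & y == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(threshold = best_t, j = best_j)
}

# Independent evaluation of the rescaling transformation, written directly
# from its defining formula.
oracle_rescale <- function(x, b0, b1, t) {
  if (is.na(x)) return(0)
  p <- exp(b0 + b1 * x) / (1 + exp(b0 + b1 * x))
  if (p > t) (p - t) / (1 - t) else (t - p) / t
}
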