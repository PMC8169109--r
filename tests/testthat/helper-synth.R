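# Shared fixture builders. Everything is generated in code under fixed seeds.

quick_session <- function(n_match = 20, n_nonmatch = 20, seed = 1L, ...) {
  simulate_session(behavior_gen_config(n_match_trials = n_match,
                                       n_nonmatch_trials = n_nonmatch,
                                       seed = seed, ...))
}

# A homogeneous-Poisson unit at a given rate, built directly (independent of
# the package's thinning sampler) so it can serve as its oracle counterpart.
poisson_unit <- function(rate_hz, n_trials, span = c(-0.5, 3.0), seed = 1L,
                         sample_hz = rep(c(3, 12), length.out = n_trials),
                         unit_id = "u1", condition = "WM") {
  set.seed(seed)
  spikes <- lapply(seq_len(n_trials), function(i) {
    k <- rpois(1, rate_hz * diff(span))
    sort(runif(k, span[1], span[2]))
  })
  make_unit(spikes, sample_hz, span, unit_id, condition)
}

# Pair-count (Mann-Whitney) AUC with tie half-credit: brute-force oracle.
pair_count_auc <- function(pref, nonpref) {
  cmp <- outer(pref, nonpref, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive permutation null of the threshold-ROC statistic, independent of
# the package's permutation code path.
enumerate_null_auc <- function(pref, nonpref, n_thresholds = 12) {
  pooled <- c(pref, nonpref)
  n1 <- length(pref)
  combn(length(pooled), n1, function(ix)
    roc_value(pooled[ix], pooled[-ix], n_thresholds))
}
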