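test_that("threshold-sweep ROC hits its documented landmark values", {
  # complete separation in either direction
  expect_identical(roc_value(c(10, 12, 11), c(1, 2, 3)), 1)
  expect_identical(roc_value(c(1, 2, 3), c(10, 12, 11)), 0)
  # identical samples: TPR = FPR at every threshold
  expect_equal(roc_value(c(5, 7), c(5, 7)), 0.5)
  # degenerate pooled range
  expect_equal(roc_value(rep(4, 5), rep(4, 8)), 0.5)
  expect_error(roc_value(numeric(0), 1:3), "non-empty")
  # tie-laden case agrees with the pair-count oracle within 0.06
  expect_lt(abs(roc_value(c(3, 5, 5, 8), c(4, 5, 6, 6)) -
                pair_count_auc(c(3, 5, 5, 8), c(4, 5, 6, 6))), 0.06)
})

test_that("ROC stays in [0, 1] and swapping groups reflects it about 0.5", {
  set.seed(21)
  for (i in 1:50) {
    a <- rpois(sample(5:30, 1), 8)
    b <- rpois(sample(5:30, 1), sample(c(4, 8, 16), 1))
    v <- roc_value(a, b)
    expect_gte(v, 0)
    expect_lte(v, 1)
    # strict-inequality thresholds make the reflection exact only up to
    # the threshold discretisation
    expect_lt(abs(roc_value(b, a) - (1 - v)), 1 / 12 + 1e-9)
  }
})

test_that("threshold ROC converges to the pair-count AUC as thresholds grow", {
  set.seed(22)
  worst <- 0
  for (i in 1:200) {
    a <- rgamma(sample(8:40, 1), 4, 0.5)
    b <- rgamma(sample(8:40, 1), sample(2:6, 1), 0.5)
    d <- abs(roc_value(a, b, n_thresholds = 200) - pair_count_auc(a, b))
    worst <- max(worst, d)
  }
  expect_lt(worst, 0.02)
})

test_that("preferred stimulus assignment picks the higher sample-epoch rate", {
  # deterministic unit: 3 kHz trials fire 3 spikes in the sample epoch,
  # 12 kHz trials one spike
  spikes <- c(replicate(6, c(0.02, 0.08, 0.15), simplify = FALSE),
              replicate(6, 0.05, simplify = FALSE))
  u <- make_unit(spikes, rep(c(3, 12), each = 6))
  expect_equal(assign_preferred(u), 3)
  u_rev <- make_unit(rev(spikes), rep(c(3, 12), each = 6))
  expect_equal(assign_preferred(u_rev), 12)
  # exact tie breaks toward the lower frequency
  u_tie <- make_unit(c(replicate(6, 0.05, simplify = FALSE),
                       replicate(6, 0.05, simplify = FALSE)),
                     rep(c(3, 12), each = 6))
  expect_equal(assign_preferred(u_tie), 3)
  expect_error(assign_preferred(make_unit(list(0.1, 0.1, 0.1, 0.1, 0.1),
                                          rep(3, 5))), ">= 2 stimuli")
})

test_that("generator preference labels are recovered from data", {
  s <- quick_session(30, 30, seed = 23)
  hits <- vapply(1:40, function(i) {
    u <- simulate_unit(unit_gen_config(r0 = 4, a_pref = 20, a_nonpref = 10,
                                       preferred_hz = 12, seed = 500 + i), s)
    assign_preferred(u) == 12
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permutation p matches exhaustive enumeration on tiny groups", {
  pref <- c(10, 10, 10); nonpref <- c(0, 0, 0)
  res <- permutation_test(pref, nonpref, exhaustive = TRUE)
  # independent oracle: enumerate all 20 splits and apply the p formula
  null <- enumerate_null_auc(pref, nonpref)
  expect_length(null, 20)
  r_up <- sum(null > res$auc + 1e-12)
  r_lo <- sum(null < res$auc - 1e-12)
  p_oracle <- min(1, 2 * min(r_up + 1, r_lo + 1) / 21)
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$auc, 1)

  # sampled mode with the default convention reaches the minimal attainable
  # p for complete separation and flags it significant
  res_mc <- permutation_test(pref, nonpref,
                             selectivity_config(n_permutations = 1000, seed = 3))
  expect_equal(res_mc$p_value, 2 / 1001)
  expect_true(res_mc$significant)

  # a split with a mid-range statistic also matches the oracle
  pref2 <- c(5, 9, 7, 8); nonpref2 <- c(6, 4, 8)
  res2 <- permutation_test(pref2, nonpref2, exhaustive = TRUE)
  null2 <- enumerate_null_auc(pref2, nonpref2)
  r_up2 <- sum(null2 > res2$auc + 1e-12)
  r_lo2 <- sum(null2 < res2$auc - 1e-12)
  expect_equal(res2$p_value, min(1, 2 * min(r_up2 + 1, r_lo2 + 1) / (length(null2) + 1)))

  expect_error(permutation_test(1:2, 1:3), "at least 6")
  expect_error(selectivity_config(n_permutations = 0), "permutation")
})

test_that("permutation results are bit-reproducible under a fixed seed", {
  set.seed(30)
  a <- rpois(20, 6); b <- rpois(20, 9)
  cfg <- selectivity_config(n_permutations = 500, seed = 99)
  expect_identical(permutation_test(a, b, cfg), permutation_test(a, b, cfg))
})

test_that("type-I rate of the permutation test is near the nominal level", {
  # exchangeable groups; scaled-down replicate count for the unit suite
  set.seed(31)
  sig <- vapply(1:200, function(i) {
    a <- rpois(30, 0.8) / 0.1
    b <- rpois(30, 0.8) / 0.1
    permutation_test(a, b, selectivity_config(n_permutations = 400,
                                              seed = 7000 + i))$significant
  }, logical(1))
  # binomial 99% CI around 0.05 for 200 draws, plus the slight
  # anti-conservativeness of strict tail counting on discrete data
  expect_gt(mean(sig), 0.01)
  expect_lt(mean(sig), 0.12)
})

test_that("roc_timecourse tracks selectivity and its truncation in time", {
  s <- quick_session(30, 30, seed = 24)
  cfg <- selectivity_config(n_permutations = 300, seed = 41)
  u_sel <- simulate_unit(unit_gen_config(r0 = 4, a_pref = 20, a_nonpref = 5,
                                         tau_delay = 0.3,
                                         t_end_from_onset = 1.0, seed = 61), s)
  tc <- roc_timecourse(u_sel, cfg)
  expect_equal(nrow(tc$epochs), 17)  # 0 to 1.7 s in 100 ms steps
  expect_true(all(tc$epochs$auc >= 0 & tc$epochs$auc <= 1))
  # strong selectivity during the stimulus epoch (Poisson(2.4) vs
  # Poisson(0.9) counts in a 100 ms epoch separate to AUC ~ 0.75)
  expect_gt(tc$epochs$auc[1], 0.7)
  # no significant epochs after the truncation (+ one epoch of slack)
  expect_false(any(tc$epochs$significant[tc$epochs$start > 1.1]))

  # a silent unit is degenerate everywhere: AUC 0.5, never significant
  u0 <- make_unit(replicate(60, numeric(0), simplify = FALSE),
                  s$trials$sample_hz)
  tc0 <- roc_timecourse(u0, cfg)
  expect_true(all(tc0$epochs$auc == 0.5))
  expect_false(any(tc0$epochs$significant))

  expect_error(roc_timecourse(u_sel, cfg, to = 5), "beyond the recorded span")
})

test_that("population selectivity aggregates unit timecourses", {
  s <- quick_session(25, 25, seed = 25)
  cfg <- selectivity_config(n_permutations = 200, seed = 55)
  units <- simulate_population(
    6, unit_gen_config(r0 = 4, a_pref = 18, a_nonpref = 6), s, seed = 91)
  pop <- population_selectivity(units, cfg)
  expect_equal(pop$n_units, rep(6, nrow(pop)))
  expect_gt(pop$mean_auc[1], 0.7)        # sample epoch: strong selectivity
  expect_gt(pop$frac_significant[1], 0.5)
  expect_error(population_selectivity(units[1:2], cfg), "at least 3")
})

test_that("condition comparison separates long and short delay selectivity", {
  s <- quick_session(25, 25, seed = 26)
  cfg <- selectivity_config(n_permutations = 200, seed = 66)
  wm <- simulate_population(8, unit_gen_config(r0 = 4, a_pref = 18,
                                               a_nonpref = 6,
                                               t_end_from_onset = 1.0),
                            s, seed = 101)
  pv <- simulate_population(8, passive_unit_config(r0 = 4, a_pref = 18,
                                                   a_nonpref = 6),
                            s, seed = 102)
  cmp <- compare_conditions(wm, pv, cfg)
  # conditions differ where WM delay activity persists but passive has ended
  mid <- cmp$start >= 0.5 & cmp$end <= 1.0
  expect_gt(mean(cmp$mean_auc_a[mid] - cmp$mean_auc_b[mid]), 0)
  # identical settings are exchangeable: few significant epochs
  pv2 <- simulate_population(8, unit_gen_config(r0 = 4, a_pref = 18,
                                                a_nonpref = 6,
                                                t_end_from_onset = 1.0),
                             s, seed = 103)
  cmp_null <- compare_conditions(wm, pv2, cfg)
  expect_lte(sum(cmp_null$significant), 3)
  expect_error(compare_conditions(wm, list(), cfg), ">= 3 units")
})
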