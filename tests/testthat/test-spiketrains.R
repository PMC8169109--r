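test_that("unit inclusion uses a strict 2 Hz whole-session threshold", {
  span <- c(-0.5, 3.0)
  n <- 10
  # exactly 2.0 Hz: 7 spikes per 3.5 s trial
  exact2 <- make_unit(replicate(n, seq(-0.4, 2.9, length.out = 7),
                                simplify = FALSE),
                      rep(3, n), span, "exact2")
  # regular 5 Hz unit: clearly above threshold, no short intervals
  above <- make_unit(replicate(n, seq(-0.45, 2.95, by = 0.2), simplify = FALSE),
                     rep(3, n), span, "above")
  silent <- make_unit(replicate(n, numeric(0), simplify = FALSE),
                      rep(3, n), span, "silent")
  kept <- include_units(list(exact2, above, silent))
  expect_equal(vapply(kept, `[[`, "", "unit_id"), "above")

  # optional contamination screen on short inter-spike intervals
  bursty <- make_unit(replicate(n, seq(0, 0.1, by = 0.001), simplify = FALSE),
                      rep(3, n), span, "bursty")
  expect_gt(short_isi_fraction(bursty), 0.99)
  expect_length(include_units(list(above, bursty), max_short_isi = 0.01), 1)
  expect_length(include_units(list(above, bursty)), 2)
})

test_that("epoch rates are count over duration on half-open windows", {
  expect_equal(epoch_rate(c(0.21, 0.25, 0.29), c(0.2, 0.3)), 30)
  expect_equal(epoch_rate(numeric(0), c(0.2, 0.3)), 0)
  # spike exactly at the right edge is excluded
  expect_equal(epoch_rate(0.3, c(0.2, 0.3)), 0)
  expect_equal(epoch_rate(0.2, c(0.2, 0.3)), 10)
  expect_error(epoch_rate(1, c(0.3, 0.3)), "positive duration")
  # delay-referenced windows resolve by adding the sample duration
  w <- epoch_window(0.3, 0.8, "delay_onset")
  expect_equal(resolve_epoch(w, task_config()), c(0.5, 1.0))
  expect_equal(epoch_rate(0.55, w), 2)
})

test_that("baseline rates cover [-0.5, 0) per trial", {
  u <- make_unit(list(c(-0.4, -0.1), numeric(0), c(-0.6, 0.0, 0.5)),
                 rep(3, 3), span = c(-0.7, 3.0))
  expect_equal(baseline_rates(u), c(4, 0, 0))  # -0.6 outside, 0.0 outside
  u10 <- poisson_unit(10, 200, seed = 8)
  # per-trial rate variance for Poisson counts: (r / w) / n_trials
  expect_lt(abs(mean(baseline_rates(u10)) - 10), 3 * sqrt(10 / 0.5 / 200))
  short <- make_unit(list(numeric(0)), 3, span = c(-0.2, 3.0))
  expect_error(baseline_rates(short), "pre-stimulus")
})

test_that("unsmoothed PSTH conserves spike mass and is linear in trials", {
  u <- poisson_unit(7, 40, seed = 5)
  p <- make_psth(u, sigma = 0)
  bin <- diff(p$bin_edges[1:2])
  expect_equal(sum(p$rate) * bin * p$n_trials, sum(lengths(u$spikes)))
  expect_true(all(p$rate >= 0))
  expect_length(p$rate, length(p$bin_edges) - 1)

  # merged trial set equals the trial-count-weighted mean of subset PSTHs
  p1 <- make_psth(u, sigma = 0, trial_filter = 1:15)
  p2 <- make_psth(u, sigma = 0, trial_filter = 16:40)
  expect_equal(p$rate, (15 * p1$rate + 25 * p2$rate) / 40)
})

test_that("single spike with no smoothing lands in a single bin", {
  u <- make_unit(list(0.105), 3, span = c(-0.5, 3.0))
  p <- make_psth(u, sigma = 0)
  expect_equal(sum(p$rate > 0), 1)
  expect_equal(max(p$rate), 100)  # 1 / (1 trial * 10 ms)
})

test_that("Gaussian smoothing preserves a constant rate, including edges", {
  u <- poisson_unit(10, 200, seed = 6)
  p <- make_psth(u, sigma = 0.1)
  expect_true(all(abs(p$rate - 10) < 1))
  # kernel is mass-preserving for interior bins: smoothing a constant
  # vector returns it to numerical precision
  flat <- make_unit(list(seq(-0.45, 2.95, by = 0.1)), 3, span = c(-0.5, 3.0))
  p0 <- make_psth(flat, sigma = 0)
  ps <- make_psth(flat, sigma = 0.1)
  expect_lt(abs(mean(ps$rate) - mean(p0$rate)) / mean(p0$rate), 0.005)
  expect_error(make_psth(u, sigma = -0.1), "sigma")
})

test_that("population PSTH is the unweighted mean over units", {
  us <- lapply(1:3, function(i) poisson_unit(i * 4, 30, seed = 20 + i))
  pop <- make_psth(us, sigma = 0)
  per <- lapply(us, make_psth, sigma = 0)
  expect_equal(pop$rate, (per[[1]]$rate + per[[2]]$rate + per[[3]]$rate) / 3)
  expect_equal(pop$n_units, 3)
})

test_that("responsiveness screen flags evoked units and spares null units", {
  s <- quick_session(25, 25, seed = 9)
  flagged <- vapply(1:20, function(i) {
    u <- simulate_unit(unit_gen_config(r0 = 5, a_pref = 15, a_nonpref = 15,
                                       seed = 300 + i), s)
    responsiveness(u)$task_related
  }, logical(1))
  expect_gte(mean(flagged), 0.99)

  # null units: flagged at roughly the family-wise rate of the epoch set,
  # bounded well away from certainty
  null_flagged <- vapply(1:60, function(i) {
    u <- simulate_unit(unit_gen_config(r0 = 8, a_pref = 0, a_nonpref = 0,
                                       seed = 400 + i), s)
    responsiveness(u)$task_related
  }, logical(1))
  expect_lt(mean(null_flagged), 0.6)

  one_trial <- make_unit(list(c(0.1)), 3)
  expect_error(responsiveness(one_trial), "at least 5")
})

test_that("significance timecourse recovers the delay-activity truncation", {
  s <- quick_session(30, 30, seed = 10)
  units <- simulate_population(
    30, unit_gen_config(r0 = 4, a_pref = 18, a_nonpref = 18,
                        tau_delay = 0.3, t_end_from_onset = 1.0),
    s, seed = 77)
  tc <- bin_significance_timecourse(units, from = 0, to = 1.7)
  early <- tc$start >= 0 & tc$end <= 0.7
  late <- tc$start >= 1.1
  expect_gt(min(tc$frac_units_sig[early]), 0.5)
  expect_lte(max(tc$frac_units_sig[late]), 0.15)
  expect_true(all(tc$population_sig[early]))
  expect_error(bin_significance_timecourse(units[1:2]), "at least 3")
})

test_that("passive preset yields a shorter significant span than WM", {
  s <- quick_session(30, 30, seed = 11)
  mk <- function(cfg) simulate_population(25, cfg, s, seed = 88)
  wm <- mk(unit_gen_config(r0 = 4, a_pref = 18, a_nonpref = 18,
                           t_end_from_onset = 1.0))
  pv <- mk(passive_unit_config(r0 = 4, a_pref = 18, a_nonpref = 18))
  span_of <- function(us) {
    tc <- bin_significance_timecourse(us, from = 0, to = 1.7)
    sum(tc$frac_units_sig > 0.5)
  }
  expect_lt(span_of(pv), span_of(wm))
})

test_that("time-shifting spikes and windows leaves statistics unchanged", {
  u <- poisson_unit(9, 30, seed = 14)
  shift <- 0.37
  u_sh <- make_unit(lapply(u$spikes, `+`, shift), u$sample_hz,
                    u$span + shift, u$unit_id)
  expect_equal(unit_mean_rate(u_sh), unit_mean_rate(u))
  expect_equal(unit_epoch_rates(u_sh, c(0.2, 0.3) + shift),
               unit_epoch_rates(u, c(0.2, 0.3)))
  expect_equal(make_psth(u_sh, sigma = 0.05)$rate,
               make_psth(u, sigma = 0.05)$rate)
  expect_equal(roc_value(unit_epoch_rates(u_sh, c(0, 0.1) + shift)[1:15],
                         unit_epoch_rates(u_sh, c(0, 0.1) + shift)[16:30]),
               roc_value(unit_epoch_rates(u, c(0, 0.1))[1:15],
                         unit_epoch_rates(u, c(0, 0.1))[16:30]))
})
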