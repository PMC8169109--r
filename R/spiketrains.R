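#' Construct a unit from per-trial spike-time lists
#'
#' Builds the trial-aligned unit container used throughout the analyses.
#' Spike times are seconds from sample onset; every trial must have exactly
#' one (possibly empty) spike vector.
#'
#' @param spikes list of numeric vectors, one per trial, each sorted.
#' @param sample_hz sample stimulus identity per trial.
#' @param span recorded span `c(t_start, t_end)` (s).
#' @param unit_id unit identifier.
#' @param condition `"WM"` or `"passive"`.
#' @param trial_id trial ids; default `seq_along(spikes)`.
#' @return a `wm_unit`.
#' @export
make_unit <- function(spikes, sample_hz, span = c(-0.5, 3.0), unit_id = "u1",
                      condition = "WM", trial_id = seq_along(spikes)) {
  stopifnot(is.list(spikes), length(sample_hz) == length(spikes),
            length(trial_id) == length(spikes), length(span) == 2)
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    if (length(s) && (is.unsorted(s) || s[1] < span[1] - 1e-9 ||
                      s[length(s)] > span[2] + 1e-9))
      stop("spike times in trial ", i, " unsorted or outside the span")
  }
  new_unit(unit_id, condition, trial_id, spikes, span, sample_hz)
}

#' Whole-session mean firing rate of a unit
#' @param unit a `wm_unit`.
#' @return rate in Hz: total spikes / (n_trials * recorded span).
#' @export
unit_mean_rate <- function(unit) {
  stopifnot(inherits(unit, "wm_unit"))
  span <- diff(unit$span)
  sum(lengths(unit$spikes)) / (length(unit$spikes) * span)
}

#' Fraction of inter-spike intervals shorter than a refractory cutoff
#'
#' Quality-control statistic: a well-isolated single unit should have
#' essentially no inter-spike intervals below ~2 ms.
#'
#' @param unit a `wm_unit`.
#' @param cutoff_s interval cutoff (s).
#' @return fraction in [0, 1]; 0 for units with < 2 spikes.
#' @export
short_isi_fraction <- function(unit, cutoff_s = 0.002) {
  isi <- unlist(lapply(unit$spikes, function(s) if (length(s) > 1) diff(s) else numeric(0)))
  if (!length(isi)) return(0)
  mean(isi < cutoff_s)
}

#' Unit inclusion filter
#'
#' Keeps units whose whole-session mean firing rate strictly exceeds
#' `min_rate` (default 2 Hz). Optionally also drops units whose fraction of
#' inter-spike intervals below 2 ms exceeds `max_short_isi`, as a
#' contamination screen.
#'
#' @param units list of `wm_unit`.
#' @param min_rate inclusion threshold (Hz); strict inequality.
#' @param max_short_isi if non-`NULL`, maximum tolerated short-ISI fraction.
#' @return filtered list of `wm_unit`.
#' @export
include_units <- function(units, min_rate = 2, max_short_isi = NULL) {
  keep <- vapply(units, function(u) {
    ok <- unit_mean_rate(u) > min_rate
    if (ok && !is.null(max_short_isi)) ok <- short_isi_fraction(u) <= max_short_isi
    ok
  }, logical(1))
  units[keep]
}

#' Firing rate of one spike train in a window
#'
#' Count of spikes in the half-open window `[start, end)` divided by the
#' window duration.
#'
#' @param spike_times numeric spike times (s).
#' @param window numeric `c(start, end)` or a [epoch_window()] (resolved
#'   against `task`).
#' @param task a [task_config()] used to resolve delay-referenced windows.
#' @return rate in Hz.
#' @export
epoch_rate <- function(spike_times, window, task = task_config()) {
  w <- if (inherits(window, "wm_epoch")) resolve_epoch(window, task) else window
  # snap the duration to 1 ns so equal-width windows at different offsets
  # yield identical rate values (floating-point subtraction would otherwise
  # break rate ties across windows)
  dur <- round(w[2] - w[1], 9)
  if (dur <= 0) stop("window must have positive duration")
  sum(spike_times >= w[1] & spike_times < w[2]) / dur
}

#' Per-trial epoch rates for a unit
#' @inheritParams epoch_rate
#' @param unit a `wm_unit`.
#' @return numeric vector, one rate per trial.
#' @export
unit_epoch_rates <- function(unit, window, task = task_config()) {
  w <- if (inherits(window, "wm_epoch")) resolve_epoch(window, task) else window
  dur <- round(w[2] - w[1], 9)  # see epoch_rate
  if (dur <= 0) stop("window must have positive duration")
  vapply(unit$spikes, function(s) sum(s >= w[1] & s < w[2]), numeric(1)) / dur
}

#' Per-trial baseline firing rates
#'
#' The baseline period is the 0.5 s immediately preceding the sample onset,
#' `[-0.5, 0)`.
#'
#' @param unit a `wm_unit`.
#' @param baseline_s baseline duration (s).
#' @return numeric vector of rates (Hz), one per trial.
#' @export
baseline_rates <- function(unit, baseline_s = 0.5) {
  stopifnot(inherits(unit, "wm_unit"))
  if (unit$span[1] > -baseline_s + 1e-9) {
    stop("recording lacks a ", baseline_s, " s pre-stimulus window")
  }
  unit_epoch_rates(unit, c(-baseline_s, 0))
}

#' Peri-stimulus time histogram (PSTH)
#'
#' Bins spikes at `bin` (10 ms default) across trials, converts to rate
#' (count / (n_trials * bin)), and smooths with a Gaussian kernel of
#' standard deviation `sigma` (100 ms default). The kernel is truncated at
#' +/- 4 sigma, unit-normalised, and convolution is edge-renormalised (each
#' bin divided by the kernel mass that fell inside the span) so a constant
#' rate is preserved at the borders. `sigma = 0` skips smoothing. When given
#' a list of units, returns the unweighted mean of the per-unit PSTHs.
#'
#' @param x a `wm_unit` or list of `wm_unit` with identical spans.
#' @param bin bin width (s).
#' @param sigma Gaussian kernel sd (s); 0 for no smoothing.
#' @param trial_filter optional logical/integer vector selecting trials
#'   (applied per unit).
#' @return A `wm_psth`: list(bin_edges, rate, n_trials, smoothing_sigma,
#'   smoothed).
#' @export
make_psth <- function(x, bin = 0.01, sigma = 0.1, trial_filter = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (inherits(x, "wm_unit")) {
    return(psth_one(x, bin, sigma, trial_filter))
  }
  stopifnot(is.list(x), length(x) >= 1)
  ps <- lapply(x, psth_one, bin = bin, sigma = sigma, trial_filter = trial_filter)
  edges <- ps[[1]]$bin_edges
  for (p in ps) {
    if (length(p$bin_edges) != length(edges) || max(abs(p$bin_edges - edges)) > 1e-9)
      stop("units must share an identical recorded span for a population PSTH")
  }
  structure(list(bin_edges = edges,
                 rate = Reduce(`+`, lapply(ps, `[[`, "rate")) / length(ps),
                 n_trials = NA_integer_, n_units = length(ps),
                 smoothing_sigma = sigma, smoothed = sigma > 0),
            class = "wm_psth")
}

psth_one <- function(unit, bin, sigma, trial_filter) {
  spikes <- unit$spikes
  if (!is.null(trial_filter)) spikes <- spikes[trial_filter]
  if (!length(spikes)) stop("no trials left after filtering")
  edges <- seq(unit$span[1], unit$span[2], by = bin)
  counts <- numeric(length(edges) - 1)
  all_sp <- unlist(spikes)
  all_sp <- all_sp[all_sp >= edges[1] & all_sp < edges[length(edges)]]
  if (length(all_sp)) {
    idx <- findInterval(all_sp, edges, left.open = FALSE)
    tab <- tabulate(idx, nbins = length(counts))
    counts <- tab
  }
  rate <- counts / (length(spikes) * bin)
  if (sigma > 0) rate <- smooth_gaussian(rate, bin, sigma)
  structure(list(bin_edges = edges, rate = rate, n_trials = length(spikes),
                 smoothing_sigma = sigma, smoothed = sigma > 0),
            class = "wm_psth")
}

# Gaussian smoothing with +/-4 sigma truncation and edge renormalisation.
smooth_gaussian <- function(rate, bin, sigma) {
  half <- max(1L, ceiling(4 * sigma / bin))
  k <- stats::dnorm(seq(-half, half) * bin, sd = sigma)
  k <- k / sum(k)
  n <- length(rate)
  num <- stats::filter(c(rep(0, half), rate, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  out <- (num / den)[(half + 1):(half + n)]
  as.numeric(out)
}

#' @export
print.wm_psth <- function(x, ...) {
  cat(sprintf("<wm_psth> %d bins of %g ms over [%.2f, %.2f] s, %s\n",
              length(x$rate), diff(x$bin_edges[1:2]) * 1000,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              if (x$smoothed) sprintf("Gaussian sigma = %g ms", x$smoothing_sigma * 1000)
              else "unsmoothed"))
  invisible(x)
}

#' Default epoch set for the responsiveness screen
#'
#' The sample epoch plus successive 100 ms delay bins up to the end of the
#' delay period.
#'
#' @param task a [task_config()].
#' @return list of `wm_epoch`.
#' @export
default_response_epochs <- function(task = task_config()) {
  delay_end <- task$sample_s + task$delay_s
  c(list(epoch_window(0, task$sample_s, "sample_onset", label = "sample")),
    tile_epochs(task$sample_s, delay_end, 0.1))
}

#' Task-relatedness screen for one unit
#'
#' For each epoch, the per-trial epoch rates are compared to the per-trial
#' baseline rates with a paired t-test. A unit is flagged task-related if any
#' epoch reaches p < `alpha`; no multiple-comparison correction is applied.
#' Epochs with zero-variance rate differences are skipped with a warning.
#'
#' @param unit a `wm_unit` with >= 5 trials.
#' @param epochs list of [epoch_window()]s; default [default_response_epochs()].
#' @param alpha significance level.
#' @param task a [task_config()].
#' @return list(task_related, p_values, epochs).
#' @export
responsiveness <- function(unit, epochs = NULL, alpha = 0.05,
                           task = task_config()) {
  stopifnot(inherits(unit, "wm_unit"))
  if (length(unit$spikes) < 5) stop("need at least 5 trials")
  epochs <- epochs %||% default_response_epochs(task)
  base <- baseline_rates(unit)
  p <- vapply(epochs, function(e) {
    r <- unit_epoch_rates(unit, e, task)
    d <- r - base
    if (stats::sd(d) == 0) {
      warning("zero-variance differences in epoch ",
              if (inherits(e, "wm_epoch")) e$label else "window", "; skipped")
      return(NA_real_)
    }
    stats::t.test(r, base, paired = TRUE)$p.value
  }, numeric(1))
  list(task_related = any(p < alpha, na.rm = TRUE), p_values = p,
       epochs = epochs)
}

#' Baseline-referenced significance timecourse across a population
#'
#' Tiles the span from sample onset in successive `binwidth` (100 ms) bins
#' and, for each bin, reports (i) a population-level Wilcoxon rank-sum test
#' of per-unit mean bin rates against per-unit mean baseline rates, and
#' (ii) the fraction of units individually significant in that bin, where
#' each unit is tested with a Wilcoxon rank-sum of its per-trial bin rates
#' against its baseline rates computed in sub-bins of the same `binwidth`
#' (all baseline sub-bins of all trials pooled). Matching the bin width on
#' both sides keeps the rank-sum exchangeable under the null: rates from
#' windows of different durations have different count granularity, which a
#' rank test would otherwise flag even at equal mean rate.
#'
#' @param units list of >= 3 `wm_unit` sharing task timing.
#' @param from,to tiled range (s from sample onset); default sample onset to
#'   the end of the units' recorded span.
#' @param binwidth bin width (s).
#' @param alpha significance level.
#' @param task a [task_config()].
#' @return data frame: `start`, `end`, `population_p`, `population_sig`,
#'   `frac_units_sig`.
#' @export
bin_significance_timecourse <- function(units, from = 0, to = NULL,
                                        binwidth = 0.1, alpha = 0.05,
                                        task = task_config()) {
  if (length(units) < 3) stop("need at least 3 units for the population test")
  to <- to %||% min(vapply(units, function(u) u$span[2], numeric(1)))
  starts <- seq(from, to - binwidth + 1e-9, by = binwidth)
  base_starts <- seq(-0.5, -binwidth + 1e-9, by = binwidth)
  base_binned <- lapply(units, function(u) {
    unlist(lapply(base_starts, function(b)
      unit_epoch_rates(u, c(b, b + binwidth), task)))
  })
  base_means <- vapply(lapply(units, baseline_rates), mean, numeric(1))
  out <- lapply(starts, function(s) {
    w <- c(s, s + binwidth)
    rates <- lapply(units, unit_epoch_rates, window = w, task = task)
    unit_means <- vapply(rates, mean, numeric(1))
    pop_p <- suppressWarnings(
      stats::wilcox.test(unit_means, base_means, exact = FALSE)$p.value)
    unit_p <- vapply(seq_along(units), function(i) {
      suppressWarnings(
        stats::wilcox.test(rates[[i]], base_binned[[i]], exact = FALSE)$p.value)
    }, numeric(1))
    data.frame(start = w[1], end = w[2], population_p = pop_p,
               population_sig = is.finite(pop_p) && pop_p < alpha,
               frac_units_sig = mean(unit_p < alpha, na.rm = TRUE))
  })
  do.call(rbind, out)
}
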