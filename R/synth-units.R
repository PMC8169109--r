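#' Configuration for the synthetic single-unit generator
#'
#' Parameterises a piecewise trial-aligned rate function: baseline `r0`
#' everywhere, a phasic response of amplitude `a_pref` or `a_nonpref`
#' (depending on the sample stimulus) during the stimulus, an exponential
#' decay of that response with time constant `tau_delay` after stimulus
#' offset, and a hard truncation of all above-baseline activity
#' `t_end_from_onset` seconds after stimulus ONSET. Tying the truncation to
#' onset rather than offset reflects delay activity that lasts a fixed time
#' from stimulus onset regardless of stimulus duration; the default 1.0 s
#' gives elevated activity through the stimulus and ~800 ms into the delay.
#' The passive-listening condition uses a shorter truncation (see
#' [passive_unit_config()]).
#'
#' @param r0 baseline rate (Hz), >= 0.
#' @param a_pref,a_nonpref evoked amplitudes (Hz) for the preferred and
#'   nonpreferred sample stimulus, >= 0.
#' @param preferred_hz preferred sample stimulus identity (kHz label).
#' @param stim_onset,stim_duration stimulus timing (s from sample onset).
#' @param tau_delay decay constant of post-offset activity (s), > 0.
#' @param t_end_from_onset truncation of above-baseline activity, measured
#'   from stimulus onset (s).
#' @param condition `"WM"` (task engaged) or `"passive"`.
#' @param seed RNG seed for spike sampling.
#' @return An object of class `wm_unit_cfg`.
#' @export
unit_gen_config <- function(r0 = 5, a_pref = 15, a_nonpref = 5,
                            preferred_hz = 3,
                            stim_onset = 0, stim_duration = 0.2,
                            tau_delay = 0.3, t_end_from_onset = 1.0,
                            condition = c("WM", "passive"), seed = 1L) {
  condition <- match.arg(condition)
  if (r0 < 0 || a_pref < 0 || a_nonpref < 0) stop("rates and amplitudes must be >= 0")
  if (tau_delay <= 0) stop("tau_delay must be positive")
  if (t_end_from_onset <= 0) stop("t_end_from_onset must be positive")
  structure(list(r0 = r0, a_pref = a_pref, a_nonpref = a_nonpref,
                 preferred_hz = preferred_hz,
                 stim_onset = stim_onset, stim_duration = stim_duration,
                 tau_delay = tau_delay, t_end_from_onset = t_end_from_onset,
                 condition = condition, seed = as.integer(seed)),
            class = "wm_unit_cfg")
}

#' Passive-listening preset for the unit generator
#'
#' Same structure as [unit_gen_config()] but with delay activity truncated
#' much earlier (default 0.5 s from stimulus onset) and a faster decay. The
#' truncation value is a free generator parameter, not an estimate.
#'
#' @param t_end_from_onset truncation (s); default 0.5.
#' @param tau_delay decay constant (s); default 0.15.
#' @param ... passed to [unit_gen_config()].
#' @export
passive_unit_config <- function(t_end_from_onset = 0.5, tau_delay = 0.15, ...) {
  unit_gen_config(t_end_from_onset = t_end_from_onset, tau_delay = tau_delay,
                  condition = "passive", ...)
}

#' Trial-aligned firing-rate function of a synthetic unit
#'
#' Piecewise intensity, in Hz, for a given sample stimulus:
#' \deqn{r(t) = r_0 \; (t < onset);\quad r_0 + a_s \; (onset \le t < offset);}
#' \deqn{r_0 + a_s e^{-(t - offset)/\tau} \; (offset \le t < onset + T_{end});\quad r_0 \; after,}
#' where \eqn{a_s} is `a_pref` or `a_nonpref` and \eqn{T_{end}} =
#' `t_end_from_onset`. All segments are half-open on the right.
#'
#' @param t time(s) in seconds from sample onset; vectorised.
#' @param stimulus_hz sample stimulus identity.
#' @param cfg a [unit_gen_config()].
#' @return numeric rate(s) in Hz, same length as `t`.
#' @export
rate_function <- function(t, stimulus_hz, cfg) {
  stopifnot(inherits(cfg, "wm_unit_cfg"))
  a <- if (identical(stimulus_hz, cfg$preferred_hz)) cfg$a_pref else cfg$a_nonpref
  onset <- cfg$stim_onset
  offset <- onset + cfg$stim_duration
  t_end <- onset + cfg$t_end_from_onset
  r <- rep(cfg$r0, length(t))
  in_stim <- t >= onset & t < min(offset, t_end)
  in_decay <- t >= offset & t < t_end
  r[in_stim] <- cfg$r0 + a
  r[in_decay] <- cfg$r0 + a * exp(-(t[in_decay] - offset) / cfg$tau_delay)
  r
}

#' Simulate spike trains for one unit over a session
#'
#' Samples an inhomogeneous Poisson process with intensity [rate_function()]
#' independently on every trial, by Bernoulli thinning on a 1 ms grid (the
#' rate is treated as constant within each 1 ms bin, exact enough for the
#' 100 ms-epoch statistics downstream). Spike times are uniform within their
#' 1 ms bin, trial-aligned, and sorted.
#'
#' @param cfg a [unit_gen_config()].
#' @param session a `wm_session` whose trials provide sample identities.
#' @param unit_id identifier stored on the unit.
#' @param span recorded span `c(t_start, t_end)`; default [trial_span()] of
#'   the session task.
#' @return A `wm_unit`: list(unit_id, condition, trial_id, spikes, span,
#'   sample_hz), with one (possibly empty) spike vector per trial.
#' @export
simulate_unit <- function(cfg, session, unit_id = "u1", span = NULL) {
  stopifnot(inherits(cfg, "wm_unit_cfg"), inherits(session, "wm_session"))
  n <- nrow(session$trials)
  if (n == 0) stop("session has no trials")
  span <- span %||% trial_span(session$task)
  dt <- 1e-3
  grid <- seq(span[1], span[2] - dt / 2, by = dt)
  restore <- set_local_seed(cfg$seed)
  on.exit(restore())
  spikes <- vector("list", n)
  # rate profile depends only on stimulus identity; precompute both
  prof <- lapply(unique(session$trials$sample_hz), function(s)
    pmin(1, rate_function(grid, s, cfg) * dt))
  names(prof) <- as.character(unique(session$trials$sample_hz))
  for (i in seq_len(n)) {
    p <- prof[[as.character(session$trials$sample_hz[i])]]
    hit <- stats::runif(length(grid)) < p
    spikes[[i]] <- grid[hit] + stats::runif(sum(hit), 0, dt)
  }
  new_unit(unit_id, cfg$condition, session$trials$trial_id, spikes, span,
           session$trials$sample_hz)
}

new_unit <- function(unit_id, condition, trial_id, spikes, span, sample_hz) {
  structure(list(unit_id = unit_id, condition = condition,
                 trial_id = trial_id, spikes = spikes, span = span,
                 sample_hz = sample_hz),
            class = "wm_unit")
}

#' @export
print.wm_unit <- function(x, ...) {
  cat(sprintf("<wm_unit> %s (%s): %d trials, %d spikes, mean rate %.2f Hz\n",
              x$unit_id, x$condition, length(x$spikes),
              sum(lengths(x$spikes)), unit_mean_rate(x)))
  invisible(x)
}

#' Simulate a population of independent units
#'
#' Per-unit seeds are derived deterministically from `seed` so the whole
#' population is reproducible and units are mutually independent.
#'
#' @param n_units number of units, >= 1.
#' @param cfg_sampler either a single [unit_gen_config()] used for every
#'   unit, a list of length `n_units`, or a `function(i)` returning the
#'   config for unit `i` (its `seed` field is overwritten).
#' @param session a `wm_session`.
#' @param seed master seed.
#' @param id_prefix prefix for generated unit ids.
#' @return list of `wm_unit`.
#' @export
simulate_population <- function(n_units, cfg_sampler, session, seed = 1L,
                                id_prefix = "unit") {
  if (n_units < 1) stop("n_units must be >= 1")
  get_cfg <- if (inherits(cfg_sampler, "wm_unit_cfg")) {
    function(i) cfg_sampler
  } else if (is.function(cfg_sampler)) {
    cfg_sampler
  } else if (is.list(cfg_sampler)) {
    if (length(cfg_sampler) != n_units) stop("config list length must equal n_units")
    function(i) cfg_sampler[[i]]
  } else stop("cfg_sampler must be a config, a list of configs, or a function")
  # draw config choices (if any) under the master seed, then give each unit
  # its own derived stream
  restore <- set_local_seed(seed)
  cfgs <- lapply(seq_len(n_units), get_cfg)
  restore()
  lapply(seq_len(n_units), function(i) {
    cfg <- cfgs[[i]]
    cfg$seed <- (as.integer(seed) %% 100000L) * 10000L + i
    simulate_unit(cfg, session, unit_id = sprintf("%s%03d", id_prefix, i))
  })
}
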