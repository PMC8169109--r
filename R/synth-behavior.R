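#' Configuration for the synthetic session generator
#'
#' Defines the outcome probabilities of a simulated subject and, optionally, a
#' laser (optogenetic inactivation) manipulation. Laser ON and OFF trials are
#' randomly interleaved; the laser shifts the hit and false-alarm
#' probabilities only when its window covers at least half of the
#' `effective_window`, the task period (default: stimulus plus early delay,
#' 0.2-1.0 s from sample onset) in which inactivation is behaviorally
#' effective. Shifted probabilities are clamped to [0, 1].
#'
#' @param n_match_trials,n_nonmatch_trials trial counts per type.
#' @param p_hit,p_fa baseline hit and false-alarm probabilities.
#' @param laser_window `c(start, end)` s from sample onset, or `NULL`.
#' @param delta_p_hit_laser,delta_p_fa_laser signed probability shifts applied
#'   on laser-ON trials when the laser overlaps the effective window.
#' @param effective_window `c(start, end)` s; period in which the laser acts.
#' @param p_laser probability that a trial is laser-ON when a window is set.
#' @param distractor_window optional `c(start, end)` s noise-distractor window
#'   annotated on every trial (e.g. 0.3-0.5 s).
#' @param task a [task_config()] giving trial timing.
#' @param seed RNG seed for the session draw.
#'
#' @return An object of class `wm_behavior_cfg`.
#' @export
behavior_gen_config <- function(n_match_trials = 100, n_nonmatch_trials = 100,
                                p_hit = 0.9, p_fa = 0.25,
                                laser_window = NULL,
                                delta_p_hit_laser = 0, delta_p_fa_laser = 0,
                                effective_window = c(0.2, 1.0),
                                p_laser = 0.5,
                                distractor_window = NULL,
                                task = task_config(), seed = 1L) {
  if (n_match_trials + n_nonmatch_trials < 1) stop("at least one trial required")
  for (p in c(p_hit, p_fa)) {
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  chk_win <- function(w, nm) {
    if (!is.null(w) && (length(w) != 2 || w[1] >= w[2]))
      stop(nm, " must be c(start, end) with start < end")
  }
  chk_win(laser_window, "laser_window")
  chk_win(effective_window, "effective_window")
  chk_win(distractor_window, "distractor_window")
  structure(list(n_match_trials = as.integer(n_match_trials),
                 n_nonmatch_trials = as.integer(n_nonmatch_trials),
                 p_hit = p_hit, p_fa = p_fa,
                 laser_window = laser_window,
                 delta_p_hit_laser = delta_p_hit_laser,
                 delta_p_fa_laser = delta_p_fa_laser,
                 effective_window = effective_window,
                 p_laser = p_laser,
                 distractor_window = distractor_window,
                 task = task, seed = as.integer(seed)),
            class = "wm_behavior_cfg")
}

#' Does the configured laser window engage the behavioral effect?
#'
#' The effect is gated on the laser window covering at least 50% of the
#' effective window, collapsing "early vs late delay" inactivation timing
#' into a single overlap rule.
#'
#' @param cfg a [behavior_gen_config()].
#' @return logical.
#' @export
laser_effect_active <- function(cfg) {
  stopifnot(inherits(cfg, "wm_behavior_cfg"))
  if (is.null(cfg$laser_window)) return(FALSE)
  lw <- cfg$laser_window; ew <- cfg$effective_window
  ov <- max(0, min(lw[2], ew[2]) - max(lw[1], ew[1]))
  ov / (ew[2] - ew[1]) >= 0.5
}

clamp01 <- function(p) pmin(1, pmax(0, p))

#' Simulate one behavioral session
#'
#' Draws a randomly interleaved trial sequence of match and nonmatch trials
#' (3 kHz / 12 kHz sample-test tone pairs), assigns laser ON/OFF labels when a
#' laser window is configured, draws trial outcomes from the (possibly laser-
#' shifted) hit / false-alarm probabilities, and places lick times uniformly
#' inside the response window for lick outcomes (hit, FA). Miss and CR trials
#' have no licks. Only response-window membership of licks matters downstream,
#' so no licking microstructure is modeled.
#'
#' @param cfg a [behavior_gen_config()].
#' @return A `wm_session`: list with a `trials` data frame (format of
#'   [read_trials()]), the task config, and generator provenance.
#' @export
#' @examples
#' s <- simulate_session(behavior_gen_config(n_match_trials = 20,
#'                                           n_nonmatch_trials = 20, seed = 7))
#' session_metrics(classify_trials(s))
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "wm_behavior_cfg"))
  n <- cfg$n_match_trials + cfg$n_nonmatch_trials
  task <- cfg$task
  withr_seed <- set_local_seed(cfg$seed)
  on.exit(withr_seed())

  is_match <- sample(rep(c(TRUE, FALSE), c(cfg$n_match_trials, cfg$n_nonmatch_trials)))
  sample_hz <- sample(c(3, 12), n, replace = TRUE)
  test_hz <- ifelse(is_match, sample_hz, ifelse(sample_hz == 3, 12, 3))
  if (task$task_type != "DMS") test_hz <- rep(NA_real_, n)

  laser_on <- if (is.null(cfg$laser_window)) rep(FALSE, n) else
    stats::runif(n) < cfg$p_laser
  effect <- laser_on & laser_effect_active(cfg)

  p_hit_eff <- clamp01(cfg$p_hit + ifelse(effect, cfg$delta_p_hit_laser, 0))
  p_fa_eff  <- clamp01(cfg$p_fa  + ifelse(effect, cfg$delta_p_fa_laser, 0))
  lick_p <- ifelse(is_match, p_hit_eff, p_fa_eff)
  licks <- stats::runif(n) < lick_p

  rw <- response_window(task)
  lick_times <- vector("list", n)
  for (i in seq_len(n)) {
    if (licks[i]) {
      k <- 1L + stats::rpois(1, 2)
      lick_times[[i]] <- sort(stats::runif(k, rw[1], rw[2] - 1e-6))
    } else lick_times[[i]] <- numeric(0)
  }

  trials <- data.frame(
    trial_id = seq_len(n),
    task_type = task$task_type,
    sample_hz = sample_hz,
    test_hz = test_hz,
    is_match = is_match,
    delay_s = task$delay_s,
    laser_start_s = ifelse(laser_on, (cfg$laser_window %||% c(NA, NA))[1], NA_real_),
    laser_end_s   = ifelse(laser_on, (cfg$laser_window %||% c(NA, NA))[2], NA_real_),
    distractor_start_s = (cfg$distractor_window %||% c(NA, NA))[1],
    distractor_end_s   = (cfg$distractor_window %||% c(NA, NA))[2],
    stringsAsFactors = FALSE)
  trials$lick_times_s <- I(lick_times)

  structure(list(trials = trials, task = task,
                 provenance = list(seed = cfg$seed, generator = "simulate_session")),
            class = "wm_session")
}

#' @export
print.wm_session <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("<wm_session> %d trials (%d match / %d nonmatch), task %s, delay %g s\n",
              n, sum(x$trials$is_match), sum(!x$trials$is_match),
              x$task$task_type, x$task$delay_s))
  if (any(!is.na(x$trials$laser_start_s)))
    cat(sprintf("  laser ON trials: %d\n", sum(!is.na(x$trials$laser_start_s))))
  invisible(x)
}

#' Is a trial laser-ON?
#' @param session a `wm_session`.
#' @return logical vector, one element per trial.
#' @export
laser_on_trials <- function(session) {
  stopifnot(inherits(session, "wm_session"))
  !is.na(session$trials$laser_start_s)
}

# Seed scoping: set the RNG seed, return a restore function. Keeps generator
# determinism without clobbering the caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
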