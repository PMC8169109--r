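#' Write / read a session trial table
#'
#' Flat UTF-8 CSV, one row per trial, header
#' `trial_id,task_type,sample_hz,test_hz,is_match,delay_s,laser_start_s,
#' laser_end_s,distractor_start_s,distractor_end_s,lick_times_s`.
#' `lick_times_s` is a semicolon-separated list; absent intervals and empty
#' lick lists are empty fields. All times are seconds from sample onset.
#'
#' @param session a `wm_session`.
#' @param path output file.
#' @export
write_trials <- function(session, path) {
  stopifnot(inherits(session, "wm_session"))
  tr <- session$trials
  out <- tr[, c("trial_id", "task_type", "sample_hz", "test_hz", "is_match",
                "delay_s", "laser_start_s", "laser_end_s",
                "distractor_start_s", "distractor_end_s")]
  out$lick_times_s <- vapply(tr$lick_times_s, function(l)
    paste(sprintf("%.6f", l), collapse = ";"), character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

TRIAL_COLS <- c("trial_id", "task_type", "sample_hz", "test_hz", "is_match",
                "delay_s", "laser_start_s", "laser_end_s",
                "distractor_start_s", "distractor_end_s", "lick_times_s")

#' @rdname write_trials
#' @param task optional [task_config()]; reconstructed from the file's
#'   task_type and delay columns when omitted.
#' @param validate check DMS match-flag consistency against stimulus ids.
#' @return `read_trials()`: a `wm_session`.
#' @export
read_trials <- function(path, task = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLS, names(tr))
  if (length(missing)) stop("trial table missing column(s): ",
                            paste(missing, collapse = ", "))
  tr$lick_times_s <- as.character(tr$lick_times_s)
  licks <- lapply(seq_len(nrow(tr)), function(i) {
    f <- tr$lick_times_s[i]
    if (is.na(f) || f == "") return(numeric(0))
    v <- suppressWarnings(as.numeric(strsplit(f, ";", fixed = TRUE)[[1]]))
    if (anyNA(v)) stop("non-numeric lick time in row ", i, ", column lick_times_s")
    if (is.unsorted(v)) stop("unsorted lick times in row ", i, ", column lick_times_s")
    v
  })
  for (col in c("sample_hz", "delay_s")) {
    if (!is.numeric(tr[[col]])) stop("non-numeric values in column ", col)
  }
  if (validate && any(tr$task_type == "DMS")) {
    i_dms <- which(tr$task_type == "DMS")
    bad <- i_dms[tr$is_match[i_dms] != (tr$sample_hz[i_dms] == tr$test_hz[i_dms])]
    if (length(bad)) stop("is_match inconsistent with stimulus ids in row ",
                          bad[1], ", column is_match")
  }
  if (is.null(task)) {
    task <- task_config(task_type = tr$task_type[1], delay_s = tr$delay_s[1])
  }
  trials <- tr[, setdiff(TRIAL_COLS, "lick_times_s")]
  trials$lick_times_s <- I(licks)
  structure(list(trials = trials, task = task,
                 provenance = list(source = path)),
            class = "wm_session")
}

#' Write / read a spike table
#'
#' Long-format CSV, one spike per row: `unit_id,condition,trial_id,
#' spike_time_s`. Times are seconds from sample onset with microsecond
#' precision. Trials with no spikes for a unit are implicit: on read, every
#' trial of the resolving session gets a (possibly empty) train per unit.
#'
#' @param units list of `wm_unit`.
#' @param path output file.
#' @export
write_spikes <- function(units, path) {
  if (inherits(units, "wm_unit")) units <- list(units)
  rows <- lapply(units, function(u) {
    n <- lengths(u$spikes)
    data.frame(unit_id = rep(u$unit_id, sum(n)),
               condition = rep(u$condition, sum(n)),
               trial_id = rep(u$trial_id, n),
               spike_time_s = sprintf("%.6f", unlist(u$spikes)),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @param session the `wm_session` the trial ids refer to.
#' @param span recorded span for the reconstructed units; default
#'   [trial_span()] of the session task.
#' @return `read_spikes()`: list of `wm_unit`, keyed by unit id.
#' @export
read_spikes <- function(path, session, span = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(inherits(session, "wm_session"))
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "condition", "trial_id", "spike_time_s")
  missing <- setdiff(need, names(sp))
  if (length(missing)) stop("spike table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (!is.numeric(sp$spike_time_s)) stop("non-numeric values in column spike_time_s")
  ids <- session$trials$trial_id
  orphan <- setdiff(unique(sp$trial_id), ids)
  if (length(orphan)) stop("spike references unknown trial_id: ", orphan[1])
  span <- span %||% trial_span(session$task)
  units <- lapply(split(sp, sp$unit_id), function(d) {
    spikes <- lapply(ids, function(tid) {
      s <- d$spike_time_s[d$trial_id == tid]
      if (is.unsorted(s)) {
        warning("out-of-order spikes for unit ", d$unit_id[1], ", trial ", tid,
                "; sorted on load")
        s <- sort(s)
      }
      s
    })
    new_unit(d$unit_id[1], d$condition[1], ids, spikes, span,
             session$trials$sample_hz)
  })
  units[order(names(units))]
}

#' Assemble a run configuration
#'
#' Either programmatically or from a YAML file (see `run_config_from_yaml()`).
#' Exactly one of a generator spec or input paths must be provided.
#'
#' @param task a [task_config()].
#' @param behavior a [behavior_gen_config()] (generator route), or `NULL`.
#' @param n_subjects number of synthetic subjects (sessions).
#' @param n_units synthetic units simulated on the first subject's session.
#' @param unit_sampler config/list/function for [simulate_population()].
#' @param trials_path,spikes_path input files (real-data route), or `NULL`.
#' @param selectivity a [selectivity_config()].
#' @param psth_bin,psth_sigma PSTH parameters (s).
#' @param master_seed master RNG seed.
#' @param output_dir where [run_full()] writes its tables.
#' @return list of class `wm_run_cfg`.
#' @export
run_config <- function(task = task_config(),
                       behavior = behavior_gen_config(task = task),
                       n_subjects = 8, n_units = 50,
                       unit_sampler = unit_gen_config(),
                       trials_path = NULL, spikes_path = NULL,
                       selectivity = selectivity_config(n_permutations = 1000),
                       psth_bin = 0.01, psth_sigma = 0.1,
                       master_seed = 1L, output_dir = "results") {
  gen <- !is.null(behavior)
  paths <- !is.null(trials_path)
  if (!gen && !paths) stop("config needs either a generator or input paths")
  structure(list(task = task, behavior = behavior, n_subjects = n_subjects,
                 n_units = n_units, unit_sampler = unit_sampler,
                 trials_path = trials_path, spikes_path = spikes_path,
                 selectivity = selectivity, psth_bin = psth_bin,
                 psth_sigma = psth_sigma, master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "wm_run_cfg")
}

#' Build a run configuration from a YAML file
#'
#' Recognised top-level keys: `task`, `behavior`, `analysis`, `paths`,
#' `master_seed`, `output_dir`; each maps onto the arguments of the
#' corresponding constructor.
#'
#' @param path YAML file.
#' @return a `wm_run_cfg`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  task <- do.call(task_config, y$task %||% list())
  beh <- if (!is.null(y$paths)) NULL else {
    b <- y$behavior %||% list()
    b$task <- task
    b$effective_window <- unlist(b$effective_window) %||% c(0.2, 1.0)
    b$laser_window <- unlist(b$laser_window)
    do.call(behavior_gen_config, b)
  }
  sel <- do.call(selectivity_config, y$analysis$selectivity %||% list())
  run_config(task = task, behavior = beh,
             n_subjects = y$n_subjects %||% 8, n_units = y$n_units %||% 50,
             trials_path = y$paths$trials, spikes_path = y$paths$spikes,
             selectivity = sel,
             psth_bin = y$analysis$psth_bin %||% 0.01,
             psth_sigma = y$analysis$psth_sigma %||% 0.1,
             master_seed = y$master_seed %||% 1L,
             output_dir = y$output_dir %||% "results")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> classify behavior -> unit inclusion -> PSTH and
#' baseline-referenced significance timecourse -> epoch-wise ROC selectivity
#' -> report. All outputs are delimited text plus a JSON provenance sidecar
#' (seed, parameters, stage counts), and are byte-reproducible from the same
#' config and seed.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress stage messages.
#' @return (invisibly) list of class `wm_report`: sessions, metrics table,
#'   laser contrast (if applicable), included units, PSTH, significance
#'   timecourse, ROC timecourses, population selectivity, provenance.
#' @export
run_full <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "wm_run_cfg"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  # --- stage: data ---------------------------------------------------------
  if (!is.null(cfg$trials_path)) {
    sessions <- list(read_trials(cfg$trials_path, task = cfg$task))
    units <- if (!is.null(cfg$spikes_path))
      read_spikes(cfg$spikes_path, sessions[[1]]) else list()
    say("loaded %d session(s), %d unit(s)", length(sessions), length(units))
  } else {
    sessions <- lapply(seq_len(cfg$n_subjects), function(i) {
      b <- cfg$behavior
      b$seed <- cfg$master_seed * 1000L + i
      simulate_session(b)
    })
    units <- simulate_population(cfg$n_units, cfg$unit_sampler, sessions[[1]],
                                 seed = cfg$master_seed)
    say("simulated %d sessions, %d units", length(sessions), length(units))
  }

  # --- stage: behavior -----------------------------------------------------
  sessions <- lapply(sessions, classify_trials)
  metrics <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    m <- session_metrics(sessions[[i]], permissive = TRUE)
    data.frame(subject = sprintf("subject%02d", i), H = m$H, M = m$M,
               CR = m$CR, FA = m$FA, performance = m$performance,
               hit_rate = m$hit_rate, fa_rate = m$fa_rate)
  }))
  utils::write.csv(metrics, file.path(cfg$output_dir, "session_metrics.csv"),
                   row.names = FALSE)
  contrast <- NULL
  if (any(vapply(sessions, function(s) any(laser_on_trials(s)), logical(1)))) {
    contrast <- laser_contrast(sessions, metric = "fa_rate")
    say("laser contrast (FA rate): delta %+0.3f, %s p = %.4g",
        contrast$delta, contrast$test_name, contrast$p_value)
  }

  # --- stage: spike trains -------------------------------------------------
  psth <- timecourse <- roc_tcs <- pop_sel <- NULL
  included <- list()
  if (length(units)) {
    included <- include_units(units)
    say("units: %d recorded, %d included (> 2 Hz)", length(units), length(included))
    if (length(included) >= 3) {
      psth <- make_psth(included, bin = cfg$psth_bin, sigma = cfg$psth_sigma)
      utils::write.csv(data.frame(time_s = psth$bin_edges[-1] - cfg$psth_bin / 2,
                                  rate_hz = psth$rate),
                       file.path(cfg$output_dir, "population_psth.csv"),
                       row.names = FALSE)
      timecourse <- bin_significance_timecourse(included, task = cfg$task)
      utils::write.csv(timecourse,
                       file.path(cfg$output_dir, "bin_significance.csv"),
                       row.names = FALSE)

      # --- stage: selectivity ---------------------------------------------
      roc_tcs <- lapply(included, roc_timecourse, cfg = cfg$selectivity,
                        task = cfg$task)
      per_unit <- do.call(rbind, lapply(roc_tcs, function(tc)
        cbind(unit_id = tc$unit_id, preferred_hz = tc$preferred_hz, tc$epochs)))
      utils::write.csv(per_unit, file.path(cfg$output_dir, "roc_timecourses.csv"),
                       row.names = FALSE)
      pop_sel <- population_selectivity(roc_tcs, cfg$selectivity, cfg$task)
      utils::write.csv(pop_sel, file.path(cfg$output_dir, "population_selectivity.csv"),
                       row.names = FALSE)
    }
  }

  prov <- list(master_seed = cfg$master_seed,
               task = unclass(cfg$task),
               psth = list(bin_s = cfg$psth_bin, sigma_s = cfg$psth_sigma),
               selectivity = unclass(cfg$selectivity)[
                 c("epoch_width", "n_thresholds", "n_permutations", "alpha",
                   "two_sided_total")],
               counts = list(sessions = length(sessions),
                             units_recorded = length(units),
                             units_included = length(included)),
               elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s; outputs in %s", prov$elapsed_s, cfg$output_dir)
  invisible(structure(list(sessions = sessions, metrics = metrics,
                           contrast = contrast, units_included = included,
                           psth = psth, timecourse = timecourse,
                           roc_timecourses = roc_tcs,
                           population_selectivity = pop_sel,
                           provenance = prov),
                      class = "wm_report"))
}
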