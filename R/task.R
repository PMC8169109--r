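#' Task timing configuration
#'
#' Describes the timing of one trial of an auditory delayed match-to-sample
#' (DMS) or go/no-go task variant. All times are in seconds relative to the
#' sample-tone onset (time 0). The response window starts at a task-dependent
#' anchor and lasts `response_window_s`:
#' \itemize{
#'   \item `"DMS"`: window starts at the test-tone offset
#'     (`sample_s + delay_s + test_s`).
#'   \item `"delayed_go_nogo"`: a response cue follows the delay; the window
#'     is anchored at the cue onset (`sample_s + delay_s`).
#'   \item `"go_nogo"`: the sample follows a starting cue; the window is
#'     anchored at the sample-tone offset (`sample_s`).
#' }
#'
#' @param task_type one of `"DMS"`, `"delayed_go_nogo"`, `"go_nogo"`.
#' @param sample_s sample tone duration (s).
#' @param delay_s delay duration between sample offset and test/cue (s).
#' @param test_s test tone duration (s; unused timing-wise for go/no-go).
#' @param response_window_s response window duration (s).
#' @param iti_s inter-trial interval (s); metadata only.
#' @param pre_s pre-stimulus recording span used as the baseline period (s).
#' @param post_s recording span retained after the response window ends (s).
#'
#' @return An object of class `wm_task`.
#' @export
#' @examples
#' cfg <- task_config()
#' response_window(cfg)  # c(1.9, 2.9) for the default 1.5 s delay
task_config <- function(task_type = c("DMS", "delayed_go_nogo", "go_nogo"),
                        sample_s = 0.2, delay_s = 1.5, test_s = 0.2,
                        response_window_s = 1.0, iti_s = 10,
                        pre_s = 0.5, post_s = 0.1) {
  task_type <- match.arg(task_type)
  durs <- c(sample_s = sample_s, delay_s = delay_s, test_s = test_s,
            response_window_s = response_window_s, iti_s = iti_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all task durations must be positive, got: ",
         paste(names(durs)[!is.finite(durs) | durs <= 0], collapse = ", "))
  }
  structure(list(task_type = task_type, sample_s = sample_s, delay_s = delay_s,
                 test_s = test_s, response_window_s = response_window_s,
                 iti_s = iti_s, pre_s = pre_s, post_s = post_s),
            class = "wm_task")
}

#' Response window of a task, `[start, start + duration)`
#'
#' @param task a [task_config()] object.
#' @param delay_s optional per-trial delay overriding the task default.
#' @return numeric `c(start, end)` in seconds from sample onset.
#' @export
response_window <- function(task, delay_s = NULL) {
  stopifnot(inherits(task, "wm_task"))
  d <- if (is.null(delay_s)) task$delay_s else delay_s
  start <- switch(task$task_type,
    DMS = task$sample_s + d + task$test_s,
    delayed_go_nogo = task$sample_s + d,
    go_nogo = task$sample_s)
  c(start, start + task$response_window_s)
}

#' Recorded trial span `[-pre_s, end]` for a task
#' @inheritParams response_window
#' @return numeric `c(t_start, t_end)` in seconds from sample onset.
#' @export
trial_span <- function(task, delay_s = NULL) {
  rw <- response_window(task, delay_s)
  c(-task$pre_s, rw[2] + task$post_s)
}

#' Analysis epoch window
#'
#' A half-open time window `[start, end)` used for epoch firing rates. Windows
#' may be stated relative to the sample onset or to the delay onset; delay-
#' referenced windows are resolved by adding the sample duration, making the
#' convention explicit rather than implicit in the numbers.
#'
#' @param start,end window bounds in seconds (relative to `reference`).
#' @param reference `"sample_onset"` or `"delay_onset"`.
#' @param label optional window label.
#' @return An object of class `wm_epoch`.
#' @export
#' @examples
#' # "300-800 ms of the delay" with a 200 ms sample:
#' resolve_epoch(epoch_window(0.3, 0.8, "delay_onset"), task_config())
epoch_window <- function(start, end, reference = c("sample_onset", "delay_onset"),
                         label = NULL) {
  reference <- match.arg(reference)
  if (!is.finite(start) || !is.finite(end) || start >= end) {
    stop("epoch window requires start < end")
  }
  structure(list(start = start, end = end, reference = reference,
                 label = label %||% sprintf("%g-%g s (%s)", start, end, reference)),
            class = "wm_epoch")
}

#' Resolve an epoch window to sample-onset coordinates
#' @param window a [epoch_window()].
#' @param task a [task_config()]; needed for delay-onset references.
#' @return numeric `c(start, end)` relative to sample onset.
#' @export
resolve_epoch <- function(window, task = task_config()) {
  stopifnot(inherits(window, "wm_epoch"))
  off <- if (window$reference == "delay_onset") task$sample_s else 0
  c(window$start + off, window$end + off)
}

#' Consecutive 100 ms analysis epochs tiling a time range
#'
#' @param from,to range in seconds from sample onset.
#' @param width epoch width in seconds.
#' @return list of `wm_epoch` objects referenced to sample onset.
#' @export
tile_epochs <- function(from = 0, to = 1.7, width = 0.1) {
  stopifnot(width > 0, to > from)
  starts <- seq(from, to - width / 2, by = width)
  lapply(starts, function(s) epoch_window(s, s + width, "sample_onset"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
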