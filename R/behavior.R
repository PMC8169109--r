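#' Classify a trial as hit, miss, CR, or FA
#'
#' A trial is a "response" trial if any lick falls in the half-open response
#' window `[start, start + response_window_s)`. Match (go) trials with a
#' response are hits, without are misses; nonmatch (no-go) trials with a
#' response are false alarms (FA), without are correct rejections (CR).
#' Licks outside the window - including during the delay - are ignored for
#' classification.
#'
#' @param lick_times numeric lick times (s from sample onset), sorted.
#' @param is_match logical; match/go trial?
#' @param task a [task_config()].
#' @param delay_s per-trial delay, if it differs from the task default.
#' @return one of `"hit"`, `"miss"`, `"CR"`, `"FA"`.
#' @export
classify_trial <- function(lick_times, is_match, task = task_config(),
                           delay_s = NULL) {
  if (is.na(is_match)) stop("is_match flag is missing")
  if (length(lick_times) && is.unsorted(lick_times)) {
    stop("lick_times must be sorted ascending")
  }
  rw <- response_window(task, delay_s)
  responded <- any(lick_times >= rw[1] & lick_times < rw[2])
  if (is_match) {
    if (responded) "hit" else "miss"
  } else {
    if (responded) "FA" else "CR"
  }
}

#' Classify every trial of a session
#'
#' @param session a `wm_session`.
#' @return the session, with an `outcome` column added to `$trials`.
#' @export
classify_trials <- function(session) {
  stopifnot(inherits(session, "wm_session"))
  tr <- session$trials
  session$trials$outcome <- vapply(seq_len(nrow(tr)), function(i) {
    classify_trial(tr$lick_times_s[[i]], tr$is_match[i], session$task,
                   delay_s = tr$delay_s[i])
  }, character(1))
  session
}

#' Session-level behavioral metrics
#'
#' Counts hit (H), miss (M), correct-rejection (CR) and false-alarm (FA)
#' trials and derives
#' \deqn{Performance = (H + CR) / (H + CR + FA + M),}
#' \deqn{Hit\,rate = H / (H + M), \quad FA\,rate = FA / (FA + CR).}
#'
#' @param session a classified `wm_session`, or a character vector of
#'   outcome labels.
#' @param permissive if `TRUE`, an empty match or nonmatch set yields `NaN`
#'   for the corresponding rate instead of an error.
#' @return list of class `wm_metrics` with fields `H`, `M`, `CR`, `FA`,
#'   `performance`, `hit_rate`, `fa_rate`.
#' @export
#' @examples
#' session_metrics(c(rep("hit", 8), rep("miss", 2), rep("CR", 7), rep("FA", 3)))
session_metrics <- function(session, permissive = FALSE) {
  outcomes <- if (inherits(session, "wm_session")) {
    if (is.null(session$trials$outcome)) session <- classify_trials(session)
    session$trials$outcome
  } else as.character(session)
  bad <- setdiff(unique(outcomes), c("hit", "miss", "CR", "FA"))
  if (length(bad)) stop("unknown outcome labels: ", paste(bad, collapse = ", "))
  H <- sum(outcomes == "hit"); M <- sum(outcomes == "miss")
  CR <- sum(outcomes == "CR"); FA <- sum(outcomes == "FA")
  rate <- function(num, den, what) {
    if (den == 0) {
      if (permissive) return(NaN)
      stop(what, " undefined: no trials in denominator")
    }
    num / den
  }
  structure(list(H = H, M = M, CR = CR, FA = FA,
                 performance = rate(H + CR, H + CR + FA + M, "performance"),
                 hit_rate = rate(H, H + M, "hit rate"),
                 fa_rate = rate(FA, FA + CR, "FA rate")),
            class = "wm_metrics")
}

#' @export
print.wm_metrics <- function(x, ...) {
  cat(sprintf("<wm_metrics> H=%d M=%d CR=%d FA=%d | performance %.3f, hit rate %.3f, FA rate %.3f\n",
              x$H, x$M, x$CR, x$FA, x$performance, x$hit_rate, x$fa_rate))
  invisible(x)
}

#' Performance by delay duration across subjects
#'
#' Aggregates session performance to one value per subject per delay (pooling
#' trials across a subject's sessions at that delay), then reports the mean
#' and s.e.m. across subjects for each delay level. With a single subject the
#' s.e.m. is reported as `NA`.
#'
#' @param sessions list of `wm_session` objects.
#' @param subjects character/factor vector, one subject id per session.
#' @param metric which metric to aggregate.
#' @return data frame with columns `delay_s`, `mean`, `sem`, `n_subjects`.
#' @export
metrics_by_delay <- function(sessions, subjects,
                             metric = c("performance", "hit_rate", "fa_rate")) {
  metric <- match.arg(metric)
  stopifnot(length(sessions) == length(subjects), length(sessions) >= 1)
  per <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    if (is.null(s$trials$outcome)) s <- classify_trials(s)
    data.frame(subject = as.character(subjects[i]),
               delay_s = s$trials$delay_s,
               outcome = s$trials$outcome, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(split(per, per$delay_s), function(d) {
    vals <- vapply(split(d$outcome, d$subject),
                   function(o) session_metrics(o, permissive = TRUE)[[metric]],
                   numeric(1))
    data.frame(delay_s = d$delay_s[1], mean = mean(vals),
               sem = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
               n_subjects = length(vals))
  }))
  out <- out[order(out$delay_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose between a paired t-test and a Wilcoxon signed-rank test
#'
#' Applies a Shapiro-Wilk normality test to the paired differences; if the
#' differences are consistent with normality (p >= `alpha_norm`) a paired
#' t-test is selected, otherwise the Wilcoxon signed-rank test. Zero-variance
#' differences are flagged degenerate and no test is chosen.
#'
#' @param a,b equal-length numeric vectors (paired observations), n >= 3.
#' @param alpha_norm normality-test level.
#' @return list(test = "t" | "wilcoxon" | "degenerate", shapiro_p).
#' @export
choose_test <- function(a, b, alpha_norm = 0.05) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) return(list(test = "degenerate", shapiro_p = NA_real_))
  sp <- stats::shapiro.test(d)$p.value
  list(test = if (sp >= alpha_norm) "t" else "wilcoxon", shapiro_p = sp)
}

#' Laser ON vs OFF behavioral contrast
#'
#' For each subject the chosen metric is computed separately on laser-ON and
#' laser-OFF trials (pooled over that subject's sessions), and the per-subject
#' ON/OFF pairs are compared with a paired test selected by [choose_test()].
#'
#' @param sessions list of `wm_session` objects with interleaved ON/OFF trials.
#' @param subjects subject id per session; defaults to one subject per session.
#' @param metric `"performance"`, `"hit_rate"` or `"fa_rate"`.
#' @param alpha_norm normality-test level passed to [choose_test()].
#' @return list of class `wm_contrast`: per_subject_on/off, test_name,
#'   statistic, p_value, mean_on/off, sem_on/off, delta.
#' @export
laser_contrast <- function(sessions, subjects = NULL,
                           metric = c("performance", "hit_rate", "fa_rate"),
                           alpha_norm = 0.05) {
  metric <- match.arg(metric)
  if (inherits(sessions, "wm_session")) sessions <- list(sessions)
  subjects <- subjects %||% sprintf("subject%02d", seq_along(sessions))
  stopifnot(length(subjects) == length(sessions))
  per <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    if (is.null(s$trials$outcome)) s <- classify_trials(s)
    data.frame(subject = as.character(subjects[i]),
               on = laser_on_trials(s), outcome = s$trials$outcome,
               stringsAsFactors = FALSE)
  }))
  m_of <- function(o) session_metrics(o, permissive = FALSE)[[metric]]
  by_subj <- split(per, per$subject)
  on_vals <- off_vals <- numeric(length(by_subj))
  for (i in seq_along(by_subj)) {
    d <- by_subj[[i]]
    if (!any(d$on) || !any(!d$on)) {
      stop("subject ", names(by_subj)[i], " lacks laser-ON or laser-OFF trials")
    }
    on_vals[i] <- m_of(d$outcome[d$on])
    off_vals[i] <- m_of(d$outcome[!d$on])
  }
  ct <- choose_test(on_vals, off_vals, alpha_norm)
  if (ct$test == "degenerate") {
    stat <- NA_real_; p <- NA_real_; name <- "degenerate"
  } else if (ct$test == "t") {
    ht <- stats::t.test(on_vals, off_vals, paired = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value; name <- "paired t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(on_vals, off_vals, paired = TRUE,
                                              exact = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value; name <- "Wilcoxon signed-rank"
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(metric = metric,
                 per_subject_on = on_vals, per_subject_off = off_vals,
                 test_name = name, statistic = stat, p_value = p,
                 mean_on = mean(on_vals), mean_off = mean(off_vals),
                 sem_on = sem(on_vals), sem_off = sem(off_vals),
                 delta = mean(on_vals) - mean(off_vals),
                 shapiro_p = ct$shapiro_p),
            class = "wm_contrast")
}

#' @export
print.wm_contrast <- function(x, ...) {
  cat(sprintf("<wm_contrast> %s: ON %.3f +/- %.3f vs OFF %.3f +/- %.3f (delta %+.3f)\n",
              x$metric, x$mean_on, x$sem_on, x$mean_off, x$sem_off, x$delta))
  cat(sprintf("  %s: statistic %.3g, p = %.4g (n = %d subjects)\n",
              x$test_name, x$statistic, x$p_value, length(x$per_subject_on)))
  invisible(x)
}
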