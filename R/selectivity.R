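#' Selectivity analysis configuration
#'
#' @param epoch_width analysis epoch width (s); 100 ms default.
#' @param n_thresholds number of ROC threshold levels (>= 2); 12 default.
#' @param n_permutations permutation count for the null; 5000 default.
#' @param alpha total two-sided significance level.
#' @param two_sided_total if `TRUE` (default), "top or bottom 5%" is read as
#'   a total level of 5% split 2.5% per tail; if `FALSE`, each tail gets the
#'   full 5%.
#' @param preferred_window window used to assign the preferred stimulus;
#'   default sample epoch.
#' @param seed RNG seed for permutations.
#' @return list of class `wm_sel_cfg`.
#' @export
selectivity_config <- function(epoch_width = 0.1, n_thresholds = 12,
                               n_permutations = 5000, alpha = 0.05,
                               two_sided_total = TRUE,
                               preferred_window = epoch_window(0, 0.2, "sample_onset",
                                                              label = "sample"),
                               seed = 1L) {
  if (n_thresholds < 2) stop("need at least 2 thresholds")
  if (n_permutations < 1) stop("need at least 1 permutation")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(epoch_width = epoch_width, n_thresholds = as.integer(n_thresholds),
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 two_sided_total = two_sided_total,
                 preferred_window = preferred_window, seed = as.integer(seed)),
            class = "wm_sel_cfg")
}

#' Assign the preferred sample stimulus of a unit
#'
#' The preferred stimulus is the one evoking the higher mean firing rate in
#' `window` (default: the sample epoch). The assignment is made once per unit
#' and reused for every analysis epoch. Exact ties break toward the lower
#' frequency, deterministically.
#'
#' @param unit a `wm_unit` whose trials carry >= 2 stimuli, >= 5 trials each.
#' @param window a [epoch_window()] or `c(start, end)`.
#' @param task a [task_config()].
#' @return the preferred stimulus identity (numeric kHz label).
#' @export
assign_preferred <- function(unit, window = NULL, task = task_config()) {
  stopifnot(inherits(unit, "wm_unit"))
  window <- window %||% epoch_window(0, task$sample_s, "sample_onset")
  stimuli <- sort(unique(unit$sample_hz))
  if (length(stimuli) < 2) stop("need >= 2 stimuli to assign a preference")
  counts <- table(unit$sample_hz)
  if (any(counts < 5)) stop("each stimulus needs >= 5 trials")
  rates <- unit_epoch_rates(unit, window, task)
  means <- vapply(stimuli, function(s) mean(rates[unit$sample_hz == s]), numeric(1))
  # which.max returns the first maximum; stimuli are sorted ascending, so
  # ties resolve to the lower frequency
  stimuli[which.max(means)]
}

#' Threshold-sweep ROC selectivity statistic
#'
#' Places `n_thresholds` evenly spaced activity thresholds spanning the
#' pooled range of the two rate samples (both endpoints included). For each
#' threshold the true-positive rate is the fraction of preferred-stimulus
#' trials with activity strictly greater than the threshold, and the
#' false-positive rate the same fraction for nonpreferred trials; ties at a
#' threshold count as non-exceeding. The points, together with (0,0) and
#' (1,1), sorted by FPR then TPR, form the ROC curve, whose area is computed
#' by the trapezoid rule. A value of 1 means every preferred-trial rate
#' exceeded every nonpreferred-trial rate; 0 the reverse; 0.5 chance. If all
#' pooled rates are equal the statistic is defined as 0.5.
#'
#' @param pref_rates,nonpref_rates non-empty numeric rate vectors.
#' @param n_thresholds number of thresholds.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' roc_value(c(10, 12, 11), c(1, 2, 3))  # 1: complete separation
roc_value <- function(pref_rates, nonpref_rates, n_thresholds = 12) {
  if (!length(pref_rates) || !length(nonpref_rates)) stop("both groups must be non-empty")
  pooled <- c(pref_rates, nonpref_rates)
  if (max(pooled) == min(pooled)) return(0.5)
  thr <- seq(min(pooled), max(pooled), length.out = n_thresholds)
  exceed <- outer(pooled, thr, `>`)
  auc_from_split(exceed, seq_along(pref_rates), length(pref_rates),
                 length(nonpref_rates))
}

# Core AUC computation shared by roc_value and the permutation loop.
# `exceed`: n_total x n_thresholds logical matrix (value > threshold);
# `idx_pref`: indices of the preferred group.
auc_from_split <- function(exceed, idx_pref, n_pref, n_nonpref) {
  s_all <- colSums(exceed)
  s_pref <- if (n_pref == 1) as.numeric(exceed[idx_pref, ]) else colSums(exceed[idx_pref, , drop = FALSE])
  tpr <- s_pref / n_pref
  fpr <- (s_all - s_pref) / n_nonpref
  # both tpr and fpr are nonincreasing in the threshold; append the anchors
  fpr <- c(0, rev(fpr), 1)
  tpr <- c(0, rev(tpr), 1)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Permutation test for an ROC value
#'
#' Builds the null by randomly redistributing all trials into two groups of
#' the original sizes (`n_permutations` seeded shuffles, or every distinct
#' split when `exhaustive = TRUE`), recomputing the ROC statistic for each.
#' The observed value is significant when it lies in the extreme total-5%
#' of the null (2.5% per tail under the default convention). Each tail
#' counts null values strictly beyond the observed one; the reported
#' p-value is `2 * min(tail proportions)` with add-one smoothing
#' `(r + 1) / (N + 1)`, capped at 1, so the minimal attainable p is
#' `2 / (N + 1)`.
#'
#' @param pref_rates,nonpref_rates numeric rate vectors, combined n >= 6.
#' @param cfg a [selectivity_config()].
#' @param exhaustive enumerate all splits instead of sampling (small n only).
#' @return list(auc, p_value, significant, n_null).
#' @export
permutation_test <- function(pref_rates, nonpref_rates,
                             cfg = selectivity_config(), exhaustive = FALSE) {
  n1 <- length(pref_rates); n2 <- length(nonpref_rates)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  if (n1 + n2 < 6) stop("need at least 6 trials in total")
  pooled <- c(pref_rates, nonpref_rates)
  obs <- roc_value(pref_rates, nonpref_rates, cfg$n_thresholds)
  if (max(pooled) == min(pooled)) {
    # degenerate: every split gives 0.5, nothing to test
    return(list(auc = obs, p_value = 1, significant = FALSE, n_null = 0L))
  }
  thr <- seq(min(pooled), max(pooled), length.out = cfg$n_thresholds)
  exceed <- outer(pooled, thr, `>`)
  n <- n1 + n2
  if (exhaustive) {
    splits <- utils::combn(n, n1, simplify = FALSE)
    null_auc <- vapply(splits, function(ix) auc_from_split(exceed, ix, n1, n2),
                       numeric(1))
  } else {
    restore <- set_local_seed(cfg$seed)
    on.exit(restore())
    null_auc <- vapply(seq_len(cfg$n_permutations), function(i) {
      auc_from_split(exceed, sample.int(n, n1), n1, n2)
    }, numeric(1))
  }
  r_up <- sum(null_auc > obs + 1e-12)
  r_lo <- sum(null_auc < obs - 1e-12)
  p <- min(1, 2 * min(r_up + 1, r_lo + 1) / (length(null_auc) + 1))
  alpha <- cfg$alpha * if (cfg$two_sided_total) 1 else 2
  list(auc = obs, p_value = p, significant = p < alpha,
       n_null = length(null_auc))
}

#' Epoch-wise ROC selectivity timecourse for one unit
#'
#' Assigns the unit's preferred stimulus once (from `cfg$preferred_window`),
#' then for every consecutive `epoch_width` epoch from the sample onset to
#' the end of the delay computes per-trial epoch rates, splits them by sample
#' identity into preferred/nonpreferred groups, and reports the ROC statistic
#' with its permutation p-value.
#'
#' @param unit a `wm_unit`.
#' @param cfg a [selectivity_config()].
#' @param task a [task_config()].
#' @param from,to epoch range (s from sample onset); default sample onset to
#'   delay end.
#' @return list of class `wm_roc_tc`: unit_id, preferred_hz, and a data
#'   frame `epochs` with start, end, auc, p_value, significant.
#' @export
roc_timecourse <- function(unit, cfg = selectivity_config(),
                           task = task_config(), from = 0, to = NULL) {
  stopifnot(inherits(unit, "wm_unit"))
  to <- to %||% (task$sample_s + task$delay_s)
  if (to > unit$span[2] + 1e-9) stop("epochs extend beyond the recorded span")
  pref <- assign_preferred(unit, cfg$preferred_window, task)
  starts <- seq(from, to - cfg$epoch_width + 1e-9, by = cfg$epoch_width)
  is_pref <- unit$sample_hz == pref
  rows <- lapply(seq_along(starts), function(k) {
    w <- c(starts[k], starts[k] + cfg$epoch_width)
    rates <- unit_epoch_rates(unit, w, task)
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k  # independent permutation stream per epoch
    pt <- permutation_test(rates[is_pref], rates[!is_pref], cfg_k)
    data.frame(start = w[1], end = w[2], auc = pt$auc,
               p_value = pt$p_value, significant = pt$significant)
  })
  structure(list(unit_id = unit$unit_id, preferred_hz = pref,
                 epochs = do.call(rbind, rows)),
            class = "wm_roc_tc")
}

#' @export
print.wm_roc_tc <- function(x, ...) {
  cat(sprintf("<wm_roc_tc> %s (preferred %g kHz): %d epochs, %d significant\n",
              x$unit_id, x$preferred_hz, nrow(x$epochs), sum(x$epochs$significant)))
  invisible(x)
}

#' Population selectivity timecourse
#'
#' Unweighted mean ROC value across units per epoch, and the fraction of
#' units whose permutation test is significant per epoch. Because preferred
#' stimuli are estimated from the data, the null expectation of the mean AUC
#' slightly exceeds 0.5; compare against simulated nulls, not 0.5.
#'
#' @param units list of >= 3 `wm_unit`, or a list of precomputed
#'   `wm_roc_tc` objects.
#' @param cfg a [selectivity_config()].
#' @param task a [task_config()].
#' @return data frame: start, end, mean_auc, frac_significant, n_units.
#' @export
population_selectivity <- function(units, cfg = selectivity_config(),
                                   task = task_config()) {
  if (length(units) < 3) stop("need at least 3 units")
  tcs <- lapply(units, function(u) {
    if (inherits(u, "wm_roc_tc")) u else roc_timecourse(u, cfg, task)
  })
  grid <- tcs[[1]]$epochs[, c("start", "end")]
  for (tc in tcs) {
    if (nrow(tc$epochs) != nrow(grid) ||
        max(abs(tc$epochs$start - grid$start)) > 1e-9)
      stop("epoch grids differ across units")
  }
  auc_mat <- vapply(tcs, function(tc) tc$epochs$auc, numeric(nrow(grid)))
  sig_mat <- vapply(tcs, function(tc) tc$epochs$significant, logical(nrow(grid)))
  data.frame(start = grid$start, end = grid$end,
             mean_auc = rowMeans(auc_mat),
             frac_significant = rowMeans(sig_mat),
             n_units = length(tcs))
}

#' Compare unit-level selectivity between two conditions
#'
#' Per epoch, a two-sample Wilcoxon rank-sum test of the unit-level ROC
#' values between conditions (e.g. task-engaged vs passive listening).
#'
#' @param units_a,units_b lists of >= 3 `wm_unit` (or `wm_roc_tc`) per
#'   condition, analysed on the same epoch grid.
#' @param cfg a [selectivity_config()].
#' @param task a [task_config()].
#' @return data frame: start, end, p_value, significant, and the two
#'   condition mean AUCs.
#' @export
compare_conditions <- function(units_a, units_b, cfg = selectivity_config(),
                               task = task_config()) {
  if (length(units_a) < 3 || length(units_b) < 3) stop("need >= 3 units per condition")
  tc_a <- lapply(units_a, function(u) if (inherits(u, "wm_roc_tc")) u else roc_timecourse(u, cfg, task))
  tc_b <- lapply(units_b, function(u) if (inherits(u, "wm_roc_tc")) u else roc_timecourse(u, cfg, task))
  grid <- tc_a[[1]]$epochs[, c("start", "end")]
  for (tc in c(tc_a, tc_b)) {
    if (nrow(tc$epochs) != nrow(grid) ||
        max(abs(tc$epochs$start - grid$start)) > 1e-9)
      stop("epoch grids differ between conditions")
  }
  a_mat <- vapply(tc_a, function(tc) tc$epochs$auc, numeric(nrow(grid)))
  b_mat <- vapply(tc_b, function(tc) tc$epochs$auc, numeric(nrow(grid)))
  p <- vapply(seq_len(nrow(grid)), function(i) {
    suppressWarnings(stats::wilcox.test(a_mat[i, ], b_mat[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(start = grid$start, end = grid$end,
             mean_auc_a = rowMeans(a_mat), mean_auc_b = rowMeans(b_mat),
             p_value = p, significant = is.finite(p) & p < cfg$alpha)
}
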