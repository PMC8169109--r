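---
title: "Analysing auditory working-memory behavior and spike trains with acwm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing auditory working-memory behavior and spike trains with acwm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acwm)
```

# The task and its metrics

`acwm` analyses head-fixed rodent auditory tasks of three related designs.
In the delayed match-to-sample (DMS) design a sample tone (3 or 12 kHz,
200 ms) is followed by a delay (1.5 s by default) and a test tone; the
animal licks if the two match. The delayed go/no-go and go/no-go variants
keep the same outcome logic but anchor the response window at the response
cue and at the sample-tone offset, respectively. All times in the package
are seconds from the sample-tone onset, and every window is half-open,
`[start, end)`, so that adjacent windows partition time with no ambiguity
about boundary spikes or licks.

A trial is a response trial if any lick falls inside the 1 s response
window; crossed with the match flag this yields the four outcomes hit (H),
miss (M), correct rejection (CR) and false alarm (FA). Session metrics are

$$\mathrm{Performance} = \frac{H + CR}{H + CR + FA + M}, \qquad
  \mathrm{Hit\ rate} = \frac{H}{H+M}, \qquad
  \mathrm{FA\ rate} = \frac{FA}{FA+CR}.$$

Hit and miss rates sum to one by construction, as do CR and FA rates, and
all metrics are invariant to trial order. Licks during the delay are kept in
the data but never classify a trial: well-trained animals lick a little
during the delay and are not punished for it, so delay licks carry no
outcome information.

Division guards matter in small sessions: with no nonmatch trials the FA
rate is undefined and `session_metrics()` raises an error unless
`permissive = TRUE` asks for `NaN` instead.

## Group-level contrasts

`laser_contrast()` computes a metric separately on laser-ON and laser-OFF
trials per subject (pooling a subject's sessions) and compares the paired
per-subject values. Pooling trials per mouse, rather than averaging
session-level values first, is the package's default because it weights
every trial equally; a per-session average can be computed by passing one
session per subject. Test selection follows the convention of first testing
the paired differences for normality (Shapiro–Wilk at $\alpha = 0.05$):
normal-looking differences get a paired *t*-test, otherwise a Wilcoxon test.
Because the design is paired, the nonparametric branch uses the *signed-rank*
test — the rank-sum test assumes independent samples and would discard the
within-mouse pairing. Per-metric tests are reported uncorrected; the three
session metrics are strongly dependent, and the analyses drawn from them
treat each metric as its own question.

# Spike-train analyses

## Inclusion and baseline

Units enter the analysis only if their whole-session mean rate strictly
exceeds 2 Hz; an optional contamination screen drops units with more than a
configurable fraction of inter-spike intervals below 2 ms. The baseline
period is the 0.5 s immediately before sample onset, `[-0.5, 0)`, giving one
baseline rate per trial.

## PSTH

`make_psth()` bins spikes at 10 ms, converts to rate (count divided by
trial count times bin width, so the unsmoothed PSTH conserves spike mass
exactly), and convolves with a Gaussian kernel of $\sigma = 100$ ms. The
kernel is truncated at $\pm 4\sigma$ and renormalised to unit mass; near the
span edges each bin is additionally divided by the kernel mass that fell
inside the span, so a constant-rate process stays flat to the very first
bin instead of sagging. A population PSTH is the unweighted mean of the unit
PSTHs, which keeps units comparable regardless of trial counts.

## Baseline-referenced significance timecourses

`bin_significance_timecourse()` tiles time from the sample onset in 100 ms
bins and reports two things per bin: a population-level Wilcoxon rank-sum
test of per-unit mean bin rates against per-unit mean baseline rates, and
the fraction of units individually significant in that bin.

The individual-unit test deserves a note, because it hides a trap. Rates
measured in a 100 ms bin are multiples of 10 Hz; rates measured over the
whole 500 ms baseline are multiples of 2 Hz. A rank test between the two is
badly miscalibrated even at identical mean rate — the medians differ purely
through count granularity (we measured a 22% rejection rate at nominal 5% on
exchangeable synthetic data). The package therefore bins the baseline at the
same width as the tested bin and pools the per-trial baseline sub-bins as
the reference sample, restoring exchangeability under the null; the
calibration test in the suite holds the empirical rate inside the binomial
confidence band of the nominal level. A related numerical point: window
durations are snapped to 1 ns inside the rate computations, because
floating-point subtraction (`1.4 - 1.3`) would otherwise make equal-width
windows differ in the 15th digit and silently break every cross-window rate
tie in the rank statistics.

The responsiveness screen (`responsiveness()`) flags a unit task-related if
any epoch of a configurable set — by default the sample epoch plus the
successive 100 ms delay bins — differs from baseline by a paired *t*-test at
p < 0.05. The epoch set is configurable because "task-related" can
reasonably be tested on one fixed epoch or on any epoch; the default mirrors
the displayed timecourse analyses and applies no multiple-comparison
correction, so the null flagging rate is the family-wise error of the epoch
set (about half, for 16 correlated epochs), not 5%.

# Selectivity: threshold-sweep ROC with a permutation null

For each consecutive 100 ms epoch, per-trial rates are split by the sample
stimulus into preferred and nonpreferred groups. The preferred stimulus is
assigned **once per unit** from the sample epoch and reused for every epoch,
so a unit's timecourse describes one coherent preference rather than
flipping epoch by epoch. Exact ties in the mean rates break toward the lower
frequency, deterministically.

The discrimination statistic sweeps 12 evenly spaced thresholds spanning the
pooled range of the two samples (both endpoints included — the description
"covering the range" leaves placement open, and including the endpoints
guarantees the curve reaches its anchors). At each threshold the fraction of
trials with activity *strictly greater* than the threshold is computed per
group; ties at a threshold count as non-exceeding, exactly as stated. These
(FPR, TPR) points plus (0,0) and (1,1), sorted, form the ROC curve, whose
trapezoid area is the statistic: 1 for complete separation in the preferred
direction, 0 for the reverse, 0.5 at chance. If all pooled rates are equal
(for example a silent epoch) the statistic is defined as 0.5. With many
thresholds the statistic converges to the Mann–Whitney pair-count AUC with
tie half-credit (the suite asserts agreement within 0.02 at 200 thresholds);
at 12 thresholds it is a slightly coarser but monotone-equivalent summary,
and the strict-inequality convention makes the group-swap reflection
$A \mapsto 1 - A$ exact only up to the threshold discretisation.

## Permutation significance

The null redistributes all trials of a unit into two groups of the original
sizes ("randomly distributing all trials, independent of the actual cues" —
group sizes are not stated in that description; preserving the observed
sizes keeps the statistic exchangeable), recomputing the statistic for each
of 5000 shuffles (scaled down where the suite documents it). Significance
uses a total two-sided level of 5% — 2.5% per tail — because the stated
"top or bottom 5%" is equated with p < 0.05; the 5%-per-tail reading is
available via `two_sided_total = FALSE`. Each tail counts null values
strictly beyond the observed statistic, and the reported p-value is
$2\min(r_{up}+1, r_{lo}+1)/(N+1)$, capped at 1, so the minimal attainable
p at $N$ shuffles is $2/(N+1)$ and complete separation on small groups is
still detectable. The cost of the strict convention on heavily tied count
data is a mild anti-conservativeness (about 5.5% empirical at nominal 5% in
our calibration ensemble), which the validation suite tracks against the
binomial confidence band. `exhaustive = TRUE` enumerates all
$\binom{n}{n_1}$ splits instead of sampling; every permutation result is
bit-reproducible under a fixed seed.

Because the preferred label is estimated from the same data, the population
mean AUC of pure-noise units exceeds 0.5 slightly (selection bias); null
expectations for population summaries are therefore established by
simulation with a-priori labels, never assumed to be 0.5.

# The synthetic generator

The generator exists so that every analysis stage can be exercised, and its
statistical guarantees measured, without recordings. It emulates the
structure the analyses assume and nothing more.

**Sessions.** Match/nonmatch trials are randomly interleaved; outcomes are
Bernoulli draws at the configured hit and FA probabilities; lick times for
response trials are placed uniformly inside the response window (1 + a
Poisson(2) count of licks), since only window membership matters downstream.
Laser-ON trials are randomly interleaved at probability 0.5. The laser
shifts the outcome probabilities additively (clamped to [0, 1]) only when
its window covers at least 50% of the *effective window*, 0.2–1.0 s from
sample onset by default — the stimulus plus the early delay, where
inactivation is behaviorally effective. One gating mechanism thus reproduces
the early-vs-late dissociation: a late-delay laser window leaves ON and OFF
trials identical in law.

**Units.** Each unit has a piecewise trial-aligned intensity: baseline
$r_0$; a phasic plateau $r_0 + a_s$ during the stimulus, with amplitude
depending on whether the sample is the unit's preferred stimulus; an
exponential decay with constant $\tau$ after stimulus offset; and a hard
truncation of all above-baseline activity at a fixed time from stimulus
**onset** (1.0 s for the task-engaged preset). Anchoring the truncation to
onset rather than offset encodes delay activity that lasts a fixed duration
from onset regardless of stimulus length. The passive-listening preset
truncates at 0.5 s with $\tau = 0.15$ s; the source material states only
that passive delay activity persists "for a much shorter interval", so 0.5 s
is a free generator parameter chosen as a plausible midpoint, not an
estimate. Spikes are sampled by Bernoulli thinning on a 1 ms grid (rate
treated as constant within a bin) — exact to well below the resolution of
any 100 ms-epoch statistic, and the suite checks mean counts against the
analytic integral of the intensity. Setting `a_pref = a_nonpref` gives a
non-selective unit by construction, which is how the null ensembles for
calibration are built.

**What the generator does not model:** correlated variability across units
or trials, non-Poisson spiking (bursting, refractoriness), licking
microstructure, adaptation across a session, and learning. Passing tests on
generated data therefore demonstrate the *statistical* correctness of the
pipeline — calibration, power against built-in effects, parameter
recovery — not that real cortical data meet the assumptions.

# Validation problem sizes

The test suite runs the behavioral checks at 10–1000 trials per session, the
calibration ensembles at 200–1000 synthetic units (permutation counts scaled
to 400–1000 shuffles where full 5000-shuffle nulls would add nothing but
time), the truncation-recovery populations at 60 units x 120 trials, and the
inactivation power study at 50 replicate experiments of 8 mice x 300 trials.
The acceptance script re-derives the reference quantities — the chance-level
mean and extreme values of the ROC statistic and the empirical type-I rate
of the permutation test — from scratch at those same scales.

# Known limitations

- The four-tone task variant is generated and classified, but the ROC
  analysis is two-class only; no pairwise extension is provided.
- Signal-detection summaries (d', criterion) are deliberately out of scope;
  the four-rate metrics are the interface.
- The per-mouse pooling default for contrasts (trials, not session means) is
  a documented choice; both conventions are reachable through the API.
- `metrics_by_delay()` reports the s.e.m. across subjects as `NA` for a
  single subject rather than 0.
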