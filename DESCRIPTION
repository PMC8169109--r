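Package: acwm
Title: Behavioral Metrics and Spike-Train Analyses for Auditory Working-Memory Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing delayed match-to-sample (DMS) and go/no-go
    auditory behavior together with trial-aligned single-unit spike trains.
    Implements trial outcome classification (hit/miss/CR/FA) and the derived
    session metrics, PSTH estimation with Gaussian kernel smoothing,
    baseline-referenced significance timecourses, epoch-wise ROC selectivity
    with a threshold-sweep statistic and a permutation null, and laser ON/OFF
    behavioral contrasts for optogenetic inactivation experiments. A seeded
    synthetic generator produces sessions and inhomogeneous-Poisson spike
    trains with the statistical structure the analyses assume, so the full
    pipeline is testable without external recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
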