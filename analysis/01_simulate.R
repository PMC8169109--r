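#!/usr/bin/env Rscript
# Generate the synthetic study used by the downstream analysis scripts:
#  - a delay-duration behavioral experiment (5 mice at 1.5 / 3 / 7 s delays,
#    with performance degrading as the delay grows),
#  - two optogenetic experiments (8 mice each): laser covering the stimulus +
#    early delay (inside the effective window) vs late delay (outside),
#  - one recording-style session with a task-engaged (WM) and a passive-
#    listening unit population.
# Raw trial/spike tables are written under scratch/sim/ (regenerated on every
# run); a small example of each file format is kept under results/data/.

suppressPackageStartupMessages(library(acwm))

master_seed <- 20240101L
sim_dir <- "scratch/sim"
for (d in c(sim_dir, file.path(sim_dir, "delay"), file.path(sim_dir, "laser_early"),
            file.path(sim_dir, "laser_late"), "results/data"))
  dir.create(d, showWarnings = FALSE, recursive = TRUE)

## Delay-duration experiment -------------------------------------------------
# Error rates grow with the memory load; the generator states them directly.
delays <- c(1.5, 3, 7)
p_hit <- c(0.93, 0.86, 0.74)
p_fa  <- c(0.12, 0.24, 0.38)
for (m in 1:5) {
  for (k in seq_along(delays)) {
    s <- simulate_session(behavior_gen_config(
      100, 100, p_hit = p_hit[k], p_fa = p_fa[k],
      task = task_config(delay_s = delays[k]),
      seed = master_seed + 100L * m + k))
    write_trials(s, file.path(sim_dir, "delay",
                              sprintf("mouse%02d_delay%.1fs.csv", m, delays[k])))
  }
}
cat("delay experiment: 5 mice x", length(delays), "delays written\n")

## Optogenetic experiments ---------------------------------------------------
# FA-rate shift of +0.19 gated on the laser covering the stimulus + early
# delay (effective window 0.2-1.0 s from sample onset).
for (m in 1:8) {
  early <- simulate_session(behavior_gen_config(
    150, 150, p_hit = 0.85, p_fa = 0.30, laser_window = c(0.2, 1.0),
    delta_p_fa_laser = 0.19, seed = master_seed + 1000L + m))
  write_trials(early, file.path(sim_dir, "laser_early", sprintf("mouse%02d.csv", m)))
  late <- simulate_session(behavior_gen_config(
    150, 150, p_hit = 0.85, p_fa = 0.30, laser_window = c(1.2, 1.7),
    delta_p_fa_laser = 0.19, seed = master_seed + 2000L + m))
  write_trials(late, file.path(sim_dir, "laser_late", sprintf("mouse%02d.csv", m)))
}
cat("laser experiments: 8 mice x {early, late} windows written\n")

## Recording session and unit populations ------------------------------------
rec <- simulate_session(behavior_gen_config(60, 60, seed = master_seed + 5000L))
write_trials(rec, file.path(sim_dir, "recording_trials.csv"))

# 40 units per condition: 60% stimulus-selective, 40% equal-amplitude;
# preferred stimulus split between the two tones. WM units keep delay
# activity until 1.0 s from stimulus onset, passive units only until 0.5 s.
mix_sampler <- function(condition) {
  function(i) {
    selective <- i <= 24
    base <- list(r0 = stats::runif(1, 3, 8),
                 a_pref = if (selective) stats::runif(1, 15, 25) else stats::runif(1, 8, 15),
                 a_nonpref = NA, preferred_hz = if (i %% 2) 3 else 12)
    base$a_nonpref <- if (selective) base$a_pref - stats::runif(1, 10, 15) else base$a_pref
    base$a_nonpref <- max(base$a_nonpref, 0)
    if (condition == "WM") {
      do.call(unit_gen_config, c(base, list(tau_delay = 0.8, t_end_from_onset = 1.0)))
    } else {
      do.call(passive_unit_config, base)
    }
  }
}
wm_units <- simulate_population(40, mix_sampler("WM"), rec,
                                seed = master_seed + 6000L, id_prefix = "wm")
pv_units <- simulate_population(40, mix_sampler("passive"), rec,
                                seed = master_seed + 7000L, id_prefix = "pv")
write_spikes(wm_units, file.path(sim_dir, "recording_spikes_wm.csv"))
write_spikes(pv_units, file.path(sim_dir, "recording_spikes_passive.csv"))
cat("recording session: 40 WM + 40 passive units written\n")

## Small format examples kept with the results -------------------------------
ex <- simulate_session(behavior_gen_config(15, 15, laser_window = c(0.2, 1.0),
                                           delta_p_fa_laser = 0.19,
                                           seed = master_seed))
write_trials(ex, "results/data/example_trials.csv")
write_spikes(simulate_population(2, unit_gen_config(), ex, seed = master_seed),
             "results/data/example_spikes.csv")
cat("format examples in results/data/\n")
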