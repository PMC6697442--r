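#!/usr/bin/env Rscript
# Stage 1: generate the synthetic knockdown datasets.
#
# Two ground-truth interaction networks for the four-species consortium
# (E. coli, S. Typhimurium, B. thetaiotaomicron, B. fragilis):
#   * wild-type-like: all-antagonistic, 7 of 12 candidate edges present,
#     carrying capacities near 1e9 CFU/ml;
#   * engineered-like: growth rates a third of wild type, carrying
#     capacities 1.5 orders of magnitude lower, two positive
#     cross-feeding edges (BF -> Ec, BF -> ST) plus two negative edges.
# Each is simulated under the five-condition design (equal inoculum +
# four 10-fold single-species knockdowns), 3 replicates, 8 sampling
# times over 27 h, with process noise and the 1e3 CFU/ml detection
# floor. These main-line datasets carry no multiplicative measurement
# error: the inference likelihood treats observed abundances as latent
# states, so this is the regime the model itself describes. The effect
# of qPCR-like lognormal measurement error (5% CV by default in
# noise_model()) is probed separately as a robustness stress in stage 3.

library(ssglv)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 20260919

for (preset in c("wt", "engineered")) {
  params <- if (preset == "wt") preset_wt_network(1) else
    preset_engineered_network(1)
  design <- make_knockdown_design(params$species)
  gd <- generate_dataset(params, design, noise_model(measurement_cv = 0),
                         seed = seed)
  write_trajectories(gd$dataset,
                     file.path(out_dir, paste0(preset, "_trajectories.tsv")))
  write_ground_truth(gd$truth,
                     file.path(out_dir, paste0(preset, "_truth.yaml")))
  n_cens <- sum(gd$dataset$censored)
  cat(sprintf("%s: %d rows (%d censored at the detection floor) -> %s\n",
              preset, nrow(gd$dataset), n_cens,
              file.path(out_dir, paste0(preset, "_trajectories.tsv"))))
}
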