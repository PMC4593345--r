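#!/usr/bin/env Rscript
# Generate the two synthetic study layouts the pipeline is exercised on:
#   paired  — 8 patients, one lesion (HELU) and one matched normal (TDLU)
#             sample each, 360-gene panel, 30 genes with a planted log2
#             effect of 2.0;
#   triplet — 8 patients, matched HN / ADH / DCIS samples, with effects
#             planted in both lesion classes.
# Inputs for the downstream scripts are written in the pipeline's TSV
# formats under results/simulated/.

suppressPackageStartupMessages(library(lesionDE))

paired <- simulate_study(simulation_params(
  n_patients = 8, classes = c("TDLU", "HELU"),
  n_genes = 360, n_de_genes = 30, effect_size = 2.0, noise_sd = 0.5,
  frac_unmatched_genes = 8 / 368, seed = 20260901))
p_paths <- write_simulated_study(paired, "results/simulated/paired")

triplet <- simulate_study(simulation_params(
  n_patients = 8, classes = c("HN", "ADH", "DCIS"),
  n_genes = 360, n_de_genes = 30, effect_size = 2.0, noise_sd = 0.5,
  seed = 20260902))
t_paths <- write_simulated_study(triplet, "results/simulated/triplet")

for (st in list(paired = paired, triplet = triplet)) {
  cat(sprintf("layout %-22s: %4d probe sets x %2d samples, %d/%d genes DE\n",
              paste(unique(st$design$tissue_class), collapse = "/"),
              nrow(st$expr), ncol(st$expr),
              sum(st$truth$genes$is_de), nrow(st$truth$genes)))
}
cat("written:", paste(basename(c(p_paths, t_paths)), collapse = ", "), "\n")
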