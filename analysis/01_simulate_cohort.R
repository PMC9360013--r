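#!/usr/bin/env Rscript
# Stage 1: simulate the paired mother-daughter cohort.
#
# Generates ground-truth compositions, the full optical measurement session
# (2,016 spectra: 84 participants x 2 breasts x 6 distances x 2 placements)
# with noise and wavelength dropout, imaging-derived volumes and covariates.
# Small tables go to results/cohort/; the bulky long-format spectra table is
# an intermediate and goes to scratch/cohort/.
suppressPackageStartupMessages(library(osdensity))

cfg <- pipeline_config(cohort = cohort_config(n_pairs = 42, seed = 20180601))
cat(sprintf("simulating %d pairs (seed %d, config %s)\n",
            cfg$cohort$n_pairs, cfg$seed, config_hash(cfg)))

coh <- simulate_cohort(cfg$cohort)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)
write_output_table(coh$truth, "results/cohort/ground_truth.csv",
                   seed = cfg$seed, config = cfg)
write_output_table(coh$measures, "results/cohort/imaging_measures.csv",
                   seed = cfg$seed, config = cfg)
write_output_table(coh$covariates, "results/cohort/covariates.csv",
                   seed = cfg$seed, config = cfg)
write_output_table(coh$spectra, "scratch/cohort/spectra.csv",
                   seed = cfg$seed, config = cfg)
save_pipeline_config(cfg, "results/cohort/config.yaml")

cat(sprintf("wrote %d participants, %d spectra rows, %d imaging rows\n",
            nrow(coh$truth), nrow(coh$spectra), nrow(coh$measures)))
cat(sprintf("daughter %%BDI mean (sd): %.1f (%.1f); mother: %.1f (%.1f)\n",
            mean(coh$truth$true_pct_density[coh$truth$group == "daughter"]),
            sd(coh$truth$true_pct_density[coh$truth$group == "daughter"]),
            mean(coh$truth$true_pct_density[coh$truth$group == "mother"]),
            sd(coh$truth$true_pct_density[coh$truth$group == "mother"])))
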