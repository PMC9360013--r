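#!/usr/bin/env Rscript
# Stage 2: spectrum quality control and constrained chromophore fitting.
#
# Applies the usability rules (>= 7 wavelengths; 985 nm; 905 or 940 nm),
# fits every retained spectrum by multi-start bound-constrained least
# squares, keeps each spectrum's best fit with at most 2 parameters at
# bounds, and averages within participant.
suppressPackageStartupMessages({
  library(osdensity)
  library(dplyr)
})

cfg <- load_pipeline_config("results/cohort/config.yaml")
spectra <- read_spectra_table("scratch/cohort/spectra.csv")

n_total <- nrow(distinct(spectra, participant_id, side, spectrum_id))
cat(sprintf("fitting: %d spectra in (seed %d)\n", n_total, cfg$seed))

res <- run_spectral_pipeline(spectra, n_starts = cfg$n_starts,
                             seed = cfg$seed,
                             residual_scale = cfg$residual_scale)

# QC accounting in the style of the instrument's flow numbers
excl <- table(res$exclusions$reason)
cat(sprintf("QC: %d retained; excluded: %s\n",
            n_total - nrow(res$exclusions),
            paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")))
cat(sprintf("fits accepted: %d of %d retained spectra\n",
            sum(res$fit_log$accepted), nrow(res$fit_log)))
if (nrow(res$participants_excluded))
  cat("participants without usable spectra:",
      paste(res$participants_excluded$participant_id, collapse = ", "), "\n")

dir.create("results/fit", recursive = TRUE, showWarnings = FALSE)
write_output_table(res$compositions, "results/fit/compositions.csv",
                   seed = cfg$seed, config = cfg)
write_output_table(res$exclusions, "results/fit/exclusion_log.csv",
                   seed = cfg$seed, config = cfg)
write_output_table(res$fit_log, "results/fit/fit_log.csv",
                   seed = cfg$seed, config = cfg)
write_output_table(res$participants_excluded,
                   "results/fit/participants_excluded.csv",
                   seed = cfg$seed, config = cfg)
cat(sprintf("wrote compositions for %d participants\n",
            nrow(res$compositions)))
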