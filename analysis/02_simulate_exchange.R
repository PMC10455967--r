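#!/usr/bin/env Rscript
# Synthetic rapid-sampling H/D exchange experiment.
#
# Generates the centroided ESI-TOF time course the quantification pipeline
# consumes: triplicate runs sampled every 15 s over 90 s after dissolution
# in deuterated methanol, exchange at k1 = 0.1311 s^-1 and k2 = 0.0755
# s^-1, 3% multiplicative intensity noise per centroid, then extracts and
# corrects the d0/d1/d2 fractions.

library(petrokin)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(k1 = 0.1311, k2 = 0.0755, noise_cv = 0.03, seed = 17)
spectra <- simulate_time_course(cfg)
write_peaks_csv(spectra, "results/peaks.csv")
cat(sprintf("simulated %d spectra (%d replicates x %d timepoints)\n",
            length(spectra), cfg$n_replicates, length(cfg$t_grid)))

series <- correct_time_series(spectra, cfg$ec, max_d = 2,
                              resolving_power = cfg$resolving_power,
                              abundance_floor = cfg$abundance_floor)
write_fractions_csv(series, "results/fractions.csv")

cat("\ncorrected isotopologue fractions (replicate 1):\n")
print(format(subset(as.data.frame(series), replicate_id == "rep1",
                    select = c(time_s, f_d0, f_d1, f_d2)), digits = 3),
      row.names = FALSE)
cat("\nby 90 s the d2 species dominates: exchange is essentially complete\nwithin the sampling window.\n")
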