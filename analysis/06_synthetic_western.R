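#!/usr/bin/env Rscript
# Synthetic redox-Western experiment and statistical comparison.
#
# Emulates the experimental readout: per-dose/time/replicate band
# intensities for reduced (monomer) and oxidized (dimer) Prx3 plus a
# loading control, generated from model trajectories under a synthetic
# D-alanine -> kDAAO dose map with multiplicative log-normal noise.
# Each time point is then analyzed as in the wet experiment: densitometry
# fractions, one-way ANOVA across doses, Tukey HSD against the 0 mM
# control.  Expected findings: fraction oxidized rises with dose at every
# time; the dose trend is highly significant at n = 3 replicates.

library(mitoredox)
dir.create("results", showWarnings = FALSE)

dm <- dose_map()
obs <- simulate_westerns(dm, times_min = c(15, 30, 60), n_reps = 3,
                         noise = noise_model(0.1, 0.15), seed = 1)
fr <- densitometry_fractions(obs)
write.csv(fr, "results/synthetic_westerns.csv", row.names = FALSE)

stats <- lapply(c(15, 30, 60), function(tm) {
  res <- anova_tukey(fr[fr$time_min == tm, ])
  cat(sprintf("t = %2d min: omnibus P = %.2e; significant doses vs 0 mM: %s\n",
              tm, res$p_omnibus,
              paste(res$vs_control$dose_mM[res$vs_control$significant],
                    collapse = ", ")))
  c(list(time_min = tm), res)
})
jsonlite::write_json(stats, "results/western_anova.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

means <- aggregate(fraction_oxidized ~ dose_mM + time_min, fr, mean)
print(reshape(means, idvar = "dose_mM", timevar = "time_min",
              direction = "wide"), digits = 3)
cat("wrote results/synthetic_westerns.csv and results/western_anova.json\n")
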