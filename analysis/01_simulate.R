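#!/usr/bin/env Rscript
# Stage 1: simulate the study.
#
# Two chemicals are emulated on the study's dilution designs: "chemA" on the
# 50 -> 0.2048 uM series (2.5x, 7 levels) and the more potent "chemB" on the
# 10 -> 0.04096 uM series, each with 3 technical x 3 biological treated
# replicates per concentration, 27 vehicle controls, pooled QCs and
# extraction blanks per time point. chemA is sampled at 2, 24 and 48 h with
# planted potency increasing over exposure time (the half-max concentrations
# of its responsive features shrink), so the POD time trend is recoverable
# downstream. Acquisition artifacts are overlaid: +2 -> -2 ppm mass-accuracy
# drift, 1.3x in-batch signal drift, and intensity-threshold (MNAR) dropout.

suppressPackageStartupMessages(library(bmcpod))

seed <- 2026
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

scale_potency <- function(truths, fold) {
  i <- truths$category == "responsive"
  truths$k[i] <- truths$k[i] / fold
  truths$true_bmc_1sd[i] <- truths$true_bmc_1sd[i] / fold
  truths
}

datasets <- list(
  list(chem = "chemA", top = 50, time = 2,  potency = 0.25),
  list(chem = "chemA", top = 50, time = 24, potency = 1),
  list(chem = "chemA", top = 50, time = 48, potency = 4),
  list(chem = "chemB", top = 10, time = 24, potency = 1)
)

# a few responsive features sit at library adduct m/z (within ~1 ppm), so
# the annotated-POD method has something to find
library_mz <- c(
  adduct_mz(monoisotopic_mass("C10H12N2O3"), "[M+H]+") * (1 + 0.8e-6),
  adduct_mz(monoisotopic_mass("C59H106O6"), "[M+NH4]+") * (1 - 0.6e-6),
  adduct_mz(monoisotopic_mass("C7H15NO3"), "[M+H]+") * (1 + 1.2e-6)
)

for (ds in datasets) {
  d <- build_design(ds$top, 2.5, 7, chemical = ds$chem,
                    time_points = ds$time, n_qc = 12, n_blank = 4,
                    n_batches = 2)
  tr <- make_truths(d, n_responsive = 35, n_null = 40, n_blank_only = 3,
                    sdlog = 0.1, seed = seed + ds$time)
  tr <- scale_potency(tr, ds$potency)
  ri <- which(tr$category == "responsive")
  tr$feature_mz[ri[seq_along(library_mz)]] <- round(library_mz, 5)
  tab <- simulate_intensities(d, tr, noise = list(sdlog = 0.1),
                              seed = seed + ds$time)
  tab <- apply_artifacts(tab,
                         drift = list(ppm_start = 2, ppm_end = -2,
                                      fold_end = 1.3),
                         missing = list(threshold = 2e5),
                         seed = seed + ds$time)
  prefix <- file.path(out_dir, sprintf("%s_t%02d", ds$chem, ds$time))
  write_feature_table(tab, prefix)
  truth <- attr(tab, "truth")
  jsonlite::write_json(truth, paste0(prefix, "_truth.json"), digits = NA)
  resp <- truth[truth$category == "responsive", ]
  cat(sprintf(
    "%s %2d h: %d samples x %d features; %d responsive (true 1 SD BMC %.3g-%.3g uM)\n",
    ds$chem, ds$time, nrow(tab$samples), nrow(tab$features),
    nrow(resp), min(resp$true_bmc_1sd), max(resp$true_bmc_1sd)))
}
cat("feature tables written under", out_dir, "\n")
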