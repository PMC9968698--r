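#!/usr/bin/env Rscript
# Stage 5: putative annotation of concentration-responsive features.
#
# Features passing the dual-BMR screen are matched against the bundled
# synthetic metabolite library (name, formula, ionisation mode): each
# library formula yields its monoisotopic mass and the positive-mode adduct
# m/z values ([M+H]+, [M+Na]+, [M+NH4]+, with electron-mass bookkeeping),
# and features within +/- 5 ppm are reported. Isobaric entries produce
# multiple annotations per feature, deliberately left undisambiguated.

suppressPackageStartupMessages(library(bmcpod))

in_dir <- "results/bmc"
out_dir <- "results/annotation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

scr <- read.table(file.path(in_dir, "screen_all.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
lib <- read_library(system.file("extdata",
                                "metabolite_library_synthetic.tsv",
                                package = "bmcpod"))
passed <- scr[scr$passed_dual, c("feature_id", "mz")]
passed <- passed[!duplicated(passed$feature_id), ]
ann <- match_library(passed, lib, tolerance_ppm = 5, mode = "positive")
write.table(ann, file.path(out_dir, "annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "%d of %d dual-pass features carry >= 1 putative annotation (of %d library entries)\n",
  length(unique(ann$feature_id)), nrow(passed), nrow(lib)))
if (nrow(ann))
  print(ann[, c("feature_id", "name", "adduct", "ppm")], row.names = FALSE)
cat("annotations written under", out_dir, "\n")
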