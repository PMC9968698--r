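#!/usr/bin/env Rscript
# Stage 4: POD derivation and time-course summary.
#
# Screened features are rank-ordered by their 1 SD BMC; PODs are derived by
# the three methods (1st ranked feature, 1st annotated feature, n-th ranked
# feature with n = 25), flagged against the extrapolation floor (1/3 of the
# lowest tested concentration), and the chemA time course is summarised as
# the fold decrease between the earliest and latest sampling points.
# Accumulation curves and the POD-versus-time figure are written alongside.

suppressPackageStartupMessages(library(bmcpod))

in_dir <- "results/bmc"
out_dir <- "results/pod"
fig_dir <- "results/figures"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

scr <- read.table(file.path(in_dir, "screen_all.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
lib <- read_library(system.file("extdata",
                                "metabolite_library_synthetic.tsv",
                                package = "bmcpod"))
floors <- c(chemA = extrapolation_floor(build_design(50, 2.5, 7)),
            chemB = extrapolation_floor(build_design(10, 2.5, 7)))

pods <- list(); curves <- list()
for (key in unique(paste(scr$chemical, scr$time))) {
  part <- scr[paste(scr$chemical, scr$time) == key, ]
  chem <- part$chemical[1]; tp <- part$time[1]
  ranked <- rank_records(part)
  ann <- if (nrow(ranked))
    match_library(ranked[, c("feature_id", "mz")], lib, 5, "positive")
  else NULL
  for (meth in c("first_unannotated", "first_annotated", "nth_feature")) {
    pod <- derive_pod(ranked, meth, annotations = ann, n = 25,
                      floor = floors[[chem]])
    pod$chemical <- chem; pod$time <- tp; pod$assay <- "polar_pos"
    pods[[paste(key, meth)]] <- pod
  }
  cv <- accumulation_curve(part)
  if (nrow(cv)) {
    cv$group <- sprintf("%s %d h", chem, tp)
    curves[[key]] <- cv
  }
}
pods <- do.call(rbind, pods)
rownames(pods) <- NULL
write.table(pods, file.path(out_dir, "pods.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("PODs (uM):\n")
print(pods[, c("chemical", "time", "method", "status", "pod", "feature_id",
               "below_extrapolation_floor")], row.names = FALSE)

# chemA time course from the first-ranked-feature method
m1 <- pods[pods$method == "first_unannotated" & pods$chemical == "chemA" &
             pods$status == "ok", ]
tc <- time_course(data.frame(assay = m1$assay, time = m1$time,
                             pod = m1$pod))
write.table(tc$fold, file.path(out_dir, "time_course_fold.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf(
  "\nchemA first-ranked-feature POD falls %.1f-fold from %g h to %g h\n",
  tc$fold$fold[1], tc$fold$earliest[1], tc$fold$latest[1]))

curves <- do.call(rbind, curves)
ggplot2::ggsave(file.path(fig_dir, "accumulation.png"),
                plot_accumulation(curves, floors[["chemA"]]),
                width = 7, height = 5, dpi = 150)
ggplot2::ggsave(file.path(fig_dir, "pod_time.png"),
                plot_pod_time(data.frame(assay = m1$assay, time = m1$time,
                                         pod = m1$pod),
                              floors[["chemA"]]),
                width = 5, height = 4, dpi = 150)
cat("figures written under", fig_dir, "\n")
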