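# End-to-end orchestration: simulate (optionally), preprocess, screen per
# chemical x time point, rank, derive PODs by the three methods, annotate,
# and report. Fully deterministic given the seed in the config.

#' Build a run configuration
#'
#' @param design A [build_design()] object (used when simulating and for the
#'   extrapolation floor).
#' @param table A [feature_table()]; `NULL` simulates one from `design`,
#'   `truths` and `seed`.
#' @param truths Truth data frame for simulation (default: a standard
#'   responsive + null mixture from [make_truths()]).
#' @param library Metabolite library data frame from [read_library()]
#'   (`NULL`: the first-annotated POD method reports `undefined`).
#' @param assay Assay label (e.g. `polar_pos`); also selects the ionisation
#'   mode for annotation (`*_pos` = positive).
#' @param cascade A [cascade_config()].
#' @param bmr Benchmark responses in SD multiples (filter pass first).
#' @param confidence BMCL/BMCU confidence level.
#' @param max_iter Optimiser iteration cap.
#' @param p_min,bmc_bmcl_max Retention criteria thresholds.
#' @param pod_n Rank for the n-th-feature POD method.
#' @param tolerance_ppm Annotation tolerance.
#' @param seed Integer seed for all randomness.
#' @return List of class `run_config`.
#' @export
run_config <- function(design, table = NULL, truths = NULL, library = NULL,
                       assay = "polar_pos", cascade = cascade_config(),
                       bmr = c(3, 1), confidence = 0.95, max_iter = 250,
                       p_min = 1e-4, bmc_bmcl_max = 20, pod_n = 25,
                       tolerance_ppm = 5, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' simulate (optional) -> preprocessing cascade -> per chemical x time point
#' BMC group preparation, imputation, glog transform and dual-BMR screening
#' -> ranking -> PODs by the three methods -> annotation -> report.
#'
#' @param config A [run_config()].
#' @return List of class `run_report`: `filter_log`, `screen` (per
#'   chemical/time BMC records), `pods`, `annotations`, `floor`,
#'   `glog_lambda`, `config` echo, `version`, `timestamp`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  design <- config$design
  tab <- config$table
  if (is.null(tab)) {
    truths <- config$truths
    if (is.null(truths))
      truths <- make_truths(design, n_responsive = 15, n_null = 60,
                            n_blank_only = 3, seed = config$seed)
    tab <- simulate_intensities(design, truths, seed = config$seed)
    tab <- apply_artifacts(tab,
                           drift = list(ppm_start = 2, ppm_end = -2,
                                        fold_end = 1.2),
                           missing = list(threshold = 2e5),
                           seed = config$seed)
  }
  casc <- run_cascade(tab, config$cascade)
  floor <- extrapolation_floor(design)
  mode <- if (grepl("neg", config$assay)) "negative" else "positive"

  chems <- unique(stats::na.omit(casc$table$samples$chemical))
  times <- unique(stats::na.omit(casc$table$samples$time))
  screens <- list(); pods <- list(); annos <- list()
  for (ch in chems) for (tp in times) {
    prep <- tryCatch(prepare_bmc_groups(casc$table, ch, tp,
                                        config$cascade$group_min),
                     error = function(e) NULL)
    if (is.null(prep) || ncol(prep$table$intensities) == 0) next
    sub <- impute_knn(prep$table, config$cascade$knn_k)
    sub <- glog_mean_centre(sub, lambda = casc$glog_lambda, centre = FALSE)
    keep <- sub$samples$class %in% c("study", "control")
    scr <- screen_features(sub$samples$conc[keep],
                           sub$intensities[keep, , drop = FALSE],
                           sub$features,
                           bmr = config$bmr, confidence = config$confidence,
                           max_iter = config$max_iter, p_min = config$p_min,
                           bmc_bmcl_max = config$bmc_bmcl_max)
    scr$chemical <- ch; scr$time <- tp; scr$rule <- prep$rule
    screens[[paste(ch, tp)]] <- scr
    ranked <- rank_records(scr)
    ann <- NULL
    if (!is.null(config$library) && nrow(ranked)) {
      ann <- match_library(ranked[, c("feature_id", "mz")], config$library,
                           config$tolerance_ppm, mode)
      if (nrow(ann)) {
        ann$chemical <- ch; ann$time <- tp
        annos[[paste(ch, tp)]] <- ann
      }
    }
    for (meth in c("first_unannotated", "first_annotated", "nth_feature")) {
      pod <- derive_pod(ranked, meth, annotations = ann, n = config$pod_n,
                        floor = floor)
      pod$chemical <- ch; pod$time <- tp; pod$assay <- config$assay
      pods[[paste(ch, tp, meth)]] <- pod
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, unname(l)) else NULL
  structure(list(filter_log = casc$log, screen = bind(screens),
                 pods = bind(pods), annotations = bind(annos),
                 floor = floor, glog_lambda = casc$glog_lambda,
                 pca_outliers = casc$pca_outliers,
                 table = casc$table,
                 config = config,
                 version = as.character(utils::packageVersion("bmcpod")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (", x$version, ")\n", sep = "")
  if (!is.null(x$screen))
    cat("  screened features:", nrow(x$screen),
        " passed dual criteria:", sum(x$screen$passed_dual), "\n")
  if (!is.null(x$pods)) {
    ok <- x$pods[x$pods$status == "ok", ]
    cat("  PODs derived:", nrow(ok), "of", nrow(x$pods), "requested\n")
  }
  cat("  extrapolation floor:", signif(x$floor, 5), "uM\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `report.json` (filter log, counts, PODs, config echo), delimited
#' result tables (`screen.tsv`, `pods.tsv`, `annotations.tsv`) and, when
#' results are present, accumulation-curve and POD-versus-time figures.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param plots Also write figures (default TRUE).
#' @return Invisibly, the files written.
#' @export
write_report <- function(report, dir, plots = TRUE) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  files <- character(0)
  wtab <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wtab(report$filter_log, "filter_log.tsv")
  wtab(report$screen, "screen.tsv")
  wtab(report$pods, "pods.tsv")
  wtab(report$annotations, "annotations.tsv")
  js <- list(
    version = report$version,
    timestamp = report$timestamp,
    floor_uM = report$floor,
    glog_lambda = report$glog_lambda,
    pca_outliers = report$pca_outliers,
    filter_log = report$filter_log,
    n_screened = if (is.null(report$screen)) 0L else nrow(report$screen),
    n_passed_dual = if (is.null(report$screen)) 0L
                    else sum(report$screen$passed_dual),
    pods = report$pods,
    config = list(assay = report$config$assay, bmr = report$config$bmr,
                  confidence = report$config$confidence,
                  max_iter = report$config$max_iter,
                  p_min = report$config$p_min,
                  bmc_bmcl_max = report$config$bmc_bmcl_max,
                  pod_n = report$config$pod_n,
                  tolerance_ppm = report$config$tolerance_ppm,
                  seed = report$config$seed)
  )
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(js, pj, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, pj)
  if (plots && !is.null(report$screen) && any(report$screen$passed_dual)) {
    curve <- accumulation_curve(report$screen)
    p1 <- plot_accumulation(curve, report$floor)
    f1 <- file.path(dir, "accumulation.png")
    ggplot2::ggsave(f1, p1, width = 5, height = 4, dpi = 150)
    files <- c(files, f1)
    ok <- report$pods[report$pods$status == "ok" &
                        report$pods$method == "first_unannotated", ]
    if (nrow(ok) > 1) {
      tcp <- data.frame(assay = ok$assay, time = ok$time, pod = ok$pod)
      f2 <- file.path(dir, "pod_time.png")
      ggplot2::ggsave(f2, plot_pod_time(tcp, report$floor),
                      width = 5, height = 4, dpi = 150)
      files <- c(files, f2)
    }
  }
  invisible(files)
}
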