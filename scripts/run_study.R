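#!/usr/bin/env Rscript

# Thin command-line wrapper over the trochfem pipeline.
#
#   Rscript scripts/run_study.R run   [--config cfg.yaml] [--seed N]
#                                     [--out DIR] [--formats csv,json,vtu,stl]
#   Rscript scripts/run_study.R score --table indicators.csv [--out DIR]
#
# Exit codes: 0 success, 2 configuration error, 3 solver failure, 4 I/O error.

suppressPackageStartupMessages({
  library(optparse)
  library(trochfem)
})

args <- commandArgs(trailingOnly = TRUE)
verb <- if (length(args) >= 1) args[[1]] else ""
rest <- args[-1]

fail <- function(code, msg) {
  message(msg)
  quit(status = code, save = "no")
}

if (!verb %in% c("run", "score")) {
  fail(2, "usage: run_study.R <run|score> [options]; see script header")
}

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--table", type = "character", default = NULL),
  make_option("--out", type = "character", default = "study_out"),
  make_option("--formats", type = "character", default = "csv,json")
))
opts <- parse_args(parser, args = rest)

if (verb == "run") {
  cfg <- tryCatch({
    cfg <- if (is.null(opts$config)) study_config() else read_study_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- opts$seed
    cfg
  }, error = function(e) fail(2, paste("config error:", conditionMessage(e))))
  formats <- strsplit(opts$formats, ",")[[1]]
  report <- tryCatch(
    run_study(cfg, keep_meshes = any(c("vtu", "stl") %in% formats),
              verbose = TRUE),
    error = function(e) fail(3, paste("solver failure:", conditionMessage(e))))
  if (!is.null(report$failures)) {
    print(report$failures)
    message("study finished with variant failures")
  }
  tryCatch(export_artifacts(report, opts$out, formats = formats),
           error = function(e) fail(4, paste("I/O error:", conditionMessage(e))))
  print(report)
  if (!is.null(report$failures)) quit(status = 3, save = "no")
} else {
  if (is.null(opts$table)) fail(2, "score needs --table <csv>")
  sc <- tryCatch(run_scoring(opts$table),
                 error = function(e) fail(2, paste("parse error:", conditionMessage(e))))
  print(sc$instability)
  cat(sprintf("concordance with reference ordering: %.3f (exact match: %s)\n",
              sc$ranking$concordance, sc$ranking$exact_match))
  tryCatch({
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    pr <- sc$instability$per_indicator_ratios
    utils::write.csv(
      data.frame(model = rownames(pr), pr,
                 mean_ratio = sc$instability$mean_ratio, check.names = FALSE),
      file.path(opts$out, "instability_ratios.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(ranking = sc$ranking$ranking, concordance = sc$ranking$concordance,
           exact_match = sc$ranking$exact_match,
           mean_ratio = as.list(sc$instability$mean_ratio)),
      file.path(opts$out, "scoring_summary.json"), auto_unbox = TRUE, digits = NA)
  }, error = function(e) fail(4, paste("I/O error:", conditionMessage(e))))
}
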