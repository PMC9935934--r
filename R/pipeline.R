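# Study orchestration: build the eight wall-defect assemblies, assign
# materials, solve the selected load cases (with repetitions re-randomizing
# the seeded fracture line and HU noise), extract indicators, and score the
# relative instability ratios.

#' Study configuration
#'
#' Collects every tunable of a full wall-defect study. Defaults reproduce
#' the package's reference desk-scale study: eight variants, static walking
#' and climbing plus the quasi-static climbing envelope, three repetitions
#' with re-randomized fracture line and HU noise, instability scored on the
#' dynamic climbing envelope.
#'
#' @param femur,implant,rules,hu,calibration,contact,thresholds Component
#'   parameter objects (see their constructors).
#' @param variants Character vector of variants to run.
#' @param load_cases Character vector of load case names.
#' @param target_edge Mesh grid spacing, mm.
#' @param order Element order (1 or 2).
#' @param fracture_amplitude Fracture-line perturbation amplitude, mm.
#' @param n_material_bins Bone modulus bins (NULL = continuous).
#' @param scoring_load_case Load case whose indicators feed the instability
#'   scoring; `NULL` picks the dynamic climbing envelope when it is run,
#'   otherwise the last load case listed.
#' @param gait_phases Number of phases per gait cycle.
#' @param repetitions Number of stochastic repetitions (>= 1).
#' @param seed Master seed; every randomness source derives from it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(femur = femur_params(), implant = implant_spec(),
                         rules = defect_rules(), hu = hu_field_spec(),
                         calibration = material_calibration(),
                         contact = contact_spec(),
                         thresholds = risk_thresholds(),
                         variants = fracture_variants(),
                         load_cases = c("static_walking", "static_climbing",
                                        "dynamic_climbing"),
                         target_edge = 4, order = 1,
                         fracture_amplitude = 3,
                         n_material_bins = 10,
                         scoring_load_case = NULL,
                         gait_phases = 8,
                         repetitions = 3, seed = 1L) {
  check_that(repetitions >= 1, "repetitions must be >= 1")
  check_that(all(variants %in% fracture_variants()),
             "unknown variant(s): %s",
             paste(setdiff(variants, fracture_variants()), collapse = ", "))
  scoring_load_case <- scoring_load_case %||%
    (if ("dynamic_climbing" %in% load_cases) "dynamic_climbing"
     else load_cases[length(load_cases)])
  check_that(scoring_load_case %in% load_cases,
             "scoring_load_case must be one of load_cases")
  seed <- as.integer(seed)
  repetitions <- as.integer(repetitions)
  structure(as.list(environment())[names(formals(study_config))],
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Scalar fields override the defaults of [study_config()]; nested blocks
#' (`femur`, `implant`, `rules`, `hu`, `calibration`, `contact`,
#' `thresholds`) override the corresponding constructor arguments.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  ctors <- list(femur = femur_params, implant = implant_spec,
                rules = defect_rules, hu = hu_field_spec,
                calibration = material_calibration, contact = contact_spec,
                thresholds = risk_thresholds)
  args <- list()
  for (nm in names(y)) {
    if (nm %in% names(ctors)) {
      args[[nm]] <- do.call(ctors[[nm]], y[[nm]])
    } else {
      args[[nm]] <- y[[nm]]
    }
  }
  do.call(study_config, args)
}

# derive the per-repetition seed from the master seed (kept below 2^31)
rep_seed <- function(seed, rep) (as.integer(seed) + 7919L * (as.integer(rep) - 1L)) %% 2147483647L

solve_case <- function(assembly, materials, case_name, config, ctx) {
  lc <- load_case(case_name)
  if (lc$dynamic) {
    solve_gait(assembly, materials, lc,
               template = gait_template(lc$gait, n_phases = config$gait_phases),
               contact = config$contact, ctx = ctx)
  } else {
    solve_static(assembly, materials, lc, contact = config$contact, ctx = ctx)
  }
}

#' Run the full wall-defect instability study
#'
#' Builds every requested variant (for every repetition, with the fracture
#' line and HU noise re-randomized from the derived seed), assigns
#' materials, solves the requested load cases, extracts the outcome
#' indicators, and scores the relative instability ratios on the scoring
#' load case (repetition means). A failing variant is recorded and skipped;
#' the remaining variants still run.
#'
#' @param config A [study_config()].
#' @param keep_meshes Keep the per-variant assemblies of the first
#'   repetition in the report (needed for [export_artifacts()] mesh output).
#' @param verbose Print progress lines.
#' @return Object of class `study_report`: `indicators` (long data frame:
#'   variant, load_case, repetition, indicator, value), `summary`
#'   (mean/sd over repetitions), `instability`, `ranking` (vs the reference
#'   ordering), `equilibrium` log, `failures`, `provenance`.
#' @export
run_study <- function(config = study_config(), keep_meshes = FALSE,
                      verbose = interactive()) {
  t0 <- Sys.time()
  rows <- list()
  eq_log <- list()
  failures <- list()
  assemblies <- list()
  for (rep in seq_len(config$repetitions)) {
    srep <- rep_seed(config$seed, rep)
    for (variant in config$variants) {
      if (verbose) message(sprintf("[rep %d] %s", rep, variant))
      res <- tryCatch({
        assembly <- build_assembly(
          femur = config$femur, implant = config$implant, rules = config$rules,
          variant = variant, seed = srep,
          fracture_amplitude = config$fracture_amplitude,
          target_edge = config$target_edge, order = config$order)
        hu_spec <- config$hu
        hu_spec$seed <- srep + 1L
        hu <- synthesize_hu(assembly$mesh, hu_spec)
        materials <- assign_materials(assembly$mesh, hu, config$calibration,
                                      n_bins = config$n_material_bins)
        ctx <- fe_context(assembly, materials, config$contact)
        if (keep_meshes && rep == 1L) assemblies[[variant]] <- assembly
        for (case_name in config$load_cases) {
          sol <- solve_case(assembly, materials, case_name, config, ctx)
          ind <- extract_indicators(sol, assembly, config$thresholds)
          vals <- unlist(ind[vapply(ind, is.numeric, logical(1))])
          rows[[length(rows) + 1L]] <- data.frame(
            variant = variant, load_case = case_name, repetition = rep,
            indicator = names(vals), value = unname(vals))
          if (inherits(sol, "solve_result")) {
            eq_log[[length(eq_log) + 1L]] <- data.frame(
              variant = variant, load_case = case_name, repetition = rep,
              relative_residual = sol$equilibrium$relative_residual,
              iterations = sol$iterations)
          }
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) {
        failures[[length(failures) + 1L]] <- data.frame(
          variant = variant, repetition = rep, error = res)
      }
    }
  }
  indicators <- do.call(rbind, rows)
  check_that(!is.null(indicators), "every variant failed; no indicators produced")
  agg <- stats::aggregate(value ~ variant + load_case + indicator,
                          data = indicators, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean"
  sdv <- stats::aggregate(value ~ variant + load_case + indicator,
                          data = indicators, FUN = stats::sd)
  agg$sd <- sdv$value
  agg$sd[is.na(agg$sd)] <- 0

  instability <- NULL
  ranking <- NULL
  sc <- agg[agg$load_case == config$scoring_load_case &
              agg$indicator %in% default_indicator_columns(), ]
  if (nrow(sc) > 0 && length(unique(sc$variant)) >= 2) {
    tab <- stats::reshape(sc[, c("variant", "indicator", "mean")],
                          idvar = "variant", timevar = "indicator",
                          direction = "wide")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$variant
    colnames(m) <- sub("^mean\\.", "", colnames(m))
    m <- abs(m)
    m <- m[, default_indicator_columns()[default_indicator_columns() %in% colnames(m)],
           drop = FALSE]
    instability <- aggregate_instability(m)
    ranking <- rank_models(instability)
  }
  structure(
    list(indicators = indicators, summary = agg,
         instability = instability, ranking = ranking,
         equilibrium = if (length(eq_log)) do.call(rbind, eq_log) else NULL,
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         assemblies = assemblies,
         config = config,
         provenance = list(
           seed = config$seed,
           package_version = as.character(utils::packageVersion("trochfem")),
           started = format(t0), elapsed_s = as.numeric(Sys.time() - t0, "secs"))),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d indicator rows, %d variants, seed %d\n",
              nrow(x$indicators), length(unique(x$indicators$variant)),
              x$provenance$seed))
  if (!is.null(x$failures)) {
    cat(sprintf("FAILURES: %d (see $failures)\n", nrow(x$failures)))
  }
  if (!is.null(x$instability)) print(x$instability)
  invisible(x)
}

#' Score an indicator table without running the finite-element pipeline
#'
#' Standalone entry to the relative-instability scoring: accepts a CSV file
#' (rows = models, first column or row names = model codes, remaining
#' columns = indicator magnitudes) or a data frame / matrix, and returns the
#' per-indicator ratios, mean ratios, ranking, and concordance with the
#' reference ordering.
#'
#' @param x CSV path, data frame, or numeric matrix.
#' @param reference Reference ordering (most stable first).
#' @return List: `instability` (an `instability_result`) and `ranking`
#'   (see [rank_models()]).
#' @export
run_scoring <- function(x, reference = reference_instability_order()) {
  if (is.character(x) && length(x) == 1) {
    check_that(file.exists(x), "scoring input file '%s' does not exist", x)
    df <- utils::read.csv(x, check.names = FALSE)
    check_that(nrow(df) >= 2 && ncol(df) >= 2,
               "scoring table must have >= 2 model rows and an indicator column")
    first <- df[[1]]
    if (!is.numeric(first)) {
      rn <- as.character(first)
      df <- df[, -1, drop = FALSE]
      rownames(df) <- rn
    }
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad)) {
      stop_input("non-numeric indicator column(s): %s",
                 paste(names(df)[bad], collapse = ", "))
    }
    x <- as.matrix(df)
  }
  inst <- aggregate_instability(abs(as.matrix(x)))
  ranking <- if (length(intersect(reference, names(inst$mean_ratio))) >= 2) {
    rank_models(inst, reference)
  } else {
    # model names do not overlap the reference ordering: rank only
    list(ranking = inst$ranking, exact_match = NA, concordance = NA_real_)
  }
  list(instability = inst, ranking = ranking)
}

#' Export study artifacts
#'
#' Writes the indicator tables (CSV), the instability summary (CSV + JSON
#' with provenance), and optionally VTU volume meshes / STL surfaces of the
#' kept assemblies. File names encode variant and load case.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "json", "vtu", "stl")`.
#' @return Invisibly, the vector of files written.
#' @export
export_artifacts <- function(report, dir, formats = c("csv", "json")) {
  check_that(inherits(report, "study_report"), "report must be a study_report")
  formats <- match.arg(formats, c("csv", "json", "vtu", "stl"), several.ok = TRUE)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    check_that(dir.exists(dir), "cannot create output directory '%s'", dir)
  }
  files <- character(0)
  wf <- function(p) { files <<- c(files, p); p }
  if ("csv" %in% formats) {
    utils::write.csv(report$indicators, wf(file.path(dir, "indicators.csv")),
                     row.names = FALSE)
    utils::write.csv(report$summary, wf(file.path(dir, "indicators_summary.csv")),
                     row.names = FALSE)
    if (!is.null(report$instability)) {
      pr <- report$instability$per_indicator_ratios
      out <- data.frame(variant = rownames(pr), pr,
                        mean_ratio = report$instability$mean_ratio,
                        check.names = FALSE)
      utils::write.csv(out, wf(file.path(dir, "instability_ratios.csv")),
                       row.names = FALSE)
    }
  }
  if ("json" %in% formats) {
    summary <- list(
      provenance = report$provenance,
      seed = report$config$seed,
      ranking = if (!is.null(report$ranking)) report$ranking else NULL,
      mean_ratio = if (!is.null(report$instability))
        as.list(report$instability$mean_ratio) else NULL,
      failures = if (!is.null(report$failures)) report$failures$variant else character(0)
    )
    jsonlite::write_json(summary, wf(file.path(dir, "study_summary.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (any(c("vtu", "stl") %in% formats)) {
    for (variant in names(report$assemblies)) {
      a <- report$assemblies[[variant]]
      if ("vtu" %in% formats) {
        write_vtu(a$mesh, wf(file.path(dir, sprintf("mesh_%s.vtu", variant))),
                  cell_data = list(part = as.integer(factor(a$mesh$element_part)),
                                   volume = a$mesh$element_volume))
      }
      if ("stl" %in% formats) {
        for (part in unique(a$mesh$element_part)) {
          write_stl(extract_surface(a$mesh, part),
                    wf(file.path(dir, sprintf("surface_%s_%s.stl", variant, part))))
        }
      }
    }
  }
  invisible(files)
}
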