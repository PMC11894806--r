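# End-to-end orchestration: simulate -> harmonize -> fit -> assign ->
# validate, with serialized artifacts and seed fan-out. One global seed
# plus fixed per-stage offsets keeps each stage individually reproducible.

# Tiny polynomial hash of the deparsed config; stamps artifacts so a run
# directory can be matched to the configuration that produced it.
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Serialize a subtype model to JSON
#'
#' Writes the event grid, sequences (as per-position biomarker/threshold
#' pairs), mixture fractions, noise scales and provenance (seed, config
#' hash) to a JSON file readable by [read_model()]. MCMC samples are not
#' serialized.
#'
#' @param model a [subtype_model()].
#' @param path output file path.
#' @param meta optional named list merged into the JSON (e.g. seed,
#'   config_hash).
#' @export
write_model <- function(model, path, meta = list()) {
  grid <- model$grid
  ev <- grid$events
  seqs <- lapply(model$sequences, function(s) {
    data.frame(position = seq_along(s),
               biomarker = grid$biomarkers[ev$biomarker[s]],
               level = ev$level[s], z = ev$z[s])
  })
  obj <- c(list(
    grid = list(biomarkers = grid$biomarkers,
                thresholds = grid$thresholds,
                z_max = grid$z_max),
    sequences = seqs,
    fractions = model$fractions,
    sigma = model$sigma,
    loglik = model$fit$loglik %||% NA_real_
  ), meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a subtype model from JSON
#'
#' @param path file written by [write_model()].
#' @return A [subtype_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- event_grid(obj$grid$biomarkers,
                     lapply(obj$grid$thresholds, as.numeric),
                     as.numeric(obj$grid$z_max))
  ev <- grid$events
  seqs <- lapply(obj$sequences, function(df) {
    ids <- mapply(function(b, l)
      which(ev$biomarker == match(b, grid$biomarkers) & ev$level == l),
      df$biomarker, df$level)
    as.integer(ids[order(df$position)])
  })
  subtype_model(seqs, as.numeric(obj$fractions), grid,
                as.numeric(obj$sigma))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Convenience loader for [run_pipeline()] configs kept as files. The
#' format is chosen by extension (`.yaml`/`.yml` need the yaml package).
#'
#' @param path config file path.
#' @return Named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext)
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic cohort generation (unless a scan table is
#' supplied), hemisphere combination, control-anchored harmonization,
#' effect-size ROI selection, z-scoring, subtype/stage model fitting
#' (optionally with cross-validated selection of C), MCMC sampling,
#' assignment of baseline and follow-up scans, and longitudinal /
#' enrichment validation. All tabular artifacts are written under
#' `out_dir` along with a log recording the seed and config hash.
#'
#' @param config named list with (all optional unless noted):
#'   `out_dir` (required), `seed` (default 1), `cohort` (a
#'   [cohort_settings()] or argument list for it), `scans`/`truth`
#'   (pre-made tables, bypassing simulation), `threshold` (ROI |d| cutoff,
#'   default 0.6), `thresholds`/`z_max` (fit grid, defaults `c(1, 2, 3)`
#'   and 5), `n_subtypes` (default 2), `cv` (logical; run CVIC selection),
#'   `C_max` (default 3), `K` (folds, default 10), `fit` (argument list
#'   for [fit_settings()]).
#' @return Invisible list with every intermediate object (`scans`,
#'   `model`, `assignments`, `stability`, `progression`, `enrichment`,
#'   `cv`, paths).
#' @export
run_pipeline <- function(config) {
  if (is.null(config[["out_dir"]])) stop("config$out_dir is required")
  dir.create(config[["out_dir"]], recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config[["seed"]] %||% 1L)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  outfile <- function(f) file.path(config[["out_dir"]], f)
  log_lines <- c(sprintf("seed: %d", seed),
                 sprintf("config_hash: %s", hash),
                 sprintf("package: sustainz %s",
                         as.character(utils::packageVersion("sustainz"))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------
  if (is.null(config[["scans"]])) {
    settings <- stage("simulate", {
      s <- config[["cohort"]] %||% list()
      if (!inherits(s, "cohort_settings")) {
        s$seed <- s$seed %||% (seed + 101L)
        s <- do.call(cohort_settings, s)
      }
      s
    })
    cohort <- stage("simulate", generate_cohort(settings))
    fu <- stage("simulate", generate_followups(cohort, settings,
                                               seed = seed + 102L))
    scans <- rbind(cohort$scans, fu$scans)
    truth <- rbind(cohort$truth, fu$truth)
    schema <- settings$schema
    write.csv(truth, outfile("truth.csv"), row.names = FALSE)
  } else {
    scans <- config[["scans"]]
    truth <- config[["truth"]]
    schema <- config[["schema"]] %||% default_region_schema()
  }
  write.csv(scans, outfile("scans.csv"), row.names = FALSE)

  # -- harmonize -----------------------------------------------------
  stage("harmonize", check_scan_table(scans, schema))
  combined <- stage("harmonize", combine_hemispheres(scans, schema))
  hm <- stage("harmonize", fit_covariate_model(
    combined[combined$group == "control" & combined$visit == 0L, ],
    schema))
  adjusted <- stage("harmonize", apply_harmonization(combined, hm))
  rois <- stage("harmonize", select_rois(adjusted, schema,
                                         config[["threshold"]] %||% 0.6))
  write.csv(rois$d_table, outfile("roi_selection.csv"), row.names = FALSE)
  Z <- stage("harmonize", to_zscores(adjusted, hm, rois))
  zt <- data.frame(scan_id = rownames(Z), Z, check.names = FALSE)
  write.csv(zt, outfile("zscores.csv"), row.names = FALSE)

  # -- fit -----------------------------------------------------------
  grid <- event_grid(rois$regions,
                     config[["thresholds"]] %||% c(1, 2, 3),
                     config[["z_max"]] %||% 5)
  fs <- do.call(fit_settings, c(config[["fit"]] %||% list()))
  fs$seed <- seed + 103L
  base_case <- scans$group == "case" & scans$visit == 0L
  Xfit <- Z[base_case, , drop = FALSE]
  cv <- NULL
  C <- config[["n_subtypes"]] %||% 2L
  if (isTRUE(config[["cv"]])) {
    cv <- stage("fit", cross_validate(
      Xfit, grid, C_max = config[["C_max"]] %||% 3L, K = config[["K"]] %||% 10L,
      settings = fs, subjects = scans$subject_id[base_case]))
    cvic_df <- data.frame(C = seq_along(cv$cvic),
                          t(cv$test_loglik), cvic = cv$cvic)
    write.csv(cvic_df, outfile("cvic.csv"), row.names = FALSE)
    C <- cv$selected_C
    log_lines <- c(log_lines, sprintf("cv_selected_C: %d", C))
  }
  model <- stage("fit", fit_subtypes(Xfit, grid, C = C, settings = fs))
  model <- stage("fit", mcmc_sample(model, Xfit, fs))
  write_model(model, outfile("model.json"),
              meta = list(seed = seed, config_hash = hash))

  # -- assign --------------------------------------------------------
  assignments <- stage("assign", assign_cohort(Z[scans$group == "case", ,
                                                 drop = FALSE],
                                               model, meta = scans))
  flat <- as.data.frame(assignments)
  flat$stage_posterior <- vapply(
    flat$stage_posterior, function(p)
      as.character(jsonlite::toJSON(p, digits = NA)), character(1))
  write.csv(flat, outfile("assignments.csv"), row.names = FALSE)

  # -- validate ------------------------------------------------------
  stability <- stage("validate", subtype_stability(assignments))
  progression <- stage("validate", stage_progression(assignments))
  enrichment <- stage("validate", tryCatch(enrichment_test(assignments),
                                           error = function(e) NULL))
  report <- list(
    seed = seed, config_hash = hash,
    n_scans = nrow(scans),
    n_controls = sum(scans$group == "control"),
    n_cases_baseline = sum(base_case),
    n_rois = length(rois$regions),
    n_subtypes = length(model$sequences),
    fractions = model$fractions,
    train_loglik = model$fit$loglik,
    mcmc_acceptance = model$mcmc$acceptance_rate,
    stability = stability$stability,
    n_stable = stability$n_stable,
    n_subtypable_followups = stability$n_followups,
    progression = setNames(as.list(progression$overall$proportion),
                           progression$overall$outcome),
    enrichment_p = if (!is.null(enrichment)) enrichment$p_value else NA,
    cvic = if (!is.null(cv)) as.list(cv$cvic) else NULL
  )
  jsonlite::write_json(report, outfile("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  md <- c(
    "# Pipeline report", "",
    sprintf("- seed %d, config %s", seed, hash),
    sprintf("- %d scans (%d controls, %d baseline cases)",
            report$n_scans, report$n_controls, report$n_cases_baseline),
    sprintf("- %d ROIs selected; %d subtypes; fractions %s",
            report$n_rois, report$n_subtypes,
            paste(signif(model$fractions, 3), collapse = ", ")),
    sprintf("- subtype stability %.1f%% (%d/%d)",
            100 * report$stability, report$n_stable,
            report$n_subtypable_followups),
    sprintf("- stage progression: %s",
            paste(sprintf("%s %.0f%%", names(report$progression),
                          100 * unlist(report$progression)),
                  collapse = ", ")),
    if (!is.null(enrichment))
      sprintf("- pathology enrichment p = %.3g", enrichment$p_value)
  )
  writeLines(md, outfile("report.md"))
  writeLines(log_lines, outfile("run.log"))

  invisible(list(scans = scans, truth = truth, schema = schema,
                 harmonization = hm, adjusted = adjusted, rois = rois,
                 zscores = Z, grid = grid, cv = cv, model = model,
                 assignments = assignments, stability = stability,
                 progression = progression, enrichment = enrichment,
                 out_dir = config[["out_dir"]]))
}
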