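## Pipeline orchestration: synthetic generation or CSV ingestion through
## gait metrics -> timeline -> score summaries -> ICC -> association models
## -> ROC, with CSV outputs mirroring the analysis tables and a JSON run
## manifest with checksums for reproducibility auditing.

load_config <- function(config) {
  if (inherits(config, "ep_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) ep_config_error("config file '%s' not found", config)
    raw <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    if (!is.null(raw$observer_params))
      raw$observer_params <- as.data.frame(raw$observer_params)
    return(do.call(study_config, raw))
  }
  if (is.list(config)) return(do.call(study_config, config))
  ep_config_error("config must be an ep_config, a list, or a yaml/json path")
}

validate_assessments <- function(assessments, scales = builtin_scales()) {
  for (i in seq_len(nrow(assessments))) {
    row <- assessments[i, ]
    sc <- get_scale(as.character(row$scale), scales)
    ok <- tryCatch({ validate_and_total(row, sc); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      ep_validation_error("assessment row %d (horse %s, occasion %s, observer %s): %s",
                          i, row$horse, row$occasion, row$observer,
                          conditionMessage(ok))
  }
  invisible(assessments)
}

fit_models_by_observer <- function(model_rows, k = 10, min_rows = 20) {
  combos <- unique(model_rows[, c("observer", "scale")])
  combos <- combos[order(combos$scale, combos$observer), ]
  fits <- list(); tab <- list()
  for (i in seq_len(nrow(combos))) {
    obs <- combos$observer[i]; sc <- combos$scale[i]
    d <- model_rows[model_rows$observer == obs & model_rows$scale == sc, ]
    if (nrow(d) < min_rows || length(unique(d$horse)) < 2) next
    k_eff <- min(k, length(unique(d$tas_mm)))
    fit <- fit_association_model(d, k = k_eff, min_rows = min_rows)
    key <- paste(obs, sc, sep = "|")
    fits[[key]] <- fit
    tab[[key]] <- data.frame(
      observer = obs, scale = sc, n = fit$n,
      p_association = fit$p_association, p_timing = fit$p_timing,
      r2_adj = fit$r2_adj, edf = fit$edf_smooth, phi = fit$phi,
      sigma2_horse = fit$sigma2_horse, stringsAsFactors = FALSE)
  }
  list(fits = fits, table = do.call(rbind, c(tab, make.row.names = FALSE)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or CSV/TSV
#' ingestion), stride segmentation and asymmetry metrics, TAS and
#' proportional-time normalization, pain-score descriptive summaries,
#' per-scale inter-observer ICC, per observer x scale penalized-spline mixed
#' models, and ROC/AUC of the model predictions against the TAS-defined
#' pain status. Writes `table1_summary.csv`, `icc.csv`, `table2_models.csv`,
#' `auc.csv`, `occasions.csv`, `partial_effects/*.csv` and `manifest.json`
#' to `out_dir`. Any stage error aborts the run, removes partial outputs and
#' reports the failing stage.
#'
#' @param config An `ep_config`, a list of [study_config()] arguments, or a
#'   path to a YAML/JSON file of them.
#' @param out_dir Output directory (created if needed).
#' @param input_dir For `mode = "csv"`: directory containing
#'   `occasions.csv`, `assessments.csv` and trace TSV files.
#' @param mode `"synthetic"` (default) or `"csv"`.
#' @param pain_cutoff_mm TAS cut-off defining pain status (default 10).
#' @param k Spline basis dimension for the association models.
#' @param write_traces In synthetic mode, also write the generated trace
#'   TSV files to `out_dir/traces/`.
#' @return The run manifest (invisibly), as written to `manifest.json`.
#' @export
run_analysis <- function(config = study_config(), out_dir,
                         input_dir = NULL, mode = c("synthetic", "csv"),
                         pain_cutoff_mm = 10, k = 10, write_traces = FALSE) {
  mode <- match.arg(mode)
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  warnings_log <- character(0)
  counts <- list()
  stage_name <- "setup"
  note_output <- function(path) outputs <<- c(outputs, path)
  run_stage <- function(name, expr) {
    stage_name <<- name
    t0 <- Sys.time()
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log,
                         sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    message(sprintf("stage %-12s %6.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  result <- tryCatch({
    acquired <- run_stage("acquire", {
      if (mode == "synthetic") {
        st <- generate_study(cfg, traces = TRUE)
        if (write_traces) {
          tdir <- file.path(out_dir, "traces")
          dir.create(tdir, showWarnings = FALSE)
          for (nm in names(st$traces)) {
            p <- file.path(tdir, paste0(nm, "_t1.tsv"))
            write_trace(st$traces[[nm]], p); note_output(p)
          }
        }
        st
      } else {
        if (is.null(input_dir)) ep_config_error("csv mode requires input_dir")
        occ <- utils::read.csv(file.path(input_dir, "occasions.csv"))
        ass <- utils::read.csv(file.path(input_dir, "assessments.csv"))
        files <- list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE)
        if (!length(files)) ep_config_error("no trace .tsv files in '%s'", input_dir)
        list(occasions = occ, assessments = ass,
             traces = lapply(sort(files), read_trace), config = cfg,
             inputs = sort(files))
      }
    })
    ass <- run_stage("validate", validate_assessments(acquired$assessments))
    counts$assessments <- nrow(ass)
    occ_asym <- run_stage("gait_metrics", occasion_asymmetry(
      acquired$traces,
      acquired$occasions[, c("horse", "occasion", "clock_time_h")]))
    counts$occasions <- nrow(occ_asym)
    occ_norm <- run_stage("timeline",
                          normalize_timeline(occ_asym, pain_cutoff_mm))
    p <- file.path(out_dir, "occasions.csv")
    ep_write_csv(occ_norm, p); note_output(p)

    table1 <- run_stage("summaries", summarize_scores(ass))
    p <- file.path(out_dir, "table1_summary.csv")
    ep_write_csv(table1, p); note_output(p)

    icc <- run_stage("reliability", icc_by_scale(ass))
    p <- file.path(out_dir, "icc.csv")
    ep_write_csv(icc, p); note_output(p)

    model_rows <- merge(ass, occ_norm[, c("horse", "occasion", "tas_mm",
                                          "prop_time_pct", "pain_status")],
                        by = c("horse", "occasion"), sort = FALSE)
    models <- run_stage("models", fit_models_by_observer(model_rows, k = k))
    counts$models <- length(models$fits)
    if (is.null(models$table))
      ep_insufficient_data("no observer x scale cell had enough data to model")
    p <- file.path(out_dir, "table2_models.csv")
    ep_write_csv(models$table, p); note_output(p)
    pe_dir <- file.path(out_dir, "partial_effects")
    dir.create(pe_dir, showWarnings = FALSE)
    for (key in names(models$fits)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      pp <- file.path(pe_dir, sprintf("obs%s_%s.csv", parts[1], parts[2]))
      ep_write_csv(partial_effect_curve(models$fits[[key]]), pp)
      note_output(pp)
    }

    auc_tab <- run_stage("roc", {
      rows <- lapply(names(models$fits), function(key) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        fit <- models$fits[[key]]
        d <- model_rows[model_rows$observer == parts[1] &
                          model_rows$scale == parts[2], ]
        pred <- predict_scores(fit, d, type = "population")
        if (length(unique(d$pain_status)) < 2) return(NULL)
        roc <- auc_ci(compute_roc(pred, d$pain_status), pred, d$pain_status)
        data.frame(observer = parts[1], scale = parts[2], auc = roc$auc,
                   ci_low = roc$ci_low, ci_high = roc$ci_high,
                   label = roc$label, n_obs = nrow(d),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, c(rows, make.row.names = FALSE))
    })
    p <- file.path(out_dir, "auc.csv")
    ep_write_csv(auc_tab, p); note_output(p)

    cfg_snapshot <- unclass(cfg)
    cfg_snapshot$observer_params <- as.list(cfg$observer_params)
    manifest <- list(
      package = "equipain",
      mode = mode,
      seed = cfg$seed,
      config = cfg_snapshot,
      inputs = if (mode == "csv") {
        data.frame(file = basename(acquired$inputs),
                   md5 = unname(tools::md5sum(acquired$inputs)))
      } else list(),
      outputs = data.frame(
        file = ifelse(startsWith(outputs, paste0(out_dir, "/")),
                      substring(outputs, nchar(out_dir) + 2), outputs),
        md5 = unname(tools::md5sum(outputs))),
      row_counts = counts,
      warnings = warnings_log
    )
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest
  }, equipain_error = function(e) {
    unlink(outputs)
    ep_stop(class(e)[1], "pipeline stage '%s' failed: %s", stage_name,
            conditionMessage(e))
  })
  invisible(result)
}

#' Write a small deterministic fixture study
#'
#' Three horses, a baseline plus four post-induction occasions each, three
#' observers per assessment, short trials. Used by the test suite; the file
#' set is byte-stable for a given seed.
#'
#' @param out_dir Output directory.
#' @param seed Root seed (default 42).
#' @return The fixture `ep_config`, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 42L) {
  cfg <- study_config(n_horses = 3,
                      occasions_per_horse_mean = 5,
                      occasions_per_horse_sd = 0,
                      assessments_per_horse_mean = 9,
                      assessments_per_horse_sd = 0,
                      trial_duration = 10,
                      trial_noise_sd = 1,
                      seed = seed)
  generate_study(cfg, out_dir = out_dir, traces = TRUE)
  invisible(cfg)
}
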