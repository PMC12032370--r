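# Lossless CSV writer: numerics at full double precision, NA as empty.
write_table_full <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format_full(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
}

#' Write a study to CSV files
#'
#' Writes `subjects.csv`, `measurements.csv` (long format) and
#' `behavior.csv` with full numeric precision, plus `manifest.json`
#' recording the seed, a hash of the configuration, and table summaries.
#'
#' @param tables A `"study_tables"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_full(tables$subjects, file.path(dir, "subjects.csv"))
  write_table_full(tables$measurements, file.path(dir, "measurements.csv"))
  write_table_full(tables$behavior, file.path(dir, "behavior.csv"))
  cfg <- tables$config
  manifest <- list(
    package = "metabocross",
    version = as.character(utils::packageVersion("metabocross")),
    seed = if (!is.null(cfg)) cfg$seed else NULL,
    config_hash = if (!is.null(cfg))
      fnv1a32(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               force = TRUE)) else NULL,
    n_subjects = nrow(tables$subjects),
    n_measurements = nrow(tables$measurements),
    n_behavior = nrow(tables$behavior))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a study from CSV files
#'
#' Reads and validates the three study tables written by [write_study()]
#' (or prepared externally with the same headers). Validation failures are
#' schema errors naming the offending rows: unknown treatment levels,
#' duplicate (subject, treatment, time, metabolite) keys, negative
#' concentrations, out-of-range behavioural values.
#'
#' @param dir Directory holding `subjects.csv`, `measurements.csv`,
#'   `behavior.csv`.
#' @return A `"study_tables"` object (with `config = NULL`: external studies
#'   carry no generating configuration).
#' @export
read_study <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop_schema("missing file: %s", p)
    p
  }
  subjects <- utils::read.csv(path("subjects.csv"), stringsAsFactors = FALSE)
  measurements <- utils::read.csv(path("measurements.csv"), stringsAsFactors = FALSE)
  behavior <- utils::read.csv(path("behavior.csv"), stringsAsFactors = FALSE)

  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop_schema("%s lacks column(s): %s", file,
                                  paste(miss, collapse = ", "))
  }
  need(subjects, c("subject", "group"), "subjects.csv")
  need(measurements, c("subject", "treatment", "time", "metabolite",
                       "concentration"), "measurements.csv")
  need(behavior, c("subject", "treatment", "time"), "behavior.csv")

  bad_group <- setdiff(unique(subjects$group), c("occasional", "chronic"))
  if (length(bad_group))
    stop_schema("unknown group label '%s' in subjects.csv", bad_group[1])
  unknown_subj <- setdiff(unique(measurements$subject), subjects$subject)
  if (length(unknown_subj))
    stop_schema("measurements reference unknown subject '%s'", unknown_subj[1])
  trt <- unique(measurements$treatment)
  if (length(trt) > 2)
    stop_schema("more than two treatment levels: %s", paste(trt, collapse = ", "))
  key <- paste(measurements$subject, measurements$treatment,
               measurements$time, measurements$metabolite)
  dup <- which(duplicated(key))
  if (length(dup))
    stop_schema("duplicate (subject, treatment, time, metabolite) at row %d (%s)",
                dup[1], key[dup[1]])
  neg <- which(!is.na(measurements$concentration) & measurements$concentration < 0)
  if (length(neg))
    stop_schema("negative concentration at measurements.csv row %d (subject %s, %s)",
                neg[1], measurements$subject[neg[1]], measurements$metabolite[neg[1]])
  measurements$time <- as.numeric(measurements$time)
  measurements$concentration <- as.numeric(measurements$concentration)
  behavior$time <- as.numeric(behavior$time)
  if ("high" %in% names(behavior)) behavior$high <- as.numeric(behavior$high)
  if (is.null(measurements$missing)) measurements$missing <- is.na(measurements$concentration)
  measurements$missing <- as.logical(measurements$missing)
  if ("lapses" %in% names(behavior)) {
    bad <- which(!is.na(behavior$lapses) &
                   (behavior$lapses < 0 | behavior$lapses != round(behavior$lapses)))
    if (length(bad))
      stop_schema("lapses must be non-negative integers (behavior.csv row %d)", bad[1])
    behavior$lapses <- as.integer(behavior$lapses)
  }
  if ("high" %in% names(behavior)) {
    bad <- which(!is.na(behavior$high) & (behavior$high < 0 | behavior$high > 10))
    if (length(bad))
      stop_schema("subjective high outside [0, 10] (behavior.csv row %d)", bad[1])
  }
  message(sprintf("read_study: %d subjects, %d measurements (%d missing), %d behavioural rows",
                  nrow(subjects), nrow(measurements), sum(measurements$missing),
                  nrow(behavior)))
  structure(list(subjects = subjects, measurements = measurements,
                 behavior = behavior, config = NULL),
            class = "study_tables")
}

#' Run the full analysis pipeline into a report directory
#'
#' Orchestrates every stage on one study: simulate (or read), preprocess,
#' classify user groups by rdCV-PLS-DA (optionally with the permutation
#' test), screen per-metabolite kinetics in both user groups, and screen
#' change-score associations -- writing all tabular outputs, a JSON
#' manifest, and a plain-text summary into `out_dir`. All randomness flows
#' from the single `seed` through named per-stage substreams, so identical
#' inputs give identical outputs.
#'
#' @param out_dir Report directory (created if needed).
#' @param config [study_config()] used when simulating.
#' @param input_dir If given, the study is read from CSVs there instead of
#'   simulated.
#' @param seed Manifest seed.
#' @param rdcv [rdcv_config()] for the classification stage.
#' @param run_permutation Run the (expensive) permutation test.
#' @param baseline_mode Passed to the kinetics screen.
#' @param q FDR level used throughout.
#' @param timeseries_metabolites Optional metabolite subset for the kinetics
#'   screen (the full panel can take a few minutes).
#' @return Invisibly, a list with the fitted stage objects.
#' @export
run_full_pipeline <- function(out_dir, config = study_config(),
                              input_dir = NULL, seed = config$seed %||% 1L,
                              rdcv = rdcv_config(),
                              run_permutation = FALSE,
                              baseline_mode = "covariate", q = 0.05,
                              timeseries_metabolites = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c("mc_stage_error", "mc_error"))))
  }

  tables <- stage("study", {
    if (!is.null(input_dir)) read_study(input_dir)
    else {
      config$seed <- substream_seed(seed, "generate")
      generate_study(config)
    }
  })
  write_study(tables, file.path(out_dir, "study"))

  am <- stage("preprocess", preprocess_study(tables, samples = "baseline"))
  write_table_full(data.frame(am$sample_keys, group = am$groups, am$values,
                              check.names = FALSE),
                   file.path(out_dir, "analysis_matrix.csv"))
  jsonlite::write_json(
    list(steps = am$transform_record$steps,
         center = as.list(am$transform_record$center),
         scale = as.list(am$transform_record$scale),
         dropped = am$transform_record$dropped_features,
         impute = am$transform_record$impute),
    file.path(out_dir, "transform_record.json"), auto_unbox = TRUE, digits = NA)

  rdcv$seed <- substream_seed(seed, "rdcv")
  fit <- stage("classify", rdcv_plsda(am, config = rdcv))
  if (run_permutation) {
    perm <- stage("permutation",
                  permutation_test(am, config = rdcv,
                                   observed_rate = fit$classification_rate))
    fit$permutation_p <- perm$p
  }
  utils::write.table(fit$consensus_ranking,
                     file.path(out_dir, "consensus_ranking.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  mis <- misclassification_plot_data(fit)
  utils::write.table(mis, file.path(out_dir, "misclassification_plot.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(classification_rate = fit$classification_rate,
         rate_ci = fit$rate_ci, permutation_p = fit$permutation_p,
         ci_method = "percentile interval of per-repetition rates",
         consensus_panel = fit$consensus_panel,
         per_repetition_rates = fit$per_repetition_rates,
         chosen_sizes = fit$chosen_sizes),
    file.path(out_dir, "rdcv_result.json"), digits = NA, auto_unbox = TRUE,
    na = "null")

  screens <- list()
  for (g in c("occasional", "chronic")) {
    screens[[g]] <- stage(paste0("timeseries_", g),
                          run_timeseries_screen(tables, g, baseline_mode, q = q,
                                                metabolites = timeseries_metabolites))
    utils::write.table(screens[[g]],
                       file.path(out_dir, sprintf("timeseries_%s.tsv", g)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  deltas <- stage("deltas", compute_deltas(tables))
  assoc <- stage("associate", run_delta_screen(deltas, tables, q = q))
  utils::write.table(assoc, file.path(out_dir, "delta_associations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "metabocross",
    version = as.character(utils::packageVersion("metabocross")),
    seed = seed,
    substreams = list(generate = substream_seed(seed, "generate"),
                      rdcv = substream_seed(seed, "rdcv"),
                      permutation = substream_seed(substream_seed(seed, "rdcv"),
                                                   "permutation")),
    config_hash = fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                           digits = NA, force = TRUE)),
    q = q, baseline_mode = baseline_mode,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  n_kin <- vapply(screens, function(s)
    sum(s$p_adj_treatment < q, na.rm = TRUE), numeric(1))
  n_assoc <- sum(assoc$p_adj < q, na.rm = TRUE)
  summary_lines <- c(
    "metabocross pipeline report",
    sprintf("seed: %d", seed),
    sprintf("classification rate: %.3f (95%% CI %.3f to %.3f)",
            fit$classification_rate, fit$rate_ci[1], fit$rate_ci[2]),
    sprintf("permutation p: %s",
            if (is.na(fit$permutation_p)) "not run" else format(fit$permutation_p)),
    sprintf("consensus panel (%d): %s", fit$consensus_panel_size,
            paste(fit$consensus_panel, collapse = ", ")),
    sprintf("kinetics discoveries at q = %g: occasional %d, chronic %d",
            q, n_kin[["occasional"]], n_kin[["chronic"]]),
    sprintf("change-score association discoveries at q = %g: %d", q, n_assoc))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(tables = tables, analysis_matrix = am, rdcv = fit,
                 timeseries = screens, deltas = deltas, associations = assoc,
                 manifest = manifest))
}
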