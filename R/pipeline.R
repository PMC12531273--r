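# End-to-end pipeline: simulate -> flag text -> per-database metrics ->
# overlap analysis -> recursive inference -> classifier -> fairness audit.
# Every artifact lands in one run directory stamped with the seed and a
# hash of the configuration that produced it.

#' Pipeline configuration
#'
#' Defaults describe the full study-scale conditions; tests and demos pass
#' smaller `n_patients`/`gold_n`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; stage seeds are derived from it.
#' @param population a [population_config()] (its seed is overridden by
#'   `seed`).
#' @param profiles database profiles for the structured databases
#'   ([default_database_profiles()] minus the free-text ones, which are
#'   flagged from generated documents).
#' @param gold_n,min_databases,split_fraction,gold_prevalence gold-standard
#'   sampling settings (see [sample_gold_standard()]).
#' @param classifier a [model_config()].
#' @param thresholds threshold sweep grid.
#' @param n_boot bootstrap replicates for metrics and sweeps.
#' @param replay_table optional path to a published inference summary CSV;
#'   when set, an additional `summary_replay` inference report is produced.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            population = population_config(seed = seed),
                            profiles = default_database_profiles(),
                            gold_n = 2800, min_databases = 2,
                            split_fraction = 0.3, gold_prevalence = 0.75,
                            classifier = model_config(seed = seed),
                            thresholds = c(0.25, 0.31, 0.38, 0.44, 0.5,
                                           0.56, 0.62, 0.69, 0.75),
                            n_boot = 1000,
                            replay_table = NULL) {
  population$seed <- as.integer(seed)
  classifier$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 population = population, profiles = profiles,
                 gold_n = gold_n, min_databases = min_databases,
                 split_fraction = split_fraction,
                 gold_prevalence = gold_prevalence,
                 classifier = classifier, thresholds = thresholds,
                 n_boot = n_boot, replay_table = replay_table),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] plus nested `population` and
#' `classifier` blocks whose keys are passed to [population_config()] and
#' [model_config()].
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  pop <- do.call(population_config, y$population %||% list())
  cls <- do.call(model_config, y$classifier %||% list())
  args <- y[setdiff(names(y), c("population", "classifier"))]
  args$population <- pop
  args$classifier <- cls
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

free_text_dbs <- c(letter = "Clinical Letters",
                   endoscopy = "Endoscopy Records",
                   histopathology = "Histopathology Records")

write_stamped_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_hash=%s", seed, hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate, flag-text, metrics, overlap, infer-size, fit-model and
#' audit in order, writing each stage's artifacts into `config$out_dir`.
#' Deterministic for a fixed configuration; a stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  seed <- config$seed
  stamp <- function(df, name) {
    write_stamped_csv(df, file.path(config$out_dir, name), seed, hash)
  }
  stamp_json <- function(x, name) {
    x$seed <- seed; x$config_hash <- hash
    jsonlite::write_json(x, file.path(config$out_dir, name),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  res <- list(out_dir = config$out_dir)

  stage("simulate", {
    res$population <- generate_population(config$population)
    structured <- config$profiles[setdiff(names(config$profiles), free_text_dbs)]
    res$membership <- generate_membership(res$population, structured, seed = seed + 1)
    res$documents <- generate_documents(res$population, seed = seed + 2)
    stamp(res$population, "population.csv")
    write_documents_jsonl(res$documents, file.path(config$out_dir, "documents.jsonl"))
  })

  stage("flag_text", {
    for (dt in names(free_text_dbs)) {
      fl <- flag_patients(res$documents, dt, patient_ids = res$population$patient_id)
      res$membership[[free_text_dbs[[dt]]]] <- fl$flag
    }
    stamp(res$membership, "membership.csv")
  })

  stage("gold_standard", {
    res$gold <- sample_gold_standard(res$membership, res$population,
                                     n = config$gold_n,
                                     min_databases = config$min_databases,
                                     split_fraction = config$split_fraction,
                                     target_prevalence = config$gold_prevalence,
                                     seed = seed + 3)
    stamp(res$gold, "gold_standard.csv")
  })

  stage("metrics", {
    res$metrics <- database_metrics(res$membership, res$gold,
                                    n_reps = config$n_boot, seed = seed + 4)
    stamp(res$metrics, "database_metrics.csv")
  })

  stage("overlap", {
    jm <- jaccard_matrix(res$membership, subset = "flagged_only")
    res$jaccard <- jm
    stamp(as.data.frame(as.table(unclass(jm)),
                        responseName = "jaccard"), "jaccard_pairs.csv")
    cs <- cardinality_summary(res$membership)
    res$cardinality <- cs
    stamp(cs$degree, "degree_distribution.csv")
  })

  stage("infer_size", {
    precisions <- setNames(res$metrics$precision, res$metrics$database)
    res$trace <- run_inference(res$membership, precisions,
                               primary = "ICD10 Codes", mode = "set_based")
    stamp(res$trace$steps, "inference_trace.csv")
    if (!is.null(config$replay_table)) {
      tab <- read.csv(config$replay_table, stringsAsFactors = FALSE)
      res$replay <- run_inference(tab, primary = tab$database[1],
                                  mode = "summary_replay")
      stamp(res$replay$steps, "inference_replay.csv")
    }
  })

  stage("fit_model", {
    feats <- res$membership[match(res$gold$patient_id, res$membership$patient_id), ]
    cv <- nested_cv(feats, res$gold$label, config$classifier)
    res$model <- cv
    ok <- !is.na(cv$oof_scores)
    cal <- platt_calibrate(cv$oof_scores[ok], res$gold$label[ok])
    res$calibrator <- cal
    val <- res$gold$split == "validation"
    p_val <- predict(cv, feats[val, ], calibrator = cal)
    p_pop <- predict(cv, res$membership, calibrator = cal)
    res$population_probabilities <- p_pop
    res$sweep <- threshold_sweep(p_val, res$gold$label[val], p_pop,
                                 thresholds = config$thresholds,
                                 n_boot = config$n_boot, seed = seed + 5)
    res$threshold <- select_threshold(p_val, res$gold$label[val], "max_f1")
    res$calibration <- calibration_report(p_val, res$gold$label[val])
    stamp(cv$report, "model_coefficients.csv")
    stamp(res$sweep, "threshold_sweep.csv")
    stamp(res$calibration$binned, "calibration_curve.csv")

    prec_at <- suppressWarnings(classification_metrics(confusion_counts(
      as.integer(p_val >= res$threshold), res$gold$label[val])))[["precision"]]
    model_tp <- as.integer(round_half_away(sum(p_pop >= res$threshold) * prec_at))
    steps <- res$trace$steps
    letters_inc <- steps$incremental_tp[steps$database == free_text_dbs[["letter"]]]
    baseline <- if (nrow(steps) >= 2) steps$cumulative_tp[2] else steps$cumulative_tp[1]
    combined <- combine_estimates(model_tp,
                                  setNames(letters_inc, free_text_dbs[["letter"]]))
    missed <- if (combined$total >= baseline) {
      missed_fraction(baseline, combined$total)
    } else NA_real_
    res$estimates <- list(
      baseline_estimate = baseline,
      jaccard_estimate = res$trace$cumulative_tp,
      jaccard_union_upper_bound = res$trace$combined_size,
      model_threshold = res$threshold,
      model_confident_tp = model_tp,
      letters_unaccounted_tp = letters_inc,
      combined_estimate = combined$total,
      missed_fraction_pct = missed,
      outer_auroc_mean = cv$auc_mean,
      brier_validation = brier_score(p_val, res$gold$label[val]))
    stamp_json(res$estimates, "estimate_report.json")
  })

  stage("audit", {
    val <- res$gold$split == "validation"
    demo <- res$population[match(res$gold$patient_id[val],
                                 res$population$patient_id), ]
    p_val <- predict(res$model, res$membership[match(res$gold$patient_id[val],
                                                     res$membership$patient_id), ],
                     calibrator = res$calibrator)
    groups <- data.frame(sex = demo$sex, ethnicity = demo$ethnicity,
                         age_band = age_band(demo$age),
                         imd_band = imd_band(demo$imd_decile))
    res$fairness <- stratified_auc(p_val, res$gold$label[val], groups)
    stamp(res$fairness$groups, "fairness_groups.csv")
    stamp_json(list(gaps = res$fairness$gaps,
                    pooled_auc = res$fairness$pooled_auc), "fairness_summary.json")
  })

  invisible(res)
}
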