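#' Default run configuration
#'
#' The configuration tree for [run_pipeline()], materialized with every
#' default: the full stated experiment (25 subjects, 10 + 10 questions,
#' 30 s at 500 Hz, empirical answer rates, 2% dropout), zero class effects,
#' standard artifact levels, the documented preprocessing and selection
#' parameters, both tasks, both selectors, all four classifier families and
#' the two frontal channel subsets. Override any leaf via a partial config
#' list or JSON file passed to [validate_config()].
#'
#' @return nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    duration_s = 30,
    fs = 500,
    write_recordings = FALSE,
    write_features = TRUE,
    design = list(n_subjects = 25L, n_insider = 10L, n_conflict = 10L,
                  yes_prob_insider = 96 / 242, yes_prob_conflict = 150 / 248,
                  dropout_prob = 10 / 500),
    effects = list(intent_effect = 0, scenario_effect = 0,
                   subject_variability = 0.1),
    artifacts = list(line_amp = 5, line_freq = 50, drift_amp = 20,
                     blink_rate = 0.1, blink_amp = 100, dead_prob = 0),
    preprocess = list(target_fs = 250, hp_freq = 1, hp_order = 4,
                      line_freq = 50, notch_bw = 1, flat_var = 1e-10,
                      corr_min = 0.4, max_bad_frac = 0.5),
    epoch = list(window = 2, step = 1, min_len = 1),
    selection = list(max_iter = 100L, alpha = 0.01, ntree_boruta = 100L,
                     importance = "perm_z", drop_frac = 0.2,
                     ntree_initial = 500L, ntree_iter = 200L),
    evaluate = list(tasks = c("intent", "scenario_type"),
                    selectors = c("boruta", "varselrf"),
                    classifiers = c("knn", "svm_rbf", "gnb", "mlp"),
                    channel_subsets = list(
                      frontopolar = c("FP1", "FPz", "FP2"),
                      midfrontal = c("F3", "Fz", "F4")))),
    class = "run_config")
}

# recursive merge of user values over defaults; unknown keys collected.
# `channel_subsets` is a value (arbitrary named list), not a schema section.
merge_config <- function(default, user, path = "", errors) {
  leaf_lists <- "channel_subsets"
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(default)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown key '%s'", key))
      next
    }
    if (nm %in% leaf_lists) {
      default[[nm]] <- user[[nm]]
      next
    }
    if (is.list(default[[nm]]) && !is.null(names(default[[nm]]))) {
      if (!is.list(user[[nm]])) {
        errors$msgs <- c(errors$msgs, sprintf("'%s' must be a section", key))
      } else {
        default[[nm]] <- merge_config(default[[nm]], user[[nm]], key, errors)
      }
    } else {
      default[[nm]] <- user[[nm]]
    }
  }
  default
}

#' Validate a run configuration
#'
#' Accepts a JSON file path or a (partial) configuration list, merges it
#' over [default_config()], rejects unknown keys and reports all range
#' violations at once.
#'
#' @param config path to a JSON config file, or a list.
#' @return a complete validated `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found",
                                           config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (inherits(config, "run_config")) return(config)
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- merge_config(unclass(default_config()), config, "", errors)

  chk <- function(ok, msg) if (!isTRUE(ok)) errors$msgs <<- c(errors$msgs, msg)
  chk(cfg$design$n_subjects >= 0, "design.n_subjects must be >= 0")
  chk(cfg$design$n_insider >= 0, "design.n_insider must be >= 0")
  chk(cfg$design$n_conflict >= 0, "design.n_conflict must be >= 0")
  for (p in c("yes_prob_insider", "yes_prob_conflict", "dropout_prob"))
    chk(cfg$design[[p]] >= 0 && cfg$design[[p]] <= 1,
        sprintf("design.%s must lie in [0, 1]", p))
  chk(cfg$effects$intent_effect >= 0, "effects.intent_effect must be >= 0")
  chk(cfg$effects$scenario_effect >= 0,
      "effects.scenario_effect must be >= 0")
  chk(cfg$duration_s > 0, "duration_s must be > 0")
  chk(cfg$fs >= cfg$preprocess$target_fs,
      "fs must be >= preprocess.target_fs")
  chk(cfg$selection$drop_frac > 0 && cfg$selection$drop_frac < 1,
      "selection.drop_frac must lie in (0, 1): legal range (0, 1)")
  chk(cfg$selection$alpha > 0 && cfg$selection$alpha < 0.5,
      "selection.alpha must lie in (0, 0.5)")
  chk(all(cfg$evaluate$tasks %in% c("intent", "scenario_type")),
      "evaluate.tasks must be a subset of {intent, scenario_type}")
  chk(all(cfg$evaluate$selectors %in% c("boruta", "varselrf", "none")),
      "evaluate.selectors must be a subset of {boruta, varselrf, none}")
  chk(all(cfg$evaluate$classifiers %in% c("knn", "svm_rbf", "gnb", "mlp")),
      "evaluate.classifiers must be a subset of {knn, svm_rbf, gnb, mlp}")
  if (length(errors$msgs) > 0)
    stop(paste(c("invalid configuration:",
                 paste0("  - ", errors$msgs)), collapse = "\n"),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

# fixed-format CSV writer so reruns at one seed are byte-identical
write_csv_stable <- function(df, path) {
  df <- as.data.frame(df)
  for (cl in names(df))
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.10g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline: simulate, preprocess, extract, select, evaluate
#'
#' Executes every stage on a validated configuration and writes all report
#' artifacts under `out_dir`: the design table, optional recordings and
#' per-subject feature CSVs, per-task accuracy summaries (rows = selector,
#' columns = classifier), per-question predictions, pooled ROC points, the
#' channel-subset summaries, preprocessing logs and a JSON manifest
#' sufficient to reproduce the run bit-for-bit at the same seed. Stage
#' failures abort with the stage name and the offending subject/question.
#'
#' @param config a `run_config`, partial list or JSON path (validated).
#' @param out_dir output directory (created).
#' @param seed optional override of `config$seed`.
#' @return (invisibly) list with the written `out_dir`, per-task experiment
#'   results, and the feature tables.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("eegrun"),
                         seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed at %s: %s", name, id,
                   conditionMessage(e)), call. = FALSE))
  }

  design <- stage("design", "make_design",
                  make_design(cfg$design$n_subjects, cfg$design$n_insider,
                              cfg$design$n_conflict,
                              c(insider = cfg$design$yes_prob_insider,
                                conflict = cfg$design$yes_prob_conflict),
                              cfg$design$dropout_prob, cfg$seed))
  write_csv_stable(design, file.path(out_dir, "design.csv"))

  effects <- effect_spec(cfg$effects$intent_effect,
                         cfg$effects$scenario_effect,
                         cfg$effects$subject_variability,
                         do.call(artifact_config, cfg$artifacts))
  pp <- do.call(preprocess_params, cfg$preprocess)

  subjects <- unique(design$subject[design$answered])
  tables <- list()
  pp_logs <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    sub_design <- design[design$subject == sub & design$answered, ]
    base <- subject_baseline(effects, derive_seed(cfg$seed, si, 0))
    epochs <- list()
    for (qi in seq_len(nrow(sub_design))) {
      trial <- sub_design[qi, ]
      rec <- stage("synthesize", trial$question,
                   synthesize_question_recording(
                     trial, effects, base,
                     seed = derive_seed(cfg$seed, si, qi),
                     duration = cfg$duration_s, fs = cfg$fs))
      rec <- stage("artifacts", trial$question,
                   inject_artifacts(rec, effects$artifacts,
                                    seed = derive_seed(cfg$seed, si, qi,
                                                       7L)))
      if (isTRUE(cfg$write_recordings)) {
        dir.create(file.path(out_dir, "recordings"), showWarnings = FALSE)
        write_recording(rec, file.path(out_dir, "recordings",
                                       trial$question))
      }
      clean <- stage("preprocess", trial$question,
                     preprocess_recording(rec, pp))
      pp_logs[[trial$question]] <- clean$log
      epochs <- c(epochs,
                  stage("epoch", trial$question,
                        epoch_question(clean, cfg$epoch$window,
                                       cfg$epoch$step, cfg$epoch$min_len,
                                       pp$reject_epochs_uV)))
    }
    tables[[sub]] <- stage("features", sub, extract_feature_table(epochs))
    if (isTRUE(cfg$write_features)) {
      dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
      write_feature_table(tables[[sub]],
                          file.path(out_dir, "features",
                                    paste0(sub, ".csv")))
    }
  }
  jsonlite::write_json(pp_logs, file.path(out_dir, "preprocess_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  sel_cfg <- do.call(selection_config, cfg$selection)
  task_results <- list()
  for (task in cfg$evaluate$tasks) {
    res <- stage("evaluate", task,
                 run_experiment(tables, task,
                                selectors = cfg$evaluate$selectors,
                                families = cfg$evaluate$classifiers,
                                seed = derive_seed(cfg$seed,
                                                   match(task,
                                                         cfg$evaluate$tasks),
                                                   1000L),
                                sel_config = sel_cfg))
    task_results[[task]] <- res
    wide <- tidyr::pivot_wider(res$summary[c("selector", "classifier",
                                             "mean_accuracy")],
                               names_from = "classifier",
                               values_from = "mean_accuracy")
    write_csv_stable(wide, file.path(out_dir,
                                     sprintf("summary_%s.csv", task)))
    write_csv_stable(res$predictions,
                     file.path(out_dir, sprintf("predictions_%s.csv", task)))

    td <- task_def(task)
    roc_rows <- list()
    cells <- unique(res$predictions[c("selector", "classifier")])
    for (ci in seq_len(nrow(cells))) {
      sub_pred <- dplyr::filter(res$predictions,
                                .data$selector == cells$selector[ci],
                                .data$classifier == cells$classifier[ci])
      if (length(unique(sub_pred$truth)) < 2) next
      roc <- roc_points(sub_pred$score, sub_pred$truth, td$positive)
      roc_rows[[ci]] <- dplyr::mutate(roc$points,
                                      selector = cells$selector[ci],
                                      classifier = cells$classifier[ci],
                                      auc = roc$auc)
    }
    if (length(roc_rows) > 0)
      write_csv_stable(dplyr::bind_rows(roc_rows),
                       file.path(out_dir, sprintf("roc_%s.csv", task)))

    for (sub_nm in names(cfg$evaluate$channel_subsets)) {
      cs <- stage("channel_subset", sub_nm,
                  channel_subset_run(tables,
                                     cfg$evaluate$channel_subsets[[sub_nm]],
                                     task,
                                     selectors = cfg$evaluate$selectors,
                                     families = cfg$evaluate$classifiers,
                                     seed = derive_seed(cfg$seed,
                                                        match(task,
                                                              cfg$evaluate$tasks),
                                                        2000L),
                                     sel_config = sel_cfg))
      wide <- tidyr::pivot_wider(cs$summary[c("selector", "classifier",
                                              "mean_accuracy")],
                                 names_from = "classifier",
                                 values_from = "mean_accuracy")
      write_csv_stable(wide,
                       file.path(out_dir, sprintf("summary_%s_%s.csv",
                                                  task, sub_nm)))
      task_results[[paste(task, sub_nm, sep = "_")]] <- cs
    }
  }

  jsonlite::write_json(
    list(config = unclass(cfg), package_version =
           as.character(utils::packageVersion("eegintent"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out_dir = out_dir, results = task_results,
                 tables = tables, design = design))
}
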