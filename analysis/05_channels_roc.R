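#!/usr/bin/env Rscript
# Two follow-up analyses: (1) frontal channel subsets — the frontopolar row
# (FP1/FPz/FP2) and the mid-frontal row (F3/Fz/F4) — re-evaluated with the
# identical pipeline on their 3 x 65 feature columns; (2) pooled ROC curves
# from the question-level positive-epoch-fraction scores.

suppressPackageStartupMessages(library(eegintent))

seed <- 2026
subjects <- sub("\\.csv$", "",
                list.files("scratch/features", pattern = "\\.csv$"))
tables <- lapply(subjects, function(s)
  read_feature_table(file.path("scratch/features", paste0(s, ".csv"))))
names(tables) <- subjects
sel_cfg <- selection_config(max_iter = 40)

subsets <- list(frontopolar = c("FP1", "FPz", "FP2"),
                midfrontal = c("F3", "Fz", "F4"))
for (task in c("intent", "scenario_type")) {
  for (nm in names(subsets)) {
    cs <- suppressWarnings(
      channel_subset_run(tables, subsets[[nm]], task,
                         selectors = "varselrf",
                         families = c("knn", "svm_rbf", "gnb", "mlp"),
                         seed = seed, sel_config = sel_cfg))
    wide <- tidyr::pivot_wider(cs$summary[c("selector", "classifier",
                                            "mean_accuracy")],
                               names_from = "classifier",
                               values_from = "mean_accuracy")
    write.csv(wide, sprintf("results/summary_%s_%s.csv", task, nm),
              row.names = FALSE)
    cat(sprintf("%s / %s: mean accuracy %.1f%%\n", task, nm,
                mean(cs$summary$mean_accuracy)))
  }

  # pooled ROC per classifier with the varSelRF selector
  ex <- suppressWarnings(
    run_experiment(tables, task, selectors = "varselrf",
                   families = c("knn", "svm_rbf", "gnb", "mlp"),
                   seed = seed, sel_config = sel_cfg))
  positive <- if (task == "intent") "yes" else "insider"
  roc_rows <- list()
  for (fam in unique(ex$predictions$classifier)) {
    pq <- ex$predictions[ex$predictions$classifier == fam, ]
    if (length(unique(pq$truth)) < 2) next
    roc <- roc_points(pq$score, pq$truth, positive)
    roc_rows[[fam]] <- dplyr::mutate(roc$points, classifier = fam,
                                     auc = roc$auc)
    cat(sprintf("%s / %s: AUC %.3f\n", task, fam, roc$auc))
  }
  write.csv(dplyr::bind_rows(roc_rows),
            sprintf("results/roc_%s.csv", task), row.names = FALSE)
}
cat("channel-subset tables and ROC points -> results/\n")
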