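#!/usr/bin/env Rscript
# Extract the 65-feature-per-channel catalogue (time, wavelet, spectral,
# nonlinear) from every epoch of every cleaned recording: one feature table
# per subject, 21 x 65 = 1365 columns plus metadata. Tables are bulky and
# go to scratch/; a compact per-subject overview goes to results/.

suppressPackageStartupMessages(library(eegintent))

dir.create("scratch/features", showWarnings = FALSE)
files <- list.files("scratch/clean", pattern = "\\.json$")
qids <- sub("\\.json$", "", files)
recs <- lapply(qids, function(q) read_recording(file.path("scratch/clean",
                                                          q)))
subjects <- sort(unique(vapply(recs, function(r) r$subject, "")))

overview <- list()
for (s in subjects) {
  eps <- list()
  for (r in recs[vapply(recs, function(r) r$subject, "") == s])
    eps <- c(eps, epoch_question(r))
  tbl <- extract_feature_table(eps)
  write_feature_table(tbl, file.path("scratch/features",
                                     paste0(s, ".csv")))
  deg <- attr(tbl, "degeneracies")
  overview[[s]] <- data.frame(subject = s, n_epochs = nrow(tbl),
                              n_features = length(feature_columns(tbl)),
                              n_degenerate = nrow(deg))
}
ov <- do.call(rbind, overview)
write.csv(ov, "results/feature_overview.csv", row.names = FALSE)
print(ov, row.names = FALSE)
cat("feature tables -> scratch/features/; overview -> results/\n")
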