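#!/usr/bin/env Rscript
# Clean every simulated recording (resample to 250 Hz, 1 Hz zero-phase
# high-pass, 50/100 Hz notch, bad-channel interpolation, average
# re-reference) and cut 2 s / 1 s epochs. Cleaned recordings go to scratch/
# (bulky); a per-question preprocessing summary goes to results/.

suppressPackageStartupMessages(library(eegintent))

dir.create("scratch/clean", showWarnings = FALSE)
files <- list.files("scratch/recordings", pattern = "\\.json$")
qids <- sub("\\.json$", "", files)

rows <- list()
for (q in qids) {
  rec <- read_recording(file.path("scratch/recordings", q))
  clean <- preprocess_recording(rec)
  write_recording(clean, file.path("scratch/clean", q))
  eps <- epoch_question(clean)
  rows[[q]] <- data.frame(question = q, subject = clean$subject,
                          fs = clean$fs,
                          n_interpolated = length(clean$interpolated),
                          n_epochs = length(eps))
}
log <- do.call(rbind, rows)
write.csv(log, "results/preprocess_summary.csv", row.names = FALSE)
cat(sprintf("cleaned %d questions; %d epochs total; %d channel interpolations\n",
            nrow(log), sum(log$n_epochs), sum(log$n_interpolated)))
cat("per-question log -> results/preprocess_summary.csv\n")
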