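#!/usr/bin/env Rscript
# Simulate the study cohort at desk scale: 3 subjects x (10 insider + 10
# everyday-conflict) questions, 15 s of 21-channel EEG per question at
# 500 Hz, with planted class effects (beta-up/alpha-down for affirmative
# intent, plus a scenario-type shift) and standard artifacts. Writes the
# design table to results/ and the raw recordings to scratch/ (bulky).

suppressPackageStartupMessages(library(eegintent))

seed <- 2026
n_subjects <- 3
duration <- 15

dir.create("results", showWarnings = FALSE)
dir.create("scratch/recordings", recursive = TRUE, showWarnings = FALSE)

design <- make_design(n_subjects, 10, 10, dropout_prob = 10 / 500,
                      seed = seed)
write.csv(design, "results/design.csv", row.names = FALSE)

effects <- effect_spec(intent_effect = 1, scenario_effect = 1,
                       subject_variability = 0.1)
recs <- simulate_recordings(design, effects, seed = seed,
                            duration = duration)
for (q in names(recs))
  write_recording(recs[[q]], file.path("scratch/recordings", q))

answered <- design[design$answered, ]
cat(sprintf("simulated %d/%d questions for %d subjects (%d insider yes)\n",
            nrow(answered), nrow(design), n_subjects,
            sum(answered$scenario_type == "insider" &
                  answered$answer == "yes")))
cat("design -> results/design.csv; recordings -> scratch/recordings/\n")
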