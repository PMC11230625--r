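#!/usr/bin/env Rscript
# EEG event chain on synthetic data: generate an SWD-laden trace with known
# seizure times and a stimulation schedule, then run the automated pipeline
# (filtering, SWD detection with the merging/duration rules, 8-way
# stimulation-block classification) and score it against the ground truth.

library(gaersim)

dir.create("results", showWarnings = FALSE)
set.seed(1)

seizures <- data.frame(start = c(60, 150, 260, 380, 460),
                       end = c(72, 156, 273, 388, 465))
ee <- make_eeg(duration = 520, seizure_schedule = seizures, seed = 7)
sched <- make_stim_schedule(520, seizures, seed = 8)

filtered <- preprocess_eeg(ee$trace)
detected <- detect_swd(filtered)
message(sprintf("detected %d/%d seizure intervals", nrow(detected),
                nrow(seizures)))
boundary_err <- c(abs(detected$start - seizures$start),
                  abs(detected$end - seizures$end))
message(sprintf("max boundary error %.2f s", max(boundary_err)))
write_intervals(detected, "results/detected_seizures.tsv")

blocks <- classify_stimulations(sched$blocks, detected)
tab <- table(intended = blocks$intended_state, label = blocks$label)
print(tab[, colSums(tab) > 0, drop = FALSE])
write_events(data.frame(onset = blocks$onset, duration = blocks$duration,
                        trial_type = as.character(blocks$label)),
             "results/classified_stimulations.tsv")

agree <- mean((blocks$intended_state == "interictal") ==
                (blocks$label == "baseline"))
message(sprintf("intended-state vs classified agreement: %.0f%%", 100 * agree))
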