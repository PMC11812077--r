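#!/usr/bin/env Rscript
# Stage 2: apply the standard data edits and carve out the calibration /
# validation split (one randomly chosen BCS record per cow is kept for
# fitting; all her other BCS records are held out as prediction targets).

library(bcsrr)

seed <- 1L
din <- "results/data"
records <- read_records(file.path(din, "records.csv"))

fr <- apply_edits(records)
print(fr$report)
write_records(fr$records, file.path(din, "filtered.csv"))
write.csv(fr$report, file.path(din, "attrition.csv"), row.names = FALSE)

sp <- split_calibration_validation(fr$records, seed = seed + 1L)
write_records(sp$calibration, file.path(din, "calibration.csv"))
write.csv(sp$validation, file.path(din, "validation_targets.csv"),
          row.names = FALSE, quote = FALSE, na = "")

cat(sprintf("calibration: %d records (%d with BCS, one per cow)\n",
            nrow(sp$calibration), sum(!is.na(sp$calibration$bcs))))
cat(sprintf("validation: %d held-out BCS records on %d cows\n",
            nrow(sp$validation), length(unique(sp$validation$animal_id))))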