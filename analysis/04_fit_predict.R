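#!/usr/bin/env Rscript
# Stage 4: solve the mixed-model equations on the calibration data and
# predict BCS at every held-out herd-test date, combining the model part
# with the milk-residual imputation, then rounding to the 9-point scale.

library(bcsrr)

din <- "results/data"
out <- "results/predictions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

calibration <- read_records(file.path(din, "calibration.csv"))
targets <- read.csv(file.path(din, "validation_targets.csv"),
                    colClasses = c(animal_id = "character",
                                   herd_id = "character"))
for (dc in c("test_date", "calving_date", "birth_date")) {
  targets[[dc]] <- as.Date(targets[[dc]])
}
ped <- sort_pedigree(read_pedigree(file.path(din, "pedigree.csv")))
truth <- readRDS(file.path(din, "truth.rds"))

coding <- build_coding(calibration)
sys <- assemble_mme(calibration, coding, legendre_basis(),
                    truth$components, build_A_inverse(ped))
sol <- solve_mme(sys)
print(sol)

pb <- predict_bcs(sol, targets)
write.csv(pb, file.path(out, "predictions.csv"), row.names = FALSE,
          quote = FALSE, na = "")
cat(sprintf("predicted %d held-out BCS records; ", nrow(pb)))
cat(sprintf("mean continuous prediction %.2f (observed mean %.2f)\n",
            mean(pb$y_hat_continuous), mean(pb$obs_bcs)))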