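#!/usr/bin/env Rscript
# Stage 1: generate the synthetic herd-structured test-day dataset.
#
# The generator runs the random-regression test-day model forward at the
# default desk scale (30 herds of 15-25 first-parity cows, monthly visits,
# BCS scored on ~39% of visits) with the documented truth components, and
# keeps the full simulation truth for later comparison.

library(bcsrr)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
s <- simulate_records(cfg)

write_records(s$records, file.path(out, "records.csv"))
write.csv(data.frame(animal_id = s$pedigree$id,
                     sire_id = ifelse(is.na(s$pedigree$sire), "0",
                                      s$pedigree$id[s$pedigree$sire]),
                     dam_id = ifelse(is.na(s$pedigree$dam), "0",
                                     s$pedigree$id[s$pedigree$dam])),
          file.path(out, "pedigree.csv"), row.names = FALSE, quote = FALSE)
saveRDS(s$truth, file.path(out, "truth.rds")) # scratch artifact, not shipped

dp <- daily_parameters(s$truth$components)
write.csv(data.frame(trait = c("MY", "FP", "PP", "BCS"),
                     mean_daily_h2 = round(dp$h2_mean, 4),
                     sd_daily_h2 = round(dp$h2_sd, 4)),
          file.path(out, "truth_daily_h2.csv"), row.names = FALSE)

cat(sprintf("simulated %d test-day records on %d cows in %d herds\n",
            nrow(s$records), length(unique(s$records$animal_id)),
            length(unique(s$records$herd_id))))
cat(sprintf("BCS present on %.1f%% of records\n",
            100 * mean(!is.na(s$records$bcs))))
cat("truth mean daily h2:",
    paste(sprintf("%s %.3f", c("MY", "FP", "PP", "BCS"), dp$h2_mean),
          collapse = ", "), "\n")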