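#!/usr/bin/env Rscript
# Stage 5: evaluate the predictions against the held-out BCS records: PE,
# APE, RMSE, Pearson correlation, the 9x9 confusion matrix, Cohen's kappa
# under all three weightings, agreement bands and per-DIM curves.

library(bcsrr)

out <- "results/validation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pb <- read.csv("results/predictions/predictions.csv")
vr <- validation_report(pb)
print(vr)

m <- vr$metrics
write.csv(data.frame(
  statistic = c("n", "pe_mean", "pe_sd", "ape_mean", "ape_sd", "rmse",
                "pearson_r", "r_ci_lo", "r_ci_hi", "identical_pct",
                "within_one_pct", "kappa_unweighted", "kappa_linear",
                "kappa_quadratic"),
  value = c(m$n, m$pe_mean, m$pe_sd, m$ape_mean, m$ape_sd, m$rmse, m$r,
            m$r_ci[1], m$r_ci[2], 100 * vr$agreement$identical_frac,
            100 * vr$agreement$within_one_frac, vr$kappa$none$kappa,
            vr$kappa$linear$kappa, vr$kappa$quadratic$kappa)),
  file.path(out, "metrics.csv"), row.names = FALSE)
write.csv(as.data.frame(unclass(vr$confusion)),
          file.path(out, "confusion.csv"), row.names = FALSE)
write.csv(vr$per_dim, file.path(out, "per_dim.csv"), row.names = FALSE)

# baseline: predicting every cow at the calibration mean
cal <- read_records("results/data/calibration.csv")
const <- mean(cal$bcs, na.rm = TRUE)
cat(sprintf("constant-mean baseline APE: %.3f (model APE %.3f)\n",
            mean(abs(const - pb$obs_bcs)), m$ape_mean))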