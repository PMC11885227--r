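#!/usr/bin/env Rscript
# Fit the region-count fetal-fraction model on 500 training libraries by
# delete-5% jackknife (1,000 rounds, median coefficients) and validate on
# 200 independent libraries against both the known truth and the
# conventional chrY-dosage estimates.

source("analysis/00_common.R")

regions_bed <- file.path(results_dir, "fetal_regions.bed")
regions <- if (file.exists(regions_bed)) {
  read_regions(regions_bed, genome$chrom_sizes)
} else {
  pl <- planted_fetal_loci(genome)   # fall back to the planted truth
  pl[, c("chrom", "start", "end")]
}

cal <- chry_calibration(genome)
set.seed(base_seed + 3L)
sim_features <- function(n) {
  ffv <- runif(n, 0.05, 0.20)
  rows <- lapply(ffv, function(f) {
    sm <- simulate_sample(genome, f, n_reads = reads_per_sample)
    list(y = count_region_reads(sm$fragments, regions),
         ffy = sm$meta$ff_chrY)
  })
  list(ff = ffv, counts = do.call(rbind, lapply(rows, `[[`, "y")),
       ffy = vapply(rows, `[[`, 0, "ffy"))
}
train <- sim_features(500)
valid <- sim_features(200)

model <- fit_ff_model(train$counts, train$ff,
                      total_reads = rep(reads_per_sample, 500),
                      holdout_fraction = 0.05, iterations = 1000L,
                      seed = base_seed)
msg("fitted %d-region model; %d jackknife rounds, training SSE %.3g",
    length(model$coef) - 1L, model$iterations, model$train_sse)

rep_ <- validate_ff_model(model, valid$counts, valid$ff,
                          total_reads = rep(reads_per_sample, 200))
pred <- predict_ff(model, valid$counts, total_reads = rep(reads_per_sample, 200),
                   clamp = FALSE)
r_chry <- cor(pred, valid$ffy)
msg("validation (n=200): r(truth) = %.4f, r(chrY dosage) = %.4f, RMSE = %.4f, bias = %+.5f",
    rep_$pearson_r, r_chry, rep_$rmse, rep_$bias)

coefs <- data.frame(term = names(model$coef), estimate = unname(model$coef))
write.table(coefs, file.path(results_dir, "ff_model_coefficients.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(metric = c("pearson_r_truth", "pearson_r_chrY", "rmse", "bias"),
                       value = c(rep_$pearson_r, r_chry, rep_$rmse, rep_$bias)),
            file.path(results_dir, "ff_model_validation.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
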