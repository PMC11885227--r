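#!/usr/bin/env Rscript
# Screen aneuploidy-positive samples for confined placental mosaicism: the
# combined Z-score standardizes the discordance between the chrY-based
# fetal fraction and the aneuploidy-implied one against a reference of
# concordant (full-trisomy) positives.

source("analysis/00_common.R")

seg <- genome$segments
cal <- chry_calibration(genome)
set.seed(base_seed + 4L)

triple <- function(ff, karyotype, id) {
  sc <- simulate_segment_counts(genome, ff, karyotype = karyotype,
                                n_reads = reads_per_sample)
  cnt <- tapply(sc, seg$chrom, sum)
  fy <- cnt[["chrY"]] / sum(cnt)
  data.frame(sample_id = id,
             sexFC = min(1, max(0, (fy - cal[["b_female"]]) /
                                  (cal[["b_male"]] - cal[["b_female"]]))),
             RegFC = NA_real_,
             AneuFC = estimate_aneufc(cnt, "chr3", f_exp),
             stringsAsFactors = FALSE)
}

f_exp <- mean(replicate(50, {
  sc <- simulate_segment_counts(genome, runif(1, 0.05, 0.2),
                                n_reads = reads_per_sample)
  sum(sc[seg$chrom == "chr3"]) / sum(sc)
}))
msg("euploid chr3 reference share: %.5f", f_exp)

reference <- do.call(rbind, lapply(1:40, function(i)
  triple(runif(1, 0.05, 0.2), karyotype_trisomy("chr3", 1), sprintf("ref%02d", i))))

# test set: 30 full trisomies and 30 CPM samples with mosaic fraction 0.3-0.7
test <- rbind(
  do.call(rbind, lapply(1:30, function(i)
    triple(runif(1, 0.05, 0.2), karyotype_trisomy("chr3", 1), sprintf("full%02d", i)))),
  do.call(rbind, lapply(1:30, function(i)
    triple(runif(1, 0.10, 0.2), karyotype_trisomy("chr3", runif(1, 0.3, 0.7)),
           sprintf("cpm%02d", i)))))
calls <- combined_zscore(test, reference)
calls$truth <- rep(c("full_trisomy", "cpm"), each = 30)
write.table(calls, file.path(results_dir, "mosaicism_screen.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
msg("flagged %d / 30 CPM samples and %d / 30 full trisomies (cutoff z > %g)",
    sum(calls$flagged[calls$truth == "cpm"]),
    sum(calls$flagged[calls$truth == "full_trisomy"]), attr(calls, "cutoff"))
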