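#!/usr/bin/env Rscript
# Simulate the discovery cohort: 200 male-fetus euploid NIPT-like libraries
# with fetal fractions uniform on 5-20%, 2e5 reads each, and record the
# conventional chrY-dosage fetal-fraction estimate next to the known truth.

source("analysis/00_common.R")

coh <- simulate_cohort(cohort_spec(n_samples = n_discovery,
                                   reads_per_sample = reads_per_sample,
                                   seed = base_seed), genome)
write_sample_meta(coh$meta, file.path(results_dir, "cohort_meta.tsv"))
write_chrom_sizes(genome$chrom_sizes, file.path(results_dir, "chrom.sizes"))

err <- abs(coh$meta$ff_chrY - coh$meta$true_ff)
msg("simulated %d libraries (%d reads each)", nrow(coh$meta), reads_per_sample)
msg("chrY-dosage ff estimate: mean |error| = %.4f, r(truth) = %.4f",
    mean(err), cor(coh$meta$ff_chrY, coh$meta$true_ff))
msg("wrote %s", file.path(results_dir, "cohort_meta.tsv"))
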