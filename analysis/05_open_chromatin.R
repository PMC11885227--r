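#!/usr/bin/env Rscript
# Infer fetal open-chromatin candidates: merge four fetal-fraction tier
# libraries (5/10/15/20%), keep positions whose normalized depth falls
# strictly monotonically with ff, chain 25 bp windows into runs of >= 5,
# collect downstream genes and summarize enrichment against a toy term
# annotation derived from the genome model.

source("analysis/00_common.R")

set.seed(base_seed + 5L)
tiers <- simulate_tier_tracks(genome, n_per_tier = 250L,
                              n_reads = reads_per_sample)
msg("built %d tier libraries (%s samples each)", length(tiers),
    tiers[[1]]$n_samples)

cand <- monotonic_filter(tiers, genome$chrom_sizes, chroms = paste0("chr", 1:4))
msg("monotone positions: %d (%.1f%% down with ff)", nrow(cand),
    100 * mean(cand$direction == "down_with_ff"))

runs <- window_runs(cand, genome$chrom_sizes, flank = 12L, min_windows = 5L)
write_regions(cbind(runs[, c("chrom", "start", "end")],
                    name = runs$direction, score = runs$n_windows),
              file.path(results_dir, "open_chromatin_runs.bed"))
msg("down-with-ff window runs (>=5 windows): %d", nrow(runs))

# fold-change / significance annotation for the run positions
in_runs <- logical(nrow(cand))
for (i in seq_len(nrow(runs)))
  in_runs <- in_runs | (cand$chrom == runs$chrom[i] &
                          cand$pos >= runs$start[i] & cand$pos < runs$end[i])
sub <- cand[in_runs & cand$direction == "down_with_ff", ]
dc <- differential_coverage(sub$x1, sub$x4, tiers[[1]]$total_reads,
                            tiers[[4]]$total_reads)
msg("run positions tested: %d; median tier4/tier1 fold change %.3f",
    nrow(dc), median(dc$fold_change))

ann <- genome_annotation(genome)
genes <- map_downstream_genes(runs, ann)
writeLines(sort(genes), file.path(results_dir, "downstream_genes.txt"))
ndr_hit <- sum(grepl("^ndr", genes))
msg("downstream genes: %d (planted NDR genes among them: %d / %d)",
    length(genes), ndr_hit, sum(grepl("^ndr", ann$gene_id)))

# toy functional annotation: planted NDR genes form a "fetal development"
# term, panel genes a "placental signalling" term, plus a catch-all
terms <- list(fetal_development = ann$gene_id[grepl("^ndr", ann$gene_id)],
              placental_signalling = ann$gene_id[grepl("^pan", ann$gene_id)],
              housekeeping = ann$gene_id[grepl("^nul", ann$gene_id)])
enr <- enrich_terms(genes, terms, ann$gene_id)
write.table(enr, file.path(results_dir, "enrichment.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
msg("top term: %s (k=%d, overlap %.2f%%, p=%.3g)", enr$term_id[1],
    enr$gene_count[1], enr$overlap_pct[1], enr$p_value[1])
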