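# Shared setup for the numbered analysis drivers: one genome model, one
# base seed, one results directory. Every driver re-simulates what it needs
# from these seeds, so each script is independently runnable.

library(niptcov)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

base_seed <- 20260918L
genome <- genome_model(seed = 1L)

# scaled-down cohort design used throughout (full-scale design: 40 groups x
# ~125 samples x 4.2M reads)
n_discovery <- 200L
n_groups <- 40L
reads_per_sample <- 200000L

msg <- function(...) cat(sprintf(...), "\n")
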