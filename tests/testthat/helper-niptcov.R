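# shared fixtures and brute-force oracles (built in code, no stored data)

tiny_sizes <- c(chr1 = 1000L, chr2 = 500L)

random_intervals <- function(n, chrom_sizes, max_len = 60L) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(chrom_sizes[[chrom[i]]] - len[i], 1L) - 1L, 0L)
  gintervals(chrom, start, start + len)
}

# brute-force per-base counter (independent of accumulate_depth)
brute_depth <- function(fragments, chrom_sizes, mode = "coverage") {
  counts <- lapply(chrom_sizes, function(L) numeric(L))
  for (i in seq_len(nrow(fragments))) {
    ch <- fragments$chrom[i]
    if (mode == "coverage") {
      idx <- (fragments$start[i] + 1L):fragments$end[i]
    } else {
      idx <- fragments$start[i] + 1L
    }
    counts[[ch]][idx] <- counts[[ch]][idx] + 1
  }
  counts
}

# expand intervals to a set of per-base keys for base-level comparisons
base_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  unlist(lapply(seq_len(nrow(df)), function(i)
    paste0(df$chrom[i], ":", df$start[i]:(df$end[i] - 1L))))
}

# brute-force maximal left-maximal tandem repeat enumerator (independent
# implementation: direct substring comparisons)
brute_tandem <- function(s, unit_min = 3L, min_copies = 2L) {
  n <- nchar(s)
  res <- list()
  for (u in seq.int(unit_min, max(unit_min, n %/% 2))) {
    if (2L * u > n) break
    for (o in 0:(n - 2L * u)) {
      unit <- substr(s, o + 1L, o + u)
      # left-maximality: extending one position left must break the period
      if (o >= 1L && substr(s, o, o) == substr(s, o + u, o + u)) next
      copies <- 1L
      while (o + (copies + 1L) * u <= n &&
             substr(s, o + copies * u + 1L, o + (copies + 1L) * u) == unit)
        copies <- copies + 1L
      if (copies >= min_copies)
        res[[length(res) + 1L]] <- data.frame(unit = unit, copies = copies,
                                              offset = o, unit_len = u,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(unit = character(0), copies = integer(0),
                      offset = integer(0), unit_len = integer(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# simulate per-region counts without materializing fragments (fast path for
# model-level tests); returns counts over the planted loci plus chromosome
# totals
locus_count_sim <- function(genome, ff, n_reads = 2e5, ...) {
  sc <- simulate_segment_counts(genome, ff, n_reads = n_reads, ...)
  seg <- genome$segments
  loci <- planted_fetal_loci(genome)
  y <- vapply(loci$locus_id, function(id) sum(sc[!is.na(seg$locus_id) & seg$locus_id == id]), 0L)
  list(y = y, chrom_totals = tapply(sc, seg$chrom, sum), total = sum(sc))
}
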