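test_that("monotone direction codes match the stated examples and an oracle", {
  m <- cbind(c(4, 3, 2, 1), c(1, 3, 2, 4), c(1, 2, 3, 4), c(2, 2, 3, 4))
  expect_equal(monotone_direction(m), c(-1L, 0L, 1L, 0L))

  set.seed(24)
  x <- matrix(runif(4 * 5000), nrow = 4)
  got <- monotone_direction(x)
  oracle <- apply(x, 2, function(v)
    if (all(diff(v) < 0)) -1L else if (all(diff(v) > 0)) 1L else 0L)
  expect_identical(got, oracle)
  # distinct random 4-tuples: 2 of 24 orderings are monotone
  expect_equal(mean(got != 0L), 2 / 24, tolerance = 0.25)
})

test_that("conditional binomial test matches closed forms and binom.test", {
  # equal counts at equal totals: fold change 1, p = 1
  dc <- differential_coverage(10, 10, 1e6, 1e6)
  expect_equal(dc$fold_change, 1)
  expect_equal(dc$p, 1)
  # 0 vs 20 at equal totals: p = 2 * 0.5^20
  dc2 <- differential_coverage(0, 20, 1e6, 1e6)
  expect_equal(dc2$p, 2 * 0.5^20)
  # against stats::binom.test on random cases, including unequal totals
  set.seed(25)
  for (i in 1:20) {
    x1 <- rpois(1, 30); x2 <- rpois(1, 50)
    t1 <- 1e6; t2 <- 1.7e6
    if (x1 + x2 == 0) next
    got <- differential_coverage(x1, x2, t1, t2)$p
    ref <- stats::binom.test(x1, x1 + x2, p = t1 / (t1 + t2))$p.value
    expect_equal(got, ref, tolerance = 1e-9)
  }
  # zero totals at a position are dropped and counted
  dc3 <- differential_coverage(c(0, 5), c(0, 5), 1e6, 1e6)
  expect_equal(nrow(dc3), 1L)
  expect_equal(attr(dc3, "n_dropped"), 1L)
})

test_that("BH adjustment follows the hand-computed step-up rule", {
  # independent hand implementation of the step-up rule
  bh_hand <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n); out[o] <- pmin(adj, 1)
    out
  }
  expect_equal(bh_hand(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(26)
  x1 <- rpois(30, 20); x2 <- rpois(30, 28)
  dc <- differential_coverage(x1, x2, 1e6, 1e6)
  expect_equal(dc$adj_p, bh_hand(dc$p))
})

test_that("window runs chain, respect the 5-window cut, and match an oracle", {
  mk <- function(pos, chrom = "chr1")
    data.frame(chrom = chrom, pos = pos, direction = "down_with_ff",
               stringsAsFactors = FALSE)
  sizes <- c(chr1 = 2000L)
  r1 <- window_runs(mk(100:104), sizes)
  expect_equal(r1[, c("start", "end", "n_windows")],
               data.frame(start = 88L, end = 117L, n_windows = 5L))
  expect_equal(nrow(window_runs(mk(100:103), sizes)), 0L)

  # run count is non-increasing in min_windows (screeplot behavior)
  set.seed(27)
  cand <- mk(sort(sample(0:1999, 400)))
  counts <- vapply(1:8, function(k)
    nrow(window_runs(cand, sizes, min_windows = k)), 0L)
  expect_true(all(diff(counts) <= 0))

  # brute-force union-scanner oracle
  oracle_runs <- function(pos, L, flank = 12L, min_w = 5L) {
    covered <- logical(L)
    for (p in pos) covered[max(0L, p - flank):min(L - 1L, p + flank) + 1L] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    keep <- which(r$values)
    out <- lapply(keep, function(j) {
      nw <- sum(pos >= starts[j] & pos < ends[j])
      if (nw < min_w) return(NULL)
      data.frame(start = starts[j], end = ends[j], n_windows = nw)
    })
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  for (i in 1:50) {
    pos <- sort(sample(0:1999, sample(5:80, 1)))
    got <- window_runs(mk(pos), sizes)
    exp <- oracle_runs(pos, 2000L)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[, c("start", "end", "n_windows")], exp, ignore_attr = TRUE)
    }
  }

  # direction filter and interval restriction
  both <- rbind(mk(100:104), transform(mk(300:304), direction = "up_with_ff"))
  expect_equal(nrow(window_runs(both, sizes)), 1L)
  expect_equal(nrow(window_runs(both, sizes, direction = "up_with_ff")), 1L)
  restr <- data.frame(chrom = "chr1", start = 0L, end = 50L)
  expect_equal(nrow(window_runs(mk(100:104), sizes, restrict = restr)), 0L)
})

test_that("downstream gene mapping is strand-aware and matches all-pairs", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC"), gene_name = c("gA", "gB", "gC"),
                    chrom = "chr1", start = c(5000L, 8000L, 60000L),
                    end = c(7000L, 10000L, 62000L), strand = c("+", "-", "+"),
                    tss = c(5000L, 9999L, 60000L), stringsAsFactors = FALSE)
  runs <- data.frame(chrom = "chr1", start = 4400L, end = 4500L)
  expect_equal(map_downstream_genes(runs, ann), "gA")   # 500 bp upstream of gA
  runs2 <- data.frame(chrom = "chr1", start = 10100L, end = 10200L)
  expect_equal(map_downstream_genes(runs2, ann), "gB")  # upstream on - strand
  expect_equal(length(map_downstream_genes(
    data.frame(chrom = "chr1", start = 10000L, end = 10100L), ann,
    max_distance = 10000L)), 1L)  # 50 kb from gC is out of range for gC
  set.seed(28)
  for (i in 1:20) {
    ng <- 15
    ann_r <- data.frame(gene_id = sprintf("g%02d", 1:ng),
                        gene_name = sprintf("g%02d", 1:ng),
                        chrom = sample(c("chr1", "chr2"), ng, TRUE),
                        strand = sample(c("+", "-"), ng, TRUE),
                        tss = sample(0:99999, ng), stringsAsFactors = FALSE)
    ann_r$start <- ifelse(ann_r$strand == "+", ann_r$tss, pmax(0L, ann_r$tss - 999L))
    ann_r$end <- ifelse(ann_r$strand == "+", ann_r$tss + 1000L, ann_r$tss + 1L)
    rn <- 8
    runs_r <- data.frame(chrom = sample(c("chr1", "chr2"), rn, TRUE),
                         start = sample(0:99999, rn))
    runs_r$end <- runs_r$start + sample(50:500, rn, TRUE)
    got <- sort(map_downstream_genes(runs_r, ann_r, max_distance = 5000))
    oracle <- character(0)
    for (gi in seq_len(ng)) {
      ws <- if (ann_r$strand[gi] == "+") max(0, ann_r$tss[gi] - 5000) else ann_r$tss[gi] + 1
      we <- if (ann_r$strand[gi] == "+") ann_r$tss[gi] else ann_r$tss[gi] + 1 + 5000
      for (ri in seq_len(rn)) {
        if (runs_r$chrom[ri] == ann_r$chrom[gi] &&
            runs_r$start[ri] < we && runs_r$end[ri] > ws) {
          oracle <- c(oracle, ann_r$gene_id[gi]); break
        }
      }
    }
    expect_equal(got, sort(oracle))
  }
})

test_that("hypergeometric enrichment matches exact enumeration", {
  bg <- sprintf("g%02d", 1:20)
  terms <- list(T1 = bg[1:5], T2 = bg[6:7], T0 = character(0))
  res <- enrich_terms(bg[1:5], terms, bg)
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r1$overlap_pct, 100)  # 5 of N=5 mapped genes
  expect_false("T0" %in% res$term_id)  # K = 0 skipped
  # overlap_pct * N / 100 is integral for every row
  expect_true(all(abs(res$overlap_pct * res$list_size / 100 -
                        round(res$overlap_pct * res$list_size / 100)) < 1e-9))
  expect_error(enrich_terms(c("zzz"), terms, bg), "subset")
})

test_that("planted NDR dips are recovered as down runs on noiseless tiers", {
  g <- genome_model()
  tiers <- lapply(c(0.05, 0.10, 0.15, 0.20), function(f)
    group_from_track(expected_depth_track(g, f, n_reads = 5e7,
                                          chroms = paste0("chr", 1:4)),
                     mean_ff = f, n_samples = 1))
  cand <- monotonic_filter(tiers, g$chrom_sizes, chroms = paste0("chr", 1:4))
  runs <- window_runs(cand, g$chrom_sizes)
  ndr <- planted_ndr(g)
  hit <- vapply(seq_len(nrow(ndr)), function(i)
    any(runs$chrom == ndr$chrom[i] & runs$start < ndr$end[i] &
          runs$end > ndr$start[i]), TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("planted NDR dips are recovered at scaled-down stochastic depth", {
  g <- genome_model()
  set.seed(123)
  tiers <- simulate_tier_tracks(g)  # 4 x 250 samples x 2e5 reads
  cand <- monotonic_filter(tiers, g$chrom_sizes, chroms = paste0("chr", 1:4))
  runs <- window_runs(cand, g$chrom_sizes)
  ndr <- planted_ndr(g)
  hit <- vapply(seq_len(nrow(ndr)), function(i)
    any(runs$chrom == ndr$chrom[i] & runs$start < ndr$end[i] &
          runs$end > ndr$start[i]), TRUE)
  expect_gte(mean(hit), 0.8)
  # dip-overlapping runs point at the planted genes downstream
  genes <- map_downstream_genes(runs, genome_annotation(g))
  expect_true(all(planted_ndr(g)$gene_id %in% genes))
})
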