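test_that("stratification sorts by ff and conserves depth", {
  g <- genome_model()
  # 4 samples with known ffs into 4 singleton groups, ff order
  toy <- list(gintervals("chr1", 0, 40), gintervals("chr1", 40, 80),
              gintervals("chr1", 80, 120), gintervals("chr1", 120, 160))
  toy_meta <- data.frame(sample_id = paste0("s", 1:4), total_reads = 1L,
                         fetal_sex = "male", ff_chrY = c(0.15, 0.05, 0.20, 0.10),
                         group_label = "", condition = "control")
  groups0 <- merge_groups(toy, toy_meta, 4)
  expect_equal(vapply(groups0, `[[`, 0, "n_samples"), rep(1, 4))
  expect_equal(vapply(groups0, `[[`, 0, "mean_ff"), c(0.05, 0.10, 0.15, 0.20))
  expect_equal(groups0[[1]]$sample_ids, "s2")

  set.seed(12)
  coh <- simulate_cohort(cohort_spec(n_samples = 8, reads_per_sample = 2000), g)

  groups2 <- merge_groups(coh$samples, coh$meta, 2)
  td <- group_depth(groups2[[1]], g$chrom_sizes)
  member_mass <- sum(vapply(coh$samples[match(groups2[[1]]$sample_ids, coh$meta$sample_id)],
                            function(fr) sum(fr$end - fr$start), 0))
  expect_equal(sum(vapply(td$counts, sum, 0)), member_mass)
  expect_equal(groups2[[1]]$total_reads, 4 * 2000)

  expect_error(merge_groups(coh$samples, coh$meta, 9), "exceeds")
})

test_that("position fit matches closed-form OLS and flags degeneracy", {
  ffs <- c(0.05, 0.10, 0.15, 0.20)
  # exact fetal-only linearity
  f <- fit_position(7 * ffs, ffs)
  expect_equal(f$slope, 7)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$rel_error, 0, tolerance = 1e-12)
  # constant depths: slope 0, zero error, still evaluable
  f2 <- fit_position(rep(3, 4), ffs)
  expect_equal(f2$slope, 0)
  expect_equal(f2$rel_error, 0)
  expect_true(f2$evaluable)
  # arbitrary values vs an independent lm() fit
  set.seed(13)
  for (i in 1:5) {
    d <- runif(4, 1, 10)
    f3 <- fit_position(d, ffs)
    lmf <- stats::lm(d ~ ffs)
    expect_equal(f3$intercept, unname(stats::coef(lmf)[1]))
    expect_equal(f3$slope, unname(stats::coef(lmf)[2]))
    expect_equal(f3$rel_error, max(abs(d - stats::fitted(lmf)) / stats::fitted(lmf)))
  }
  expect_false(fit_position(rep(0, 4), ffs)$evaluable)
  expect_error(fit_position(1:4, c(0.1, 0.05, 0.15, 0.2)))
})

test_that("region calling merges adjacency and matches a brute-force scanner", {
  mk_fits <- function(pos, qual, slope = 1, minr = 5) {
    data.frame(chrom = "chr1", pos = pos, slope = slope,
               rel_error = ifelse(qual, 0.001, 0.5), evaluable = TRUE,
               min_raw = minr)
  }
  r1 <- call_fetal_regions(mk_fits(0:9, rep(TRUE, 10)))
  expect_equal(r1$regions[, c("start", "end")], data.frame(start = 0L, end = 10L))
  r2 <- call_fetal_regions(mk_fits(c(0:4, 6:9), rep(TRUE, 9)))
  expect_equal(r2$regions$start, c(0L, 6L))
  expect_equal(r2$regions$end, c(5L, 10L))

  # brute-force oracle over random fit streams
  set.seed(14)
  for (rep in 1:20) {
    n <- 200
    fits <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                       pos = c(sample(0:150, 100), sample(0:150, 100)),
                       slope = rnorm(n), rel_error = runif(n, 0, 0.05),
                       evaluable = runif(n) > 0.1,
                       min_raw = sample(0:5, n, TRUE))
    fits <- fits[!duplicated(fits[c("chrom", "pos")]), ]
    got <- call_fetal_regions(fits)$regions
    # oracle: per-base qualification then linear scan
    oracle <- list()
    for (ch in c("chr1", "chr2")) {
      sel <- fits[fits$chrom == ch, ]
      sel <- sel[order(sel$pos), ]
      q <- sel$evaluable & sel$rel_error < 0.015 & sel$slope > 0 & sel$min_raw >= 2
      qp <- sel$pos[q]
      if (!length(qp)) next
      st <- qp[1]
      for (i in seq_along(qp)) {
        if (i == length(qp) || qp[i + 1] != qp[i] + 1) {
          oracle[[length(oracle) + 1]] <- data.frame(chrom = ch, start = st,
                                                     end = qp[i] + 1)
          if (i < length(qp)) st <- qp[i + 1]
        }
      }
    }
    oracle <- do.call(rbind, oracle)
    canon <- function(df) {
      df <- df[order(df$chrom, df$start), c("chrom", "start", "end")]
      rownames(df) <- NULL
      df
    }
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(canon(got), canon(oracle), ignore_attr = TRUE)
    }
  }
})

test_that("PWM columns are normalized frequencies with stable consensus", {
  p1 <- pwm_from_sequences(rep("ACGT", 3))
  expect_equal(p1$consensus, "ACGT")
  expect_true(all(abs(colSums(p1$mat) - 1) < 1e-9))
  expect_equal(unname(p1$mat[, 1]), c(1, 0, 0, 0))

  p2 <- pwm_from_sequences(c("AAAA", "AATA"))
  expect_equal(unname(p2$mat["A", 3]), 0.5)
  expect_equal(unname(p2$mat["T", 3]), 0.5)

  set.seed(15)
  seqs <- vapply(1:20, function(i) {
    s <- strsplit(random_dna(50), "")[[1]]
    s[9:18] <- strsplit("CGGAACGGAA", "")[[1]]
    paste(s, collapse = "")
  }, "")
  p3 <- pwm_from_sequences(seqs)
  expect_equal(substr(p3$consensus, 9, 18), "CGGAACGGAA")
  # consensus invariant under duplicated input
  p4 <- pwm_from_sequences(c(seqs, seqs))
  expect_equal(p4$consensus, p3$consensus)
})

test_that("flank PWM extraction reads the genome model and skips bare flanks", {
  g <- genome_model()
  loci <- planted_fetal_loci(g)
  pw <- build_flank_pwm(loci, g)
  expect_equal(substr(pw$consensus, 7, 20), "AGCGGAACGGAACG")
  expect_equal(pw$n_seqs, nrow(loci))
  # a region without stored sequence is skipped with a warning
  with_bare <- rbind(loci[, c("chrom", "start", "end")],
                     data.frame(chrom = "chr5", start = 1000L, end = 1200L))
  expect_warning(pw2 <- build_flank_pwm(with_bare, g), "skipped")
  expect_equal(pw2$consensus, pw$consensus)
})

test_that("tandem repeat detector handles the stated edge cases", {
  r <- detect_tandem_repeat("AGCGGAACGGAACG")
  hit <- r[r$unit == "CGGAA", ]
  expect_gte(nrow(hit), 1)
  expect_equal(hit$offset[1], 2L)
  expect_gte(hit$copies[1], 2)

  r2 <- detect_tandem_repeat("AAAAAA", unit_min = 3)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$unit, "AAA")
  expect_equal(r2$copies, 2L)
  expect_equal(r2$offset, 0L)

  set.seed(16)
  for (i in 1:30) {
    s <- random_dna(sample(20:60, 1))
    expect_identical(detect_tandem_repeat(s), brute_tandem(s),
                     info = paste("string:", s))
  }
})
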