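#' Synthetic NIPT cohort generator
#'
#' The generator emulates the statistical structure of low-pass maternal
#' plasma cfDNA sequencing that the downstream stages assume: read starts are
#' drawn from a mixture `(1 - ff) * maternal + ff * fetal` of per-base
#' sampling profiles over a toy genome; chrY carries fetal mass only for male
#' fetuses; a set of planted autosomal fetal-specific loci receives sampling
#' weight only from the fetal component and is flanked by a CGGAA-repeat
#' motif; planted TSS-proximal nucleosome-depleted regions (NDRs) deplete the
#' fetal profile so their absolute coverage dips deepen linearly with fetal
#' fraction; trisomy / confined-placental-mosaicism dosage multiplies the
#' fetal weight of a target chromosome by `1 + m/2`; case samples perturb a
#' panel of promoter loci up or down.
#'
#' Profiles are piecewise constant, so they are stored as a segment table
#' (not a 10.5-Mb per-base vector); sampling draws a multinomial over
#' segments and uniform positions within each segment, which is distributed
#' identically to per-base sampling.
#'
#' @param seed integer seed controlling the (fixed) flank reference
#'   sequences of the planted loci.
#' @param fetal_region_mass total fetal-profile mass on the planted
#'   fetal-specific loci (default 0.10; strong placental enrichment
#'   compensating the scaled-down read counts, see the methods vignette).
#' @param ndr_dip fetal-density multiplier inside planted NDRs (default 0.2).
#' @param panel_effect multiplicative case effect on panel loci (default 0.5).
#' @param read_length fragment width in bp (single-end 40 bp reads).
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(seed = 1L, fetal_region_mass = 0.10, ndr_dip = 0.2,
                         panel_effect = 0.5, read_length = 40L) {
  chrom_sizes <- c(chr1 = 2000000L, chr2 = 2000000L, chr3 = 2000000L,
                   chr4 = 2000000L, chr5 = 2000000L, chrY = 500000L)
  autosomes <- paste0("chr", 1:5)

  # 12 planted fetal-specific loci, 200 bp, three per chromosome on chr1-chr4
  loci <- expand.grid(pos = c(300000L, 900000L, 1500000L),
                      chrom = paste0("chr", 1:4), stringsAsFactors = FALSE)
  fetal_loci <- gintervals(loci$chrom, loci$pos, loci$pos + 200L)
  fetal_loci$locus_id <- sprintf("fsr%02d", seq_len(nrow(fetal_loci)))

  # 24 NDR genes (six per chromosome on chr1-chr4), alternating strand;
  # the NDR is a 150 bp window upstream of the TSS
  ng <- expand.grid(k = 0:5, chrom = paste0("chr", 1:4), stringsAsFactors = FALSE)
  ng$tss <- 150000L + ng$k * 300000L
  ng$strand <- rep(c("+", "-"), length.out = nrow(ng))
  ndr_genes <- data.frame(
    gene_id = sprintf("ndr%02d", seq_len(nrow(ng))),
    chrom = ng$chrom,
    start = ifelse(ng$strand == "+", ng$tss, ng$tss - 1999L),
    end = ifelse(ng$strand == "+", ng$tss + 2000L, ng$tss + 1L),
    strand = ng$strand, tss = ng$tss, stringsAsFactors = FALSE)
  ndr <- data.frame(
    chrom = ng$chrom,
    start = ifelse(ng$strand == "+", ng$tss - 180L, ng$tss + 31L),
    end = ifelse(ng$strand == "+", ng$tss - 30L, ng$tss + 181L),
    stringsAsFactors = FALSE)

  # 20 panel genes on chr5; promoter window TSS +/- 250 bp; alternating
  # direction of the case effect
  pg <- data.frame(k = 0:19)
  pg$tss <- 50000L + pg$k * 90000L
  pg$strand <- rep(c("+", "-"), length.out = nrow(pg))
  panel_genes <- data.frame(
    gene_id = sprintf("pan%02d", seq_len(nrow(pg))),
    chrom = "chr5",
    start = ifelse(pg$strand == "+", pg$tss, pg$tss - 1999L),
    end = ifelse(pg$strand == "+", pg$tss + 2000L, pg$tss + 1L),
    strand = pg$strand, tss = pg$tss, stringsAsFactors = FALSE)
  panel <- data.frame(
    chrom = "chr5", start = pg$tss - 250L, end = pg$tss + 250L,
    direction = rep(c("up", "down"), length.out = nrow(pg)),
    stringsAsFactors = FALSE)
  panel$locus_id <- sprintf("pan%02d", seq_len(nrow(panel)))

  # null genes: annotated but carry no planted signal
  nn <- expand.grid(pos = c(1800000L, 1950000L), chrom = paste0("chr", 1:4),
                    stringsAsFactors = FALSE)
  null_genes <- data.frame(
    gene_id = sprintf("nul%02d", seq_len(nrow(nn))),
    chrom = nn$chrom, start = nn$pos, end = nn$pos + 2000L,
    strand = "+", tss = nn$pos, stringsAsFactors = FALSE)

  annotation <- rbind(ndr_genes, panel_genes, null_genes)
  annotation$gene_name <- annotation$gene_id
  annotation <- annotation[, c("gene_id", "gene_name", "chrom", "start", "end",
                               "strand", "tss")]

  # segment table: piecewise-constant density domains
  special <- rbind(
    data.frame(chrom = fetal_loci$chrom, start = fetal_loci$start,
               end = fetal_loci$end, type = "fetal_locus",
               locus_id = fetal_loci$locus_id, stringsAsFactors = FALSE),
    data.frame(chrom = ndr$chrom, start = ndr$start, end = ndr$end,
               type = "ndr_dip", locus_id = ndr_genes$gene_id,
               stringsAsFactors = FALSE),
    data.frame(chrom = panel$chrom, start = panel$start, end = panel$end,
               type = paste0("panel_", panel$direction),
               locus_id = panel$locus_id, stringsAsFactors = FALSE))
  seg <- list()
  for (ch in names(chrom_sizes)) {
    sp <- special[special$chrom == ch, , drop = FALSE]
    sp <- sp[order(sp$start), , drop = FALSE]
    if (nrow(sp) && any(sp$start[-1] < sp$end[-nrow(sp)]))
      stop("planted intervals overlap on ", ch)
    cuts <- sort(unique(c(0L, sp$start, sp$end, chrom_sizes[[ch]])))
    s <- data.frame(chrom = ch, start = cuts[-length(cuts)], end = cuts[-1],
                    type = "background", locus_id = NA_character_,
                    stringsAsFactors = FALSE)
    if (nrow(sp)) {
      idx <- match(s$start, sp$start)
      hit <- !is.na(idx)
      s$type[hit] <- sp$type[idx[hit]]
      s$locus_id[hit] <- sp$locus_id[idx[hit]]
    }
    seg[[ch]] <- s
  }
  seg <- do.call(rbind, seg)
  rownames(seg) <- NULL
  seg$len <- seg$end - seg$start
  seg$chrom_len <- unname(chrom_sizes[seg$chrom])

  # maternal profile: uniform over autosomes, zero on chrY and fetal loci
  seg$mat_d <- 0
  mat_sel <- seg$chrom %in% autosomes & seg$type != "fetal_locus"
  seg$mat_d[mat_sel] <- 1 / sum(seg$len[mat_sel])

  # fetal profile (male): uniform baseline, boosted loci, depleted NDRs
  G <- sum(as.numeric(chrom_sizes))
  u <- 1 / G
  d <- rep(u, nrow(seg))
  d[seg$type == "fetal_locus"] <- fetal_region_mass / sum(seg$len[seg$type == "fetal_locus"])
  d[seg$type == "ndr_dip"] <- ndr_dip * u
  seg$fet_d_male <- d / sum(d * seg$len)
  d_f <- d
  d_f[seg$chrom == "chrY"] <- 0
  seg$fet_d_female <- d_f / sum(d_f * seg$len)

  # flank reference sequences: random background with the tandem-repeat
  # motif planted so that the 50 bp upstream window reads AGCGGAACGGAACG
  # starting at offset 6 (CGGAACGGAA at offsets 8-17)
  motif <- "AGCGGAACGGAACG"
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  ref <- do.call(rbind, lapply(seq_len(nrow(fetal_loci)), function(i) {
    s0 <- fetal_loci$start[i] - 80L
    e0 <- fetal_loci$end[i] + 60L
    bases <- sample(c("A", "C", "G", "T"), e0 - s0, replace = TRUE)
    # genome coords of the motif: flank offset 6 within [start-50, start)
    off <- (fetal_loci$start[i] - 50L + 6L) - s0
    bases[(off + 1L):(off + nchar(motif))] <- strsplit(motif, "")[[1]]
    data.frame(chrom = fetal_loci$chrom[i], start = s0, end = e0,
               seq = paste(bases, collapse = ""), stringsAsFactors = FALSE)
  }))
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }

  structure(list(chrom_sizes = chrom_sizes, segments = seg,
                 fetal_loci = fetal_loci, ndr = cbind(ndr, gene_id = ndr_genes$gene_id),
                 panel = panel, annotation = annotation, ref_seq = ref,
                 fetal_region_mass = fetal_region_mass, ndr_dip = ndr_dip,
                 panel_effect = panel_effect, read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$chrom_sizes), " chromosomes, ",
      format(sum(as.numeric(x$chrom_sizes)), big.mark = ","), " bp\n",
      "  planted fetal-specific loci: ", nrow(x$fetal_loci),
      " (", x$fetal_region_mass * 100, "% of fetal mass)\n",
      "  planted NDR genes: ", nrow(x$ndr), "; panel loci: ", nrow(x$panel), "\n",
      sep = "")
  invisible(x)
}

#' Euploid karyotype / trisomy descriptors
#'
#' `m` is the fraction of aneuploid placental cells: `m = 1` is full trisomy,
#' `0 < m < 1` confined placental mosaicism. The fetal sampling weight of the
#' target chromosome is multiplied by `1 + m/2`.
#'
#' @param chrom target chromosome.
#' @param m mosaic fraction in (0, 1].
#' @export
karyotype_trisomy <- function(chrom = "chr3", m = 1) {
  stopifnot(m > 0, m <= 1)
  list(type = "trisomy", chrom = chrom, m = m)
}

#' @rdname karyotype_trisomy
#' @export
karyotype_euploid <- function() list(type = "euploid")

#' Per-segment sampling weights for one sample
#'
#' Returns the normalized probability that a read start falls in each segment
#' of the genome model, under the mixture
#' `(1 - ff) * maternal + ff * fetal(sex, karyotype)` with case perturbation
#' of the panel loci. The trisomy multiplier is applied to the fetal
#' component before the final normalization (a trisomic genome contributes
#' proportionally more DNA), so target-chromosome dosage inflation follows
#' the generator's closed form rather than the small-chromosome
#' approximation.
#'
#' @param genome a [genome_model()].
#' @param ff fetal fraction in `[0, 1]`.
#' @param sex `"male"` or `"female"` fetus.
#' @param karyotype [karyotype_euploid()] or [karyotype_trisomy()].
#' @param condition `"control"`, `"case"` or `"unknown"`.
#' @return numeric vector of probabilities aligned with `genome$segments`.
#' @export
sample_weights <- function(genome, ff, sex = c("male", "female"),
                           karyotype = karyotype_euploid(),
                           condition = "control") {
  sex <- match.arg(sex)
  stopifnot(ff >= 0, ff <= 1)
  seg <- genome$segments
  fet_d <- if (sex == "male") seg$fet_d_male else seg$fet_d_female
  if (sex == "female" && any(fet_d[seg$chrom == "chrY"] > 0))
    stop("internal consistency error: female fetus with chrY fetal mass")
  fet_w <- fet_d * seg$len
  if (identical(karyotype$type, "trisomy")) {
    sel <- seg$chrom == karyotype$chrom
    if (!any(sel)) stop("unknown trisomy chromosome: ", karyotype$chrom)
    fet_w[sel] <- fet_w[sel] * (1 + karyotype$m / 2)
  }
  w <- (1 - ff) * seg$mat_d * seg$len + ff * fet_w
  if (identical(condition, "case")) {
    w[seg$type == "panel_up"] <- w[seg$type == "panel_up"] * (1 + genome$panel_effect)
    w[seg$type == "panel_down"] <- w[seg$type == "panel_down"] * (1 - genome$panel_effect)
  }
  w / sum(w)
}

#' Draw per-segment read-start counts for one sample
#'
#' Multinomial draw over the segment weights; equivalent to per-base
#' sampling but without materializing positions. Uses R's global RNG.
#'
#' @inheritParams sample_weights
#' @param n_reads library size (uniquely mapped read count).
#' @return integer vector of counts aligned with `genome$segments`.
#' @export
simulate_segment_counts <- function(genome, ff, sex = "male",
                                    karyotype = karyotype_euploid(),
                                    condition = "control", n_reads = 200000L) {
  w <- sample_weights(genome, ff, sex, karyotype, condition)
  as.integer(stats::rmultinom(1L, n_reads, w))
}

#' Simulate one NIPT library
#'
#' Draws `n_reads` fixed-width read-start positions from the sample's
#' mixture profile and returns the fragment intervals plus a metadata row
#' (with the true mixing fetal fraction recorded in `true_ff` and the
#' conventional chrY-dosage estimate in `ff_chrY` for male fetuses).
#'
#' @inheritParams simulate_segment_counts
#' @param sample_id sample identifier.
#' @param group_label cohort stratum label.
#' @return list with `fragments` (interval data.frame) and `meta` (one-row
#'   data.frame).
#' @export
simulate_sample <- function(genome, ff, sex = "male",
                            karyotype = karyotype_euploid(),
                            condition = "control", n_reads = 200000L,
                            sample_id = "s1", group_label = "g1") {
  seg <- genome$segments
  cnt <- simulate_segment_counts(genome, ff, sex, karyotype, condition, n_reads)
  idx <- rep.int(seq_len(nrow(seg)), cnt)
  start <- seg$start[idx] +
    as.integer(floor(stats::runif(length(idx)) * seg$len[idx]))
  o <- order(idx, start, method = "radix")  # segments are chrom/pos sorted
  idx <- idx[o]; start <- start[o]
  frags <- data.frame(chrom = seg$chrom[idx], start = start,
                      end = pmin(start + genome$read_length, seg$chrom_len[idx]),
                      stringsAsFactors = FALSE)
  ffy <- if (sex == "male") {
    estimate_ff_chry(frags, calib = chry_calibration(genome))
  } else NA_real_
  meta <- data.frame(sample_id = sample_id, total_reads = n_reads,
                     fetal_sex = sex, ff_chrY = ffy, group_label = group_label,
                     condition = condition, true_ff = ff,
                     stringsAsFactors = FALSE)
  list(fragments = frags, meta = meta)
}

#' Cohort specification
#'
#' Defaults follow the scaled-down synthetic world: 200,000 reads per
#' library (the full-scale design is 4.2 million 40 bp single-end reads) and
#' fetal fractions uniform on 5--20%.
#'
#' @param n_samples number of libraries.
#' @param reads_per_sample reads per library.
#' @param ff_min,ff_max bounds of the uniform fetal-fraction distribution.
#' @param fraction_male probability of a male fetus.
#' @param case_fraction probability of a case (panel-perturbed) sample.
#' @param trisomy_prob probability of a trisomic sample.
#' @param trisomy_chrom,mosaic_m trisomy target and mosaic fraction.
#' @param seed RNG seed; the cohort is deterministic given the seed.
#' @export
cohort_spec <- function(n_samples, reads_per_sample = 200000L, ff_min = 0.05,
                        ff_max = 0.20, fraction_male = 1, case_fraction = 0,
                        trisomy_prob = 0, trisomy_chrom = "chr3", mosaic_m = 1,
                        seed = 1L) {
  stopifnot(n_samples >= 0, reads_per_sample > 0,
            ff_min >= 0, ff_max <= 1, ff_min <= ff_max,
            fraction_male >= 0, fraction_male <= 1,
            case_fraction >= 0, case_fraction <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 ff_min = ff_min, ff_max = ff_max,
                 fraction_male = fraction_male, case_fraction = case_fraction,
                 trisomy_prob = trisomy_prob, trisomy_chrom = trisomy_chrom,
                 mosaic_m = mosaic_m, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort
#'
#' Deterministic given `spec$seed`. If `dir` is given, per-sample BED files
#' and a metadata TSV are written there in the formats of the I/O module.
#'
#' @param spec a [cohort_spec()].
#' @param genome a [genome_model()].
#' @param dir optional output directory.
#' @return list with `samples` (list of fragment data.frames, one per
#'   library) and `meta` (metadata data.frame).
#' @export
simulate_cohort <- function(spec, genome, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  meta_cols <- data.frame(sample_id = character(0), total_reads = integer(0),
                          fetal_sex = character(0), ff_chrY = numeric(0),
                          group_label = character(0), condition = character(0),
                          true_ff = numeric(0), stringsAsFactors = FALSE)
  samples <- vector("list", spec$n_samples)
  metas <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    ff <- stats::runif(1, spec$ff_min, spec$ff_max)
    sex <- if (stats::runif(1) < spec$fraction_male) "male" else "female"
    kt <- if (stats::runif(1) < spec$trisomy_prob)
      karyotype_trisomy(spec$trisomy_chrom, spec$mosaic_m) else karyotype_euploid()
    cond <- if (stats::runif(1) < spec$case_fraction) "case" else "control"
    sm <- simulate_sample(genome, ff, sex, kt, cond,
                          n_reads = spec$reads_per_sample,
                          sample_id = sprintf("s%04d", i))
    samples[[i]] <- sm$fragments
    metas[[i]] <- sm$meta
  }
  meta <- if (spec$n_samples) do.call(rbind, metas) else meta_cols
  names(samples) <- meta$sample_id
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(spec$n_samples))
      write_fragments(samples[[i]], file.path(dir, paste0(meta$sample_id[i], ".bed")))
    write_sample_meta(meta, file.path(dir, "samples.tsv"))
    write_chrom_sizes(genome$chrom_sizes, file.path(dir, "chrom.sizes"))
  }
  list(samples = samples, meta = meta)
}

#' Noiseless expected depth track
#'
#' Analytic expectation of [accumulate_depth()] over the generator's mixture
#' for one library or a merged pool of libraries (pass a vector `ff`; each
#' member contributes `n_reads` reads). Used for noiseless recovery checks.
#'
#' @inheritParams simulate_segment_counts
#' @param ff fetal fraction(s); a vector describes a merged pool.
#' @param mode `"coverage"` or `"read_start"`.
#' @param chroms chromosomes to materialize (default all).
#' @return a raw [depth_track()] with (non-integer) expected counts.
#' @export
expected_depth_track <- function(genome, ff, sex = "male",
                                 karyotype = karyotype_euploid(),
                                 condition = "control", n_reads = 200000L,
                                 mode = c("coverage", "read_start"),
                                 chroms = NULL) {
  mode <- match.arg(mode)
  seg <- genome$segments
  w <- rowSums(vapply(ff, function(f)
    sample_weights(genome, f, sex, karyotype, condition) * n_reads,
    numeric(nrow(seg))))
  rate <- w / seg$len  # expected read starts per bp
  if (is.null(chroms)) chroms <- names(genome$chrom_sizes)
  counts <- lapply(chroms, function(ch) {
    L <- genome$chrom_sizes[[ch]]
    sel <- which(seg$chrom == ch)
    r <- numeric(L)
    for (i in sel) r[(seg$start[i] + 1L):seg$end[i]] <- rate[i]
    if (mode == "read_start") return(r)
    cs <- cumsum(r)
    k <- genome$read_length
    cs - c(rep(0, k), utils::head(cs, -k))
  })
  names(counts) <- chroms
  depth_track(counts, total_reads = length(ff) * n_reads, mode = mode)
}

#' Simulate fetal-fraction tier libraries as depth tracks
#'
#' Builds the merged tier libraries of the open-chromatin scan (by default
#' four tiers at mean fetal fractions 5/10/15/20%) directly as pooled depth
#' tracks, accumulating coverage in batches so per-sample fragments are
#' never all held in memory. Member fetal fractions are jittered uniformly
#' around the tier center.
#'
#' @param genome a [genome_model()].
#' @param tier_ffs tier center fetal fractions (strictly increasing).
#' @param n_per_tier samples per tier (equal across tiers).
#' @param n_reads reads per sample.
#' @param jitter half-width of the member ff jitter (default 0.015).
#' @param mode depth mode (default `"coverage"`).
#' @param batch_size samples pooled per accumulation batch.
#' @return list of track-backed `group_library` objects (one per tier).
#' @export
simulate_tier_tracks <- function(genome, tier_ffs = c(0.05, 0.10, 0.15, 0.20),
                                 n_per_tier = 250L, n_reads = 200000L,
                                 jitter = 0.015, mode = "coverage",
                                 batch_size = 25L) {
  stopifnot(all(diff(tier_ffs) > 0))
  cs <- genome$chrom_sizes
  lapply(seq_along(tier_ffs), function(t) {
    ffs <- stats::runif(n_per_tier, max(0.01, tier_ffs[t] - jitter),
                        tier_ffs[t] + jitter)
    counts <- lapply(cs, function(L) numeric(L))
    done <- 0L
    while (done < n_per_tier) {
      take <- min(batch_size, n_per_tier - done)
      frs <- lapply(seq_len(take), function(i)
        simulate_sample(genome, ffs[done + i], n_reads = n_reads)$fragments)
      frags <- as.data.frame(data.table::rbindlist(frs))
      batch <- accumulate_depth(frags, cs, mode = mode)
      for (ch in names(cs)) counts[[ch]] <- counts[[ch]] + batch$counts[[ch]]
      done <- done + take
    }
    tr <- depth_track(counts, total_reads = n_per_tier * n_reads, mode = mode)
    group_from_track(tr, mean_ff = mean(ffs),
                     group_label = sprintf("tier%02.0f", tier_ffs[t] * 100),
                     n_samples = n_per_tier)
  })
}

#' chrY dosage calibration shares of the generator
#'
#' Returns the chrY read-start share of a pure maternal library
#' (`b_female`) and of a pure male fetal library (`b_male`), measured from
#' the model's own profiles; the conventional chrY-dosage fetal-fraction
#' estimate interpolates between them.
#'
#' @param genome a [genome_model()].
#' @return named numeric vector `c(b_female=, b_male=)`.
#' @export
chry_calibration <- function(genome) {
  seg <- genome$segments
  y <- seg$chrom == "chrY"
  c(b_female = sum(seg$mat_d[y] * seg$len[y]),
    b_male = sum(seg$fet_d_male[y] * seg$len[y]))
}

#' Accessors for the planted truth of a genome model
#'
#' `planted_fetal_loci()` returns the fetal-specific intervals,
#' `planted_ndr()` the NDR dip intervals, `planted_panel()` the case panel
#' loci, and `genome_annotation()` the gene annotation table.
#'
#' @param genome a [genome_model()].
#' @export
planted_fetal_loci <- function(genome) genome$fetal_loci

#' @rdname planted_fetal_loci
#' @export
planted_ndr <- function(genome) genome$ndr

#' @rdname planted_fetal_loci
#' @export
planted_panel <- function(genome) genome$panel

#' @rdname planted_fetal_loci
#' @export
genome_annotation <- function(genome) genome$annotation

#' Extract reference sequence where the model stores it
#'
#' The toy genome stores sequence only around the planted fetal-specific
#' loci (motif flanks); elsewhere `NA` is returned.
#'
#' @param genome a [genome_model()].
#' @param chrom,start,end 0-based half-open query interval.
#' @return character sequence or `NA` if not covered.
#' @export
get_reference_sequence <- function(genome, chrom, start, end) {
  r <- genome$ref_seq
  hit <- which(r$chrom == chrom & r$start <= start & r$end >= end)
  if (!length(hit)) return(NA_character_)
  substr(r$seq[hit[1]], start - r$start[hit[1]] + 1L, end - r$start[hit[1]])
}
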