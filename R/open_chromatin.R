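#' Direction of strict monotonicity across fetal-fraction tiers
#'
#' Low-level kernel of the monotonic filter: given a `tiers x positions`
#' matrix of normalized depths (tier fetal fractions increasing down the
#' rows), returns an integer code per position: `-1` strictly decreasing
#' with fetal fraction (`down_with_ff`), `1` strictly increasing
#' (`up_with_ff`), `0` otherwise. Magnitude of the change is ignored.
#'
#' @param mat numeric matrix, tiers in rows (increasing ff), positions in
#'   columns.
#' @return integer vector of direction codes, one per column.
#' @export
monotone_direction <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  dn <- rep(TRUE, ncol(mat)); up <- rep(TRUE, ncol(mat))
  for (i in seq_len(nrow(mat) - 1L)) {
    dn <- dn & mat[i, ] > mat[i + 1L, ]
    up <- up & mat[i, ] < mat[i + 1L, ]
  }
  ifelse(dn, -1L, ifelse(up, 1L, 0L))
}

#' Monotonic per-base filter across fetal-fraction tiers
#'
#' Scans the merged tier libraries (typically four, at mean fetal fractions
#' of 5/10/15/20%) and keeps positions whose total-read-normalized depth is
#' strictly monotone across tiers, recording the direction. This is the
#' dimensionality-reduction filter of the open-chromatin scan: a coverage
#' dip that deepens as fetal fraction rises marks a candidate fetal
#' nucleosome-depleted region.
#'
#' @param tiers list of `group_library` objects with strictly increasing
#'   `mean_ff` and equal `n_samples`.
#' @param chrom_sizes named integer vector.
#' @param chroms chromosomes to scan (default all).
#' @param mode depth mode (default `"coverage"`).
#' @return data.frame with `chrom`, `pos` (0-based), `direction`
#'   (`"down_with_ff"` / `"up_with_ff"`), raw extreme-tier counts `x1`,
#'   `x4`, and normalized extreme-tier depths `n1`, `n4`.
#' @export
monotonic_filter <- function(tiers, chrom_sizes, chroms = NULL,
                             mode = "coverage") {
  ffs <- vapply(tiers, `[[`, 0, "mean_ff")
  if (any(diff(ffs) <= 0)) stop("tier fetal fractions must be strictly increasing")
  ns <- vapply(tiers, `[[`, 0, "n_samples")
  if (length(unique(ns)) != 1L) stop("tiers must contain equal sample counts")
  totals <- vapply(tiers, `[[`, 0, "total_reads")
  nf <- mean(totals) / totals
  if (is.null(chroms)) chroms <- names(chrom_sizes)
  out <- list()
  for (ch in chroms) {
    L <- chrom_sizes[[ch]]
    raw <- lapply(tiers, function(g) {
      if (!is.null(g$track)) return(g$track$counts[[ch]])
      fr <- g$fragments[g$fragments$chrom == ch, , drop = FALSE]
      if (!nrow(fr)) return(numeric(L))
      if (mode == "read_start") return(as.numeric(tabulate(fr$start + 1L, nbins = L)))
      cumsum(tabulate(fr$start + 1L, nbins = L) - tabulate(fr$end + 1L, nbins = L))
    })
    norm <- mapply(function(v, f) v * f, raw, nf, SIMPLIFY = FALSE)
    dir <- monotone_direction(do.call(rbind, norm))
    keep <- which(dir != 0L)
    if (!length(keep)) next
    out[[ch]] <- data.frame(
      chrom = ch, pos = keep - 1L,
      direction = ifelse(dir[keep] < 0L, "down_with_ff", "up_with_ff"),
      x1 = raw[[1L]][keep], x4 = raw[[length(raw)]][keep],
      n1 = norm[[1L]][keep], n4 = norm[[length(norm)]][keep],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0), direction = character(0),
               x1 = numeric(0), x4 = numeric(0), n1 = numeric(0), n4 = numeric(0))
  rownames(res) <- NULL
  res
}

# exact two-sided conditional binomial p-value (binom.test convention):
# sum of outcome probabilities not exceeding that of the observation
cond_binom_p <- function(x, n, p0) {
  if (n == 0) return(NA_real_)
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}

#' Differential coverage between two merged libraries
#'
#' RNA-seq-style count test reduced to the replicate-free two-library case:
#' conditional on the position total `x1 + x2`, `x1` is Binomial with
#' success probability `t1 / (t1 + t2)` under the null of equal normalized
#' coverage; the exact two-sided p-value is computed per position and
#' Benjamini-Hochberg-adjusted over the tested set. The fold change is the
#' normalized ratio `(x2/t2) / (x1/t1)`. Positions with `x1 + x2 = 0` are
#' dropped (count recorded in the `"n_dropped"` attribute).
#'
#' @param x1,x2 raw counts per position in library 1 and 2 (for the tier
#'   scan: lowest and highest fetal-fraction tier).
#' @param t1,t2 library total read counts.
#' @return data.frame with `x1`, `x2`, `fold_change`, `p`, `adj_p` for the
#'   retained positions (attribute `"keep"` maps rows to input positions).
#' @export
differential_coverage <- function(x1, x2, t1, t2) {
  stopifnot(length(x1) == length(x2), t1 > 0, t2 > 0)
  n <- x1 + x2
  keep <- which(n > 0)
  p0 <- t1 / (t1 + t2)
  p <- vapply(keep, function(i) cond_binom_p(x1[i], n[i], p0), 0)
  out <- data.frame(x1 = x1[keep], x2 = x2[keep],
                    fold_change = (x2[keep] / t2) / (x1[keep] / t1),
                    p = p, adj_p = stats::p.adjust(p, "BH"))
  attr(out, "keep") <- keep
  attr(out, "n_dropped") <- length(x1) - length(keep)
  out
}

#' Chain candidate positions into 25 bp window runs
#'
#' Each candidate position `p` spawns a window `[p - flank, p + flank + 1)`
#' (25 bp at the default 12 bp flank). Windows that overlap or abut chain
#' into runs; a run's interval is the union of its member windows and its
#' size is counted in member windows (one per candidate position). Runs
#' with at least `min_windows` windows are returned — the empirical
#' screeplot cut of the window-size distribution.
#'
#' @param candidates data.frame from [monotonic_filter()] (needs `chrom`,
#'   `pos`, `direction`).
#' @param chrom_sizes named integer vector (window clipping).
#' @param flank per-side flank in bp (default 12).
#' @param min_windows minimum run size in windows (default 5).
#' @param direction which monotone direction to keep (default
#'   `"down_with_ff"`: deeper dips at higher fetal fraction, the
#'   open-chromatin signature).
#' @param restrict optional interval data.frame; candidates outside it are
#'   discarded first (e.g. an intersection with fetal-specific regions).
#'   `NULL` (default) applies no restriction.
#' @return data.frame with `chrom`, `start`, `end`, `n_windows`,
#'   `direction`.
#' @export
window_runs <- function(candidates, chrom_sizes, flank = 12L, min_windows = 5L,
                        direction = "down_with_ff", restrict = NULL) {
  cand <- candidates[candidates$direction == direction, , drop = FALSE]
  if (!is.null(restrict) && nrow(cand)) {
    inside <- rep(FALSE, nrow(cand))
    for (ch in unique(restrict$chrom)) {
      r <- restrict[restrict$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      sel <- cand$chrom == ch
      brk <- as.vector(rbind(r$start, r$end))
      inside[sel] <- findInterval(cand$pos[sel], brk) %% 2L == 1L
    }
    cand <- cand[inside, , drop = FALSE]
  }
  out <- list()
  for (ch in unique(cand$chrom)) {
    p <- sort(cand$pos[cand$chrom == ch])
    # windows [p-flank, p+flank+1) chain when gaps <= window width
    brk <- c(0L, which(diff(p) > 2L * flank + 1L), length(p))
    for (j in seq_len(length(brk) - 1L)) {
      run <- p[(brk[j] + 1L):brk[j + 1L]]
      if (length(run) < min_windows) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = max(0L, run[1L] - flank),
        end = min(chrom_sizes[[ch]], run[length(run)] + flank + 1L),
        n_windows = length(run), direction = direction,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_windows = integer(0), direction = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collect genes downstream of window runs
#'
#' A gene is collected when a run overlaps its strand-aware TSS-upstream
#' window: `[TSS - max_distance, TSS)` on `+`, `(TSS, TSS + max_distance]`
#' on `-`. The de-duplicated union over runs is returned.
#'
#' @param runs data.frame with `chrom`, `start`, `end`.
#' @param annotation gene annotation (see [read_annotation()] /
#'   [genome_annotation()]).
#' @param max_distance upstream window size in bp (default 10 kb).
#' @return character vector of collected `gene_id`s.
#' @export
map_downstream_genes <- function(runs, annotation, max_distance = 10000L) {
  if (!nrow(annotation) || !nrow(runs)) return(character(0))
  win_start <- ifelse(annotation$strand == "+",
                      pmax(0L, annotation$tss - max_distance), annotation$tss + 1L)
  win_end <- ifelse(annotation$strand == "+",
                    annotation$tss, annotation$tss + 1L + max_distance)
  hit <- rep(FALSE, nrow(annotation))
  for (ch in unique(runs$chrom)) {
    r <- runs[runs$chrom == ch, , drop = FALSE]
    o <- order(r$start)
    rs <- r$start[o]
    re_cummax <- cummax(r$end[o])
    g <- which(annotation$chrom == ch)
    if (!length(g)) next
    # overlap exists iff some run has start < win_end and cummax(end) > win_start
    j <- findInterval(win_end[g] - 1e-9, rs)
    ok <- j > 0L
    ok[ok] <- re_cummax[j[ok]] > win_start[g][ok]
    hit[g] <- ok
  }
  unique(annotation$gene_id[hit])
}

#' Hypergeometric gene-set enrichment
#'
#' Internal replacement for web-service enrichment: for each term with
#' background count `K` out of a background of size `M`, the upper-tail
#' hypergeometric p-value of observing `k` of the `N` mapped input genes.
#' `N` is the number of input genes mapped to at least one term;
#' `Overlap% = 100 k / N`. Terms with `K = 0` are skipped; p-values are
#' BH-adjusted.
#'
#' @param genes character vector of input gene ids (subset of the
#'   background).
#' @param term_sets named list: term id -> character vector of member
#'   genes.
#' @param background character vector of all assayable gene ids.
#' @return data.frame with `term_id`, `gene_count` (k), `list_size` (N),
#'   `background_count` (K), `background_size` (M), `overlap_pct`,
#'   `p_value`, `adj_p`, sorted by p-value.
#' @export
enrich_terms <- function(genes, term_sets, background) {
  genes <- unique(genes)
  if (length(setdiff(genes, background)))
    stop("input genes must be a subset of the background")
  M <- length(unique(background))
  mapped <- unique(unlist(lapply(term_sets, intersect, x = genes)))
  N <- length(mapped)
  rows <- lapply(names(term_sets), function(tid) {
    members <- intersect(term_sets[[tid]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(genes, members))
    data.frame(term_id = tid, gene_count = k, list_size = N,
               background_count = K, background_size = M,
               overlap_pct = if (N > 0) 100 * k / N else NA_real_,
               p_value = stats::phyper(k - 1L, K, M - K, N, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term_id = character(0), gene_count = integer(0),
                      list_size = integer(0), background_count = integer(0),
                      background_size = integer(0), overlap_pct = numeric(0),
                      p_value = numeric(0), adj_p = numeric(0)))
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer the enrichment-list denominator from a reported summary row
#'
#' Published enrichment tables report per-term gene counts and
#' `Overlap% = 100 k / N` without printing the mapped-list size `N`;
#' given one row, `N = round(100 k / pct)` recovers it exactly when the
#' percentages were computed from integer counts.
#'
#' @param gene_count reported per-term gene count `k`.
#' @param overlap_pct reported overlap percentage.
#' @return inferred integer list size `N`.
#' @export
infer_list_size <- function(gene_count, overlap_pct) {
  as.integer(round(100 * gene_count / overlap_pct))
}
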