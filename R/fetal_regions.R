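#' Merge samples into fetal-fraction strata
#'
#' Samples are sorted by fetal fraction (chrY-dosage estimate when present,
#' otherwise the known/true value) and split into `n_groups` equal-size
#' strata, mirroring the 40-group stratification of the discovery design.
#' Each stratum keeps its pooled fragments; the merged depth track is
#' computed on demand by [group_depth()].
#'
#' @param samples list of fragment data.frames, one per library.
#' @param meta metadata data.frame aligned with `samples` (needs `ff_chrY`
#'   and/or `true_ff`, and `total_reads`).
#' @param n_groups number of strata; must not exceed the number of samples.
#' @return list of `group_library` objects ordered by increasing mean
#'   fetal fraction.
#' @export
merge_groups <- function(samples, meta, n_groups) {
  stopifnot(length(samples) == nrow(meta))
  if (n_groups > length(samples))
    stop("n_groups (", n_groups, ") exceeds number of samples (", length(samples), ")")
  ff <- meta$ff_chrY
  if (is.null(ff)) ff <- rep(NA_real_, nrow(meta))
  if (!is.null(meta$true_ff)) ff[is.na(ff)] <- meta$true_ff[is.na(ff)]
  if (anyNA(ff)) stop("every sample needs ff_chrY or true_ff for stratification")
  o <- order(ff)
  bins <- ceiling(seq_along(o) / (length(o) / n_groups))
  lapply(seq_len(n_groups), function(g) {
    idx <- o[bins == g]
    frags <- as.data.frame(data.table::rbindlist(samples[idx]))
    structure(list(group_label = sprintf("g%02d", g),
                   mean_ff = mean(ff[idx]), n_samples = length(idx),
                   fragments = frags,
                   total_reads = sum(meta$total_reads[idx]),
                   sample_ids = meta$sample_id[idx]),
              class = "group_library")
  })
}

#' Merged depth track of a stratum
#'
#' @param group a `group_library` from [merge_groups()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param mode `"coverage"` or `"read_start"`.
#' @return raw [depth_track()] of the pooled fragments.
#' @export
group_depth <- function(group, chrom_sizes, mode = "coverage") {
  accumulate_depth(group$fragments, chrom_sizes, mode = mode,
                   total_reads = group$total_reads)
}

#' Wrap a depth track as a stratum
#'
#' Builds a `group_library`-compatible object directly from a depth track
#' (e.g. a noiseless [expected_depth_track()]), so [scan_fetal_regions()]
#' and [monotonic_filter()] can run on analytic expectations as well as on
#' pooled fragments.
#'
#' @param track a [depth_track()].
#' @param mean_ff the stratum's mean fetal fraction.
#' @param group_label label.
#' @param n_samples member count (metadata only).
#' @return a `group_library` backed by the track.
#' @export
group_from_track <- function(track, mean_ff, group_label = "g1", n_samples = 1L) {
  structure(list(group_label = group_label, mean_ff = mean_ff,
                 n_samples = n_samples, track = track,
                 total_reads = track$total_reads),
            class = "group_library")
}

#' @export
print.group_library <- function(x, ...) {
  cat("<group_library> ", x$group_label, ": ", x$n_samples, " samples, mean ff ",
      sprintf("%.4f", x$mean_ff), ", ", format(x$total_reads, big.mark = ","),
      " reads\n", sep = "")
  invisible(x)
}

#' Per-base regression of depth on group fetal fraction
#'
#' Ordinary least squares of one position's per-group depths on the group
#' mean fetal fractions. The fitted-error statistic is the relative residual
#' `|obs - fit| / fit`, either its maximum over groups (default) or its
#' mean; it is undefined (position flagged not-evaluable) when any fitted
#' value is non-positive or all depths are zero.
#'
#' @param depths numeric vector of per-group (normalized) depths at one base.
#' @param ffs strictly increasing vector of group mean fetal fractions.
#' @param error_type `"max"` or `"mean"` relative residual.
#' @return list with `slope`, `intercept`, `rel_error`, `fitted`, `evaluable`.
#' @export
fit_position <- function(depths, ffs, error_type = c("max", "mean")) {
  error_type <- match.arg(error_type)
  stopifnot(length(depths) == length(ffs), length(ffs) >= 3,
            all(diff(ffs) > 0))
  if (all(depths == 0))
    return(list(slope = 0, intercept = 0, rel_error = NA_real_,
                fitted = rep(0, length(ffs)), evaluable = FALSE))
  xc <- ffs - mean(ffs)
  slope <- sum(xc * depths) / sum(xc^2)
  intercept <- mean(depths) - slope * mean(ffs)
  fitted <- intercept + slope * ffs
  if (any(fitted <= 0))
    return(list(slope = slope, intercept = intercept, rel_error = NA_real_,
                fitted = fitted, evaluable = FALSE))
  rel <- abs(depths - fitted) / fitted
  list(slope = slope, intercept = intercept,
       rel_error = if (error_type == "max") max(rel) else mean(rel),
       fitted = fitted, evaluable = TRUE)
}

# merge maximal runs of consecutive qualifying positions into intervals
merge_qualifying_runs <- function(chrom, pos, qualify, min_raw = NULL) {
  out <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]
    q <- qualify[sel]
    mr <- if (is.null(min_raw)) rep(NA_real_, sum(sel)) else min_raw[sel]
    o <- order(p)
    p <- p[o]; q <- q[o]; mr <- mr[o]
    qi <- which(q)
    if (!length(qi)) next
    # runs of consecutive (adjacent) qualifying positions
    brk <- c(0L, which(diff(p[qi]) != 1L), length(qi))
    for (j in seq_len(length(brk) - 1L)) {
      run <- qi[(brk[j] + 1L):brk[j + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = p[run[1L]], end = p[run[length(run)]] + 1L,
        min_raw = min(mr[run]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), min_raw = numeric(0)))
  res <- do.call(rbind, out)
  res[order(match(res$chrom, unique(chrom)), res$start), , drop = FALSE]
}

#' Call fetal-specific regions from a stream of position fits
#'
#' A position qualifies when its fitted error is below `max_rel_error`
#' (1.5% by default), its slope is positive (when required), and its minimum
#' raw merged depth across groups is at least `min_reads`. Maximal runs of
#' consecutive qualifying positions are merged into regions.
#'
#' @param fits data.frame with columns `chrom`, `pos` (0-based), `slope`,
#'   `rel_error`, `evaluable`, `min_raw` (minimum raw depth across groups).
#' @param max_rel_error fitted-error threshold (default 0.015).
#' @param min_reads minimum raw depth across groups (default 2).
#' @param require_positive_slope exclude constant/decreasing tracks
#'   (default TRUE): a fetal-origin region must gain depth with fetal
#'   fraction.
#' @return `fetal_region_set`: list with `regions` (chrom/start/end/min_raw)
#'   and the calling parameters.
#' @export
call_fetal_regions <- function(fits, max_rel_error = 0.015, min_reads = 2,
                               require_positive_slope = TRUE) {
  qualify <- fits$evaluable & !is.na(fits$rel_error) &
    fits$rel_error < max_rel_error & fits$min_raw >= min_reads
  if (require_positive_slope) qualify <- qualify & fits$slope > 0
  regions <- merge_qualifying_runs(fits$chrom, fits$pos, qualify, fits$min_raw)
  structure(list(regions = regions,
                 params = list(max_rel_error = max_rel_error,
                               min_reads = min_reads,
                               require_positive_slope = require_positive_slope)),
            class = "fetal_region_set")
}

#' @export
print.fetal_region_set <- function(x, ...) {
  cat("<fetal_region_set> ", nrow(x$regions), " regions, ",
      sum(x$regions$end - x$regions$start), " bp total\n", sep = "")
  invisible(x)
}

#' Genome-wide fetal-specific region scan
#'
#' Streams the per-base depth-on-fetal-fraction regression over whole
#' chromosomes for a set of merged strata and calls qualifying runs. Depths
#' are normalized to the mean group total for the regression; the
#' `min_reads` rule uses raw merged depth.
#'
#' Two optional noise-aware settings adapt the literal fitted-error rule to
#' scaled-down (counting-noise-dominated) depth: `noise_z` widens the
#' acceptance band around the fitted line to
#' `max_rel_error * fit + noise_z * sqrt(fit)` (Poisson allowance), and
#' `slope_alpha` additionally requires the slope to be significantly
#' positive (one-sided t-test). Both default to off, which reproduces the
#' literal rule exactly.
#'
#' @param groups list of `group_library` (see [merge_groups()]), increasing
#'   mean fetal fraction.
#' @param chrom_sizes named integer vector.
#' @param chroms chromosomes to scan (default: all; chrY-anchor mode is
#'   `chroms = "chrY"`).
#' @param mode depth mode, `"coverage"` (default) or `"read_start"`.
#' @inheritParams call_fetal_regions
#' @param error_type `"max"` or `"mean"` relative residual.
#' @param noise_z optional Poisson allowance multiplier (e.g. 4).
#' @param slope_alpha optional one-sided p-value threshold for slope > 0.
#' @return `fetal_region_set` with per-region minimum raw depth.
#' @export
scan_fetal_regions <- function(groups, chrom_sizes, chroms = NULL,
                               mode = "coverage", max_rel_error = 0.015,
                               min_reads = 2, require_positive_slope = TRUE,
                               error_type = c("max", "mean"),
                               noise_z = NULL, slope_alpha = NULL) {
  error_type <- match.arg(error_type)
  G <- length(groups)
  stopifnot(G >= 3)
  ffs <- vapply(groups, `[[`, 0, "mean_ff")
  if (any(diff(ffs) <= 0)) stop("group mean fetal fractions must be strictly increasing")
  totals <- vapply(groups, `[[`, 0, "total_reads")
  nf <- mean(totals) / totals  # normalize to mean group total
  if (is.null(chroms)) chroms <- names(chrom_sizes)
  xc <- ffs - mean(ffs)
  sxx <- sum(xc^2)
  # pre-split fragment coordinates by chromosome for cheap repeated passes;
  # track-backed groups (e.g. noiseless expected tracks) read counts directly
  split_frags <- lapply(groups, function(g) {
    if (!is.null(g$track)) return(NULL)
    f <- factor(g$fragments$chrom, levels = chroms)
    list(start = split(g$fragments$start, f), end = split(g$fragments$end, f))
  })
  chrom_cov <- function(g, ch) {
    if (!is.null(groups[[g]]$track)) return(groups[[g]]$track$counts[[ch]])
    L <- chrom_sizes[[ch]]
    s <- split_frags[[g]]$start[[ch]]
    if (!length(s)) return(numeric(L))
    if (mode == "read_start") return(as.numeric(tabulate(s + 1L, nbins = L)))
    cumsum(tabulate(s + 1L, nbins = L) -
             tabulate(split_frags[[g]]$end[[ch]] + 1L, nbins = L))
  }
  region_list <- list()
  for (ch in chroms) {
    L <- chrom_sizes[[ch]]
    sum_d <- numeric(L); sum_xd <- numeric(L)
    min_raw <- rep(Inf, L); all_zero <- rep(TRUE, L)
    for (g in seq_len(G)) {   # pass 1: sufficient statistics
      cv <- chrom_cov(g, ch)
      min_raw <- pmin(min_raw, cv)
      all_zero <- all_zero & cv == 0
      sum_d <- sum_d + cv * nf[g]
      sum_xd <- sum_xd + xc[g] * (cv * nf[g])
    }
    slope <- sum_xd / sxx
    intercept <- sum_d / G - slope * mean(ffs)
    # residual diagnostics are only needed where the cheap gates can pass
    cand <- which(min_raw >= min_reads & !all_zero &
                    (!require_positive_slope | slope > 0))
    if (!length(cand)) next
    slope_c <- slope[cand]; int_c <- intercept[cand]
    nc <- length(cand)
    rel_max <- numeric(nc); rel_sum <- numeric(nc); rss <- numeric(nc)
    band_ok <- rep(TRUE, nc); fit_pos <- rep(TRUE, nc)
    for (g in seq_len(G)) {   # pass 2: residuals at candidate positions
      fit <- int_c + slope_c * ffs[g]
      fit_pos <- fit_pos & fit > 0
      res <- abs(chrom_cov(g, ch)[cand] * nf[g] - fit)
      rss <- rss + res^2
      rel <- res / fit
      rel_max <- pmax(rel_max, rel)
      rel_sum <- rel_sum + rel
      if (!is.null(noise_z))
        band_ok <- band_ok & res <= max_rel_error * fit + noise_z * sqrt(pmax(fit, 0))
    }
    rel_error <- if (error_type == "max") rel_max else rel_sum / G
    qualify <- fit_pos &
      if (is.null(noise_z)) rel_error < max_rel_error else band_ok
    if (require_positive_slope && !is.null(slope_alpha)) {
      se <- sqrt(pmax(rss, 0) / (G - 2) / sxx)
      tval <- ifelse(se > 0, slope_c / se, ifelse(slope_c > 0, Inf, -Inf))
      qualify <- qualify & stats::pt(tval, df = G - 2, lower.tail = FALSE) < slope_alpha
    }
    qi <- cand[qualify]
    if (length(qi))
      region_list[[ch]] <- merge_qualifying_runs(rep(ch, length(qi)), qi - 1L,
                                                 rep(TRUE, length(qi)), min_raw[qi])
  }
  regions <- if (length(region_list)) do.call(rbind, region_list) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               min_raw = numeric(0))
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 params = list(max_rel_error = max_rel_error, min_reads = min_reads,
                               require_positive_slope = require_positive_slope,
                               error_type = error_type, noise_z = noise_z,
                               slope_alpha = slope_alpha, mode = mode)),
            class = "fetal_region_set")
}

#' Position weight matrix of region flanks
#'
#' Collects the `flank`-bp sequence upstream (default) or downstream of each
#' region, counts per-position base frequencies and derives the consensus
#' (column argmax, ties broken in A,C,G,T order). Regions whose flank has no
#' stored reference sequence or falls off the chromosome are skipped with a
#' warning.
#'
#' @param regions interval data.frame (or `fetal_region_set`).
#' @param genome a [genome_model()] supplying reference sequence.
#' @param flank flank width in bp (default 50).
#' @param side `"upstream"` or `"downstream"`.
#' @return object of class `pwm`: list with `mat` (4 x flank frequency
#'   matrix, rows A,C,G,T), `consensus`, `n_seqs`.
#' @export
build_flank_pwm <- function(regions, genome, flank = 50L, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  if (inherits(regions, "fetal_region_set")) regions <- regions$regions
  seqs <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(regions))) {
    s <- if (side == "upstream") regions$start[i] - flank else regions$end[i]
    e <- s + flank
    sq <- if (s < 0 || e > genome$chrom_sizes[[regions$chrom[i]]]) NA_character_
          else get_reference_sequence(genome, regions$chrom[i], s, e)
    if (is.na(sq)) skipped <- skipped + 1L else seqs <- c(seqs, sq)
  }
  if (skipped) warning(skipped, " region flank(s) without reference sequence skipped")
  if (!length(seqs)) stop("no flank sequences available")
  pwm_from_sequences(seqs)
}

#' Build a PWM from aligned equal-length sequences
#'
#' @param seqs character vector of equal-length A/C/G/T sequences.
#' @return a `pwm` object (see [build_flank_pwm()]); columns sum to 1.
#' @export
pwm_from_sequences <- function(seqs) {
  W <- unique(nchar(seqs))
  if (length(W) != 1L) stop("sequences must have equal length")
  m <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  cnt <- vapply(seq_len(W), function(j) {
    tab <- table(factor(m[, j], levels = bases))
    as.numeric(tab)
  }, numeric(4))
  rownames(cnt) <- bases
  freq <- sweep(cnt, 2, colSums(cnt), "/")
  consensus <- paste(bases[apply(freq, 2, which.max)], collapse = "")
  structure(list(mat = freq, consensus = consensus, n_seqs = length(seqs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", ncol(x$mat), " columns from ", x$n_seqs, " sequences\n",
      "  consensus: ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' Write a PWM as TSV (4 rows A,C,G,T) plus a consensus comment line
#'
#' @param pwm a `pwm` object.
#' @param path output path.
#' @export
write_pwm <- function(pwm, path) {
  lines <- c(paste0("# consensus\t", pwm$consensus),
             vapply(rownames(pwm$mat), function(b)
               paste(c(b, sprintf("%.17g", pwm$mat[b, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Detect maximal exact tandem repeats in a consensus string
#'
#' Reports every left-maximal exact tandem repeat with unit length at least
#' `unit_min` and at least `min_copies` complete copies: `(unit, copies,
#' offset)` with a 0-based offset. A stretch `s[o..o+c*u)` qualifies when it
#' is periodic with period `u` and cannot be extended one position to the
#' left with the same period.
#'
#' @param consensus non-empty A/C/G/T (or any character) string.
#' @param unit_min minimum repeat-unit length (default 3).
#' @param min_copies minimum number of complete copies (default 2).
#' @return data.frame with `unit`, `copies`, `offset`, `unit_len`.
#' @export
detect_tandem_repeat <- function(consensus, unit_min = 3L, min_copies = 2L) {
  stopifnot(nchar(consensus) > 0)
  ch <- strsplit(consensus, "")[[1]]
  n <- length(ch)
  res <- list()
  for (u in seq.int(unit_min, max(unit_min, n %/% 2))) {
    if (2L * u > n) break
    eq <- ch[seq_len(n - u)] == ch[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      copies <- r$lengths[j] %/% u + 1L
      if (copies < min_copies) next
      a <- starts[j]
      res[[length(res) + 1L]] <- data.frame(
        unit = substr(consensus, a, a + u - 1L), copies = copies,
        offset = a - 1L, unit_len = u, stringsAsFactors = FALSE)
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
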