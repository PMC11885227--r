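#' Paired case/control coverage profile within a viewport
#'
#' Rescales each (already total-read-normalized) profile to unit mean
#' within the viewing area — alleviating different numerical baselines —
#' and smooths both with a centered running mean (window truncated at the
#' viewport edges). Output is a per-base table for plotting or scanning.
#'
#' @param case_track,control_track normalized [depth_track()]s.
#' @param viewport one-row interval data.frame (`chrom`, `start`, `end`).
#' @param smooth_window running-mean window in bp (default 50).
#' @return data.frame with `pos` (0-based), `case`, `control`.
#' @export
profile_contrast <- function(case_track, control_track, viewport,
                             smooth_window = 50L) {
  stopifnot(nrow(viewport) == 1L)
  idx <- (viewport$start + 1L):viewport$end
  get <- function(tr) {
    v <- tr$counts[[viewport$chrom]][idx]
    if (sum(v) == 0) stop("viewport has zero total depth in one track")
    v / mean(v)
  }
  smooth <- function(v) {
    half <- smooth_window %/% 2L
    n <- length(v)
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  data.frame(pos = idx - 1L,
             case = smooth(get(case_track)),
             control = smooth(get(control_track)))
}

#' Build a phenotype loci panel from a binary case/control contrast
#'
#' Scans a set of candidate windows (typically promoter windows around
#' annotated TSSs) with the same conditional-binomial count test as the
#' tier scan, in a binary case-versus-control contrast. BH-significant
#' windows are assigned to the up set (higher case coverage) or down set
#' (lower case coverage) by fold-change sign.
#'
#' @param case_group,control_group `group_library` objects (merged case and
#'   control libraries).
#' @param windows candidate interval data.frame (non-overlapping).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return object of class `loci_panel`: `up_regions`, `down_regions`
#'   (interval data.frames) and the per-window `stats` table.
#' @export
build_panel <- function(case_group, control_group, windows, alpha = 0.05) {
  x_case <- count_region_reads(case_group$fragments, windows)
  x_ctrl <- count_region_reads(control_group$fragments, windows)
  dc <- differential_coverage(x_ctrl, x_case,
                              t1 = control_group$total_reads,
                              t2 = case_group$total_reads)
  keep <- attr(dc, "keep")
  stats_tab <- cbind(windows[keep, c("chrom", "start", "end"), drop = FALSE],
                     x_control = dc$x1, x_case = dc$x2,
                     fold_change = dc$fold_change, p = dc$p, adj_p = dc$adj_p)
  rownames(stats_tab) <- NULL
  sig <- stats_tab$adj_p <= alpha
  up <- stats_tab[sig & stats_tab$fold_change > 1, c("chrom", "start", "end")]
  down <- stats_tab[sig & stats_tab$fold_change < 1, c("chrom", "start", "end")]
  rownames(up) <- rownames(down) <- NULL
  structure(list(up_regions = up, down_regions = down, stats = stats_tab,
                 alpha = alpha),
            class = "loci_panel")
}

#' @export
print.loci_panel <- function(x, ...) {
  cat("<loci_panel> ", nrow(x$up_regions), " up regions, ",
      nrow(x$down_regions), " down regions (BH alpha ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Signed sum over a loci panel
#'
#' `S = sum(up counts) - sum(down counts)`: counts in regions with higher
#' case coverage add, counts in regions with lower case coverage subtract,
#' so opposite-direction effects reinforce instead of cancel.
#'
#' @param up,down numeric count vectors over the panel's up and down
#'   regions (normalized counts-per-million within sample; see
#'   [panel_signed_sums()]).
#' @return the signed sum.
#' @export
signed_sum <- function(up, down = numeric(0)) sum(up) - sum(down)

#' Per-sample signed sums over a panel
#'
#' Counts fragment starts in the panel regions and forms the signed sum on
#' counts-per-million within each sample (raw sums would confound library
#' size with phenotype).
#'
#' @param samples list of fragment data.frames.
#' @param panel a `loci_panel`.
#' @param total_reads per-sample library sizes (defaults to fragment
#'   counts).
#' @return numeric vector of signed sums, one per sample.
#' @export
panel_signed_sums <- function(samples, panel,
                              total_reads = vapply(samples, nrow, 0L)) {
  n_up <- nrow(panel$up_regions)
  regions <- rbind(panel$up_regions, panel$down_regions)
  vapply(seq_along(samples), function(i) {
    y <- count_region_reads(samples[[i]], regions) / total_reads[i] * 1e6
    signed_sum(y[seq_len(n_up)], y[-seq_len(n_up)])
  }, 0)
}

#' Score a cohort against a reference model
#'
#' Standardizes each sample's signed sum against a reference set — the
#' entire cohort taken blindly (default; robust to a small contaminating
#' case fraction and preserving relative ranking) or labeled controls only
#' — then applies the reporting adjustment `adjusted = max(0, z + shift)`.
#'
#' @param S numeric vector of per-sample signed sums.
#' @param sample_id identifiers (default `s1..sn`).
#' @param reference `"blind_all"` or `"labeled_controls"`.
#' @param labels condition labels (needed for `"labeled_controls"`).
#' @param shift reporting shift (default 4).
#' @return data.frame with `sample_id`, `S`, `z`, `adjusted`.
#' @export
score_cohort <- function(S, sample_id = sprintf("s%04d", seq_along(S)),
                         reference = c("blind_all", "labeled_controls"),
                         labels = NULL, shift = 4) {
  reference <- match.arg(reference)
  ref <- if (reference == "blind_all") S else {
    if (is.null(labels)) stop("labels required for labeled_controls reference")
    S[labels == "control"]
  }
  mu <- mean(ref)
  sigma <- stats::sd(ref)
  if (is.na(sigma) || sigma == 0) stop("degenerate reference: sigma is 0")
  z <- (S - mu) / sigma
  data.frame(sample_id = sample_id, S = S, z = z,
             adjusted = pmax(0, z + shift), stringsAsFactors = FALSE)
}

#' Call samples above an empirical score quantile
#'
#' The threshold is the empirical `q`-quantile of the adjusted scores
#' (order-statistic quantile with linear interpolation, `type = 7`;
#' configurable because tie handling near the threshold changes the number
#' of exceedances); a sample is called when its adjusted score strictly
#' exceeds the threshold.
#'
#' @param scores data.frame from [score_cohort()] (or a numeric vector of
#'   adjusted scores).
#' @param q quantile level (default 0.99).
#' @param type quantile type passed to [stats::quantile()].
#' @return list with `called` (logical), `threshold`.
#' @export
call_by_quantile <- function(scores, q = 0.99, type = 7) {
  adj <- if (is.data.frame(scores)) scores$adjusted else scores
  thr <- unname(stats::quantile(adj, q, type = type))
  list(called = adj > thr, threshold = thr)
}

#' Positive predictive value of called samples
#'
#' Among called samples, outcomes may be unknown (lost to follow-up);
#' unknowns are excluded from the denominator. For each observed outcome
#' label, `PPV = confirmed / evaluable`.
#'
#' @param called logical vector of calls.
#' @param outcomes character vector of confirmed outcome labels, `NA` for
#'   lost to follow-up, `"none"` (or any other label) for no finding.
#' @return list with `n_called`, `n_evaluable`, and `ppv` (data.frame per
#'   outcome label: `outcome`, `confirmed`, `evaluable`, `ppv`). With zero
#'   evaluable samples the PPV is `NA` (undefined).
#' @export
evaluate_ppv <- function(called, outcomes) {
  stopifnot(length(called) == length(outcomes))
  ev <- called & !is.na(outcomes)
  labs <- setdiff(unique(outcomes[ev]), "none")
  ppv <- if (length(labs)) data.frame(
    outcome = labs,
    confirmed = vapply(labs, function(l) sum(outcomes[ev] == l), 0L),
    evaluable = sum(ev),
    ppv = vapply(labs, function(l) sum(outcomes[ev] == l) / sum(ev), 0),
    stringsAsFactors = FALSE)
  else data.frame(outcome = character(0), confirmed = integer(0),
                  evaluable = integer(0), ppv = numeric(0))
  rownames(ppv) <- NULL
  list(n_called = sum(called), n_evaluable = sum(ev),
       ppv = if (sum(ev) == 0) NA else ppv)
}
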