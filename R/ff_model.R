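#' Conventional chrY-dosage fetal fraction estimate
#'
#' For a male fetus the chrY read share interpolates linearly between a
#' female-background share `b_female` and a pure-fetal share `b_male`:
#' `ff = (f_obs - b_female) / (b_male - b_female)`, clamped to `[0, 1]`.
#' Calibration shares come from the cohort's own background (for the
#' synthetic world, [chry_calibration()]).
#'
#' @param x fragment data.frame or a [depth_track()] (read-start mode).
#' @param calib numeric `c(b_female=, b_male=)` with `b_female < b_male`.
#' @return fetal fraction in `[0, 1]`.
#' @export
estimate_ff_chry <- function(x, calib) {
  bf <- calib[["b_female"]]; bm <- calib[["b_male"]]
  if (bm <= bf) stop("degenerate calibration: b_male must exceed b_female")
  f_obs <- if (inherits(x, "depth_track")) {
    tot <- sum(vapply(x$counts, sum, 0))
    if (tot == 0) stop("empty track")
    sum(x$counts[["chrY"]]) / tot
  } else {
    if (!nrow(x)) stop("no fragments")
    mean(x$chrom == "chrY")
  }
  min(1, max(0, (f_obs - bf) / (bm - bf)))
}

#' Count fragment starts per region
#'
#' `y_i` is the number of fragments whose start position lies inside region
#' `i` (start-based rule: a fragment spanning a boundary but starting
#' outside is not counted). Regions must be non-overlapping.
#'
#' @param fragments fragment data.frame.
#' @param regions interval data.frame (or `fetal_region_set`).
#' @return integer vector of counts, one per region (named by
#'   `chrom:start-end`).
#' @export
count_region_reads <- function(fragments, regions) {
  if (inherits(regions, "fetal_region_set")) regions <- regions$regions
  n <- nrow(regions)
  y <- integer(n)
  names(y) <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  for (ch in unique(regions$chrom)) {
    r <- which(regions$chrom == ch)
    o <- r[order(regions$start[r])]
    rs <- regions$start[o]; re <- regions$end[o]
    if (length(o) > 1L && any(rs[-1] < re[-length(re)]))
      stop("overlapping regions: ambiguous assignment")
    s <- fragments$start[fragments$chrom == ch]
    if (!length(s)) next
    # stab each start into the sorted region boundaries
    brk <- as.vector(rbind(rs, re))
    idx <- findInterval(s, brk)
    inside <- idx %% 2L == 1L
    hit <- tabulate((idx[inside] + 1L) %/% 2L, nbins = length(o))
    y[o] <- y[o] + hit
  }
  y
}

# OLS with minimum-norm fallback for rank-deficient designs
ols_coef <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    list(coef = drop(beta), flagged = TRUE)
  } else {
    list(coef = fit$coefficients, flagged = FALSE)
  }
}

#' Fit the region-count fetal fraction model by jackknife resampling
#'
#' The model is `ff = b0 + b1 y1 + ... + bn yn` over the per-region read
#' counts. Fitting minimizes the sum of squared fetal-fraction errors by
#' OLS; in each of `iterations` resampling rounds a random `holdout_fraction`
#' of samples is excluded, and the final coefficients are the elementwise
#' median over rounds (delete-d jackknife). Rank-deficient rounds fall back
#' to the minimum-norm solution and are counted in `n_flagged`.
#'
#' By default counts are normalized to counts-per-million within each
#' sample before fitting (libraries differ in depth); `normalize = "raw"`
#' uses raw counts.
#'
#' @param counts matrix of region counts, samples in rows.
#' @param ff known fetal fractions (training response).
#' @param total_reads per-sample library sizes (needed for `"cpm"`).
#' @param holdout_fraction fraction excluded per round (default 0.05).
#' @param iterations resampling rounds (default 1000).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @param normalize `"cpm"` or `"raw"`.
#' @return object of class `ff_model` with `coef` (length n+1), the
#'   per-round `coef_archive`, and training diagnostics.
#' @export
fit_ff_model <- function(counts, ff, total_reads = NULL,
                         holdout_fraction = 0.05, iterations = 1000L,
                         seed = 1L, normalize = c("cpm", "raw")) {
  normalize <- match.arg(normalize)
  counts <- as.matrix(counts)
  n <- nrow(counts)
  stopifnot(length(ff) == n, holdout_fraction >= 0, holdout_fraction < 1)
  X <- if (normalize == "cpm") {
    if (is.null(total_reads)) stop("total_reads required for cpm normalization")
    counts / total_reads * 1e6
  } else counts
  design <- cbind(`(Intercept)` = 1, X)
  d <- floor(holdout_fraction * n)
  if (n - d < ncol(design) + 1L)
    stop("too few samples after holdout (need >= n_regions + 2)")
  set.seed(seed)
  archive <- matrix(NA_real_, iterations, ncol(design))
  colnames(archive) <- colnames(design)
  n_flagged <- 0L
  for (it in seq_len(iterations)) {
    keep <- if (d > 0) -sample.int(n, d) else seq_len(n)
    sol <- ols_coef(design[keep, , drop = FALSE], ff[keep])
    archive[it, ] <- sol$coef
    n_flagged <- n_flagged + sol$flagged
  }
  beta <- apply(archive, 2, stats::median)
  sse <- sum((ff - drop(design %*% beta))^2)
  structure(list(coef = beta, region_names = colnames(X),
                 normalize = normalize,
                 holdout_fraction = holdout_fraction, iterations = iterations,
                 seed = seed, coef_archive = archive, n_flagged = n_flagged,
                 train_sse = sse),
            class = "ff_model")
}

#' @export
print.ff_model <- function(x, ...) {
  cat("<ff_model> ", length(x$coef) - 1L, " regions; ",
      x$iterations, " jackknife rounds (holdout ",
      x$holdout_fraction * 100, "%), ", x$n_flagged, " flagged\n",
      "  training SSE: ", format(x$train_sse), "\n", sep = "")
  invisible(x)
}

#' Predict fetal fraction from region counts
#'
#' `b0 + sum(b_i y_i)`; predictions are clamped to `[0, 1]` unless
#' `clamp = FALSE` (validation uses unclamped values). Clamped entries are
#' flagged in the `"clamped"` attribute.
#'
#' @param model an `ff_model`.
#' @param counts count vector (one sample) or matrix (samples in rows); the
#'   region layout must match the model.
#' @param total_reads per-sample library sizes (for `"cpm"` models).
#' @param clamp clamp predictions to `[0, 1]`?
#' @return numeric predictions.
#' @export
predict_ff <- function(model, counts, total_reads = NULL, clamp = TRUE) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  if (ncol(counts) != length(model$coef) - 1L)
    stop("feature dimension mismatch: model has ", length(model$coef) - 1L,
         " regions, input has ", ncol(counts))
  X <- if (model$normalize == "cpm") {
    if (is.null(total_reads)) stop("total_reads required for cpm model")
    counts / total_reads * 1e6
  } else counts
  pred <- drop(cbind(1, X) %*% model$coef)
  if (clamp) {
    clamped <- pred < 0 | pred > 1
    pred <- pmin(1, pmax(0, pred))
    attr(pred, "clamped") <- clamped
  }
  pred
}

#' Validate a fetal fraction model on held-out samples
#'
#' Pearson correlation (on unclamped predictions), RMSE and bias against the
#' reference fetal fractions of an independent validation set.
#'
#' @param model an `ff_model`.
#' @param counts validation count matrix (samples in rows).
#' @param ff reference fetal fractions.
#' @param total_reads per-sample library sizes (for `"cpm"` models).
#' @return list with `pearson_r`, `rmse`, `bias`, `n`.
#' @export
validate_ff_model <- function(model, counts, ff, total_reads = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 3) stop("need at least 3 validation samples")
  pred <- predict_ff(model, counts, total_reads, clamp = FALSE)
  list(pearson_r = stats::cor(pred, ff),
       rmse = sqrt(mean((pred - ff)^2)),
       bias = mean(pred - ff),
       n = length(ff))
}
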