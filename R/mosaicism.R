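#' Aneuploidy-implied fetal fraction (AneuFC)
#'
#' For a sample with a positive call on `target_chrom`, the excess read
#' share of that chromosome over its euploid expectation implies a fetal
#' fraction: a full trisomy adds half a chromosome's worth of fetal dosage,
#' so `AneuFC = 2 * (f_obs / f_exp - 1)`, clamped to `[0, 1]`.
#'
#' When the target chromosome is a non-negligible share of the sequenced
#' genome, the extra trisomic copy also renormalizes every chromosome's
#' share; inverting that renormalization gives the exact dosage form
#' `AneuFC = 2 (r - 1) / ((1 - f_exp) - f_exp (r - 1))` with
#' `r = f_obs / f_exp`, which reduces to the naive `2 (r - 1)` as
#' `f_exp -> 0` (the human chr21 regime). The correction is on by default;
#' `share_correction = FALSE` selects the naive form.
#'
#' @param x fragment data.frame, or a named per-chromosome count vector.
#' @param target_chrom chromosome carrying the positive call.
#' @param euploid_share expected euploid read share `f_exp` of
#'   `target_chrom` (> 0), e.g. measured from euploid reference samples.
#' @param share_correction apply the genome-share renormalization
#'   correction (default TRUE).
#' @return AneuFC in `[0, 1]`.
#' @export
estimate_aneufc <- function(x, target_chrom, euploid_share,
                            share_correction = TRUE) {
  if (euploid_share <= 0) stop("euploid reference share must be > 0")
  f_obs <- if (is.data.frame(x)) mean(x$chrom == target_chrom)
           else x[[target_chrom]] / sum(x)
  r <- f_obs / euploid_share
  val <- if (share_correction)
    2 * (r - 1) / ((1 - euploid_share) - euploid_share * (r - 1))
  else 2 * (r - 1)
  min(1, max(0, val))
}

#' Combined Z-score screen for confined placental mosaicism
#'
#' Among aneuploidy-positive samples, discordance between an independent
#' fetal-fraction estimate and the aneuploidy-implied one signals mosaicism
#' (aneuploid cells confined to part of the placenta dilute the dosage
#' signal). The discordance is `D = FF_best - AneuFC`, where `FF_best` is
#' the chrY estimate (`sexFC`) when defined and the region-model estimate
#' (`RegFC`) otherwise. `D` is standardized against a reference set of
#' concordant positives: `z = (D - mu_ref) / sigma_ref`; samples with
#' `z > cutoff` are flagged. Flags are advisory annotations, never
#' demotions of positive calls.
#'
#' @param triples data.frame with `sample_id`, `sexFC` (may be `NA`),
#'   `RegFC`, `AneuFC`.
#' @param reference data.frame of the same shape from known concordant
#'   (true-positive) samples; at least 20 rows.
#' @param cutoff flagging threshold on the combined Z (default 3).
#' @return data.frame with `D`, `combined_z`, `flagged`, plus reference
#'   statistics in attributes `mu_ref`, `sigma_ref`, `cutoff`.
#' @export
combined_zscore <- function(triples, reference, cutoff = 3) {
  if (nrow(reference) < 20) stop("reference must contain at least 20 samples")
  disc <- function(x) ifelse(!is.na(x$sexFC), x$sexFC, x$RegFC) - x$AneuFC
  d_ref <- disc(reference)
  mu <- mean(d_ref)
  sigma <- stats::sd(d_ref)
  if (sigma == 0) stop("degenerate reference: sigma is 0")
  out <- triples
  out$D <- disc(triples)
  out$combined_z <- (out$D - mu) / sigma
  out$flagged <- out$combined_z > cutoff
  attr(out, "mu_ref") <- mu
  attr(out, "sigma_ref") <- sigma
  attr(out, "cutoff") <- cutoff
  out
}

#' Assemble the three fetal-fraction estimates for one sample
#'
#' Convenience wrapper building an `FFTriple` row (sexFC / RegFC / AneuFC)
#' from fragments, a fitted region model and a chrY calibration.
#'
#' @param fragments fragment data.frame of the sample.
#' @param sample_id identifier.
#' @param sex fetal sex (`sexFC` is `NA` for female fetuses).
#' @param model an `ff_model` for RegFC.
#' @param regions region set matching the model.
#' @param calib chrY calibration (see [estimate_ff_chry()]).
#' @param target_chrom,euploid_share see [estimate_aneufc()].
#' @return one-row data.frame (`sample_id`, `sexFC`, `RegFC`, `AneuFC`,
#'   `target_chrom`).
#' @export
ff_triple <- function(fragments, sample_id, sex, model, regions, calib,
                      target_chrom, euploid_share) {
  y <- count_region_reads(fragments, regions)
  data.frame(
    sample_id = sample_id,
    sexFC = if (sex == "male") estimate_ff_chry(fragments, calib) else NA_real_,
    RegFC = predict_ff(model, y, total_reads = nrow(fragments))[1],
    AneuFC = estimate_aneufc(fragments, target_chrom, euploid_share),
    target_chrom = target_chrom, stringsAsFactors = FALSE)
}
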