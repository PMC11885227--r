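---
title: "Coverage-based fetal signal analysis for NIPT cfDNA: models and methods"
author: "niptcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based fetal signal analysis for NIPT cfDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Maternal plasma cfDNA sequenced for non-invasive prenatal testing (NIPT) is
a two-component mixture. Writing $f$ for the fetal fraction, the probability
that a sequenced read starts at genomic position $x$ is

$$p(x) = (1-f)\,m(x) + f\,g(x),$$

where $m$ is the maternal and $g$ the feto-placental sampling profile. Every
analysis in this package is a different projection of this mixture:

* **Fetal-specific regions.** Where $m(x) = 0$ and $g(x) > 0$, expected
  depth is proportional to $f$: regressing per-base depth of
  fetal-fraction-stratified merged libraries on the group mean fetal
  fraction finds exactly those loci (positive slope, intercept zero, small
  relative residual). chrY in male pregnancies is the canonical anchor; the
  genome-wide scan looks for autosomal loci with the same behavior.
* **Fetal fraction from region counts.** With regions $1..n$ fixed, a
  sample's count vector $y$ is linear in $f$, so
  $\hat f = \beta_0 + \sum_i \beta_i y_i$. The coefficients are fitted by
  delete-$d$ jackknife: in each of 1,000 rounds a random 5% of training
  samples is removed, OLS is fitted on the rest, and the reported
  $\beta_j$ is the elementwise median over rounds.
* **Mosaicism screen.** A trisomic placenta with aneuploid-cell fraction
  $m$ multiplies the fetal weight of the target chromosome by $1+m/2$, so
  its read-share excess implies a fetal fraction (AneuFC). Confined
  placental mosaicism makes AneuFC fall short of the chrY- or region-based
  estimate; the combined Z standardizes the discordance
  $D = \mathrm{FF}_{best} - \mathrm{AneuFC}$ against concordant positives
  and flags $z > 3$. Flags are advisory; positive calls are never demoted.
* **Open chromatin.** A nucleosome-depleted region (NDR) upstream of a
  transcriptionally active fetal gene depletes the *fetal* contribution at
  that locus, so total coverage falls strictly monotonically across
  fetal-fraction tiers (5/10/15/20%). Monotone positions are dilated by
  12 bp into 25 bp windows, chained, and runs of at least five windows are
  kept; genes with a TSS downstream of a run (strand-aware, within 10 kb)
  are collected and summarized by hypergeometric enrichment.
* **Phenotype score.** A case/control contrast over promoter windows
  yields an up/down loci panel; a sample's signed sum
  $S = \sum_{up} c_i - \sum_{down} c_j$ (counts per million) is
  standardized against a blind cohort reference, reported as
  $\max(0, z+4)$, and called above the empirical 99% quantile.

## The synthetic world

The clinical data behind this design is access-restricted, so the package
ships a generator that emulates its statistical structure, and every claim
a test makes is a claim about this stated world:

* Toy genome: five 2-Mb autosomes plus a 0.5-Mb chrY. Profiles are
  piecewise constant, so sampling is an exact multinomial over segments.
* 12 planted fetal-specific loci (200 bp, three each on chr1--chr4),
  maternal weight zero, flanked upstream by `AG CGGAACGGAA CG` inside an
  otherwise random 50 bp flank.
* 24 NDR genes with a 150 bp dip upstream of the TSS in which the fetal
  density is multiplied by 0.2; 20 panel loci (10 up / 10 down, effect
  $\pm 0.5$) at promoters on chr5; trisomy/CPM dosage on chr3.
* Libraries are 200,000 single-end 40 bp reads by default (the full-scale
  design is 4.2 million); fetal fractions are uniform on 5--20%.

Two scale choices deserve explanation because they are *not* in the
original design and were fixed once, from signal-to-noise arguments, before
the corresponding tests were frozen:

* The planted loci carry 10% of the fetal profile mass in 2.4 kb. At a 21×
  read-count scale-down, this strong placental enrichment keeps per-base
  depth at the loci in the tens-to-hundreds range — the same per-base SNR
  regime the full-scale data has at unenriched fetal-specific loci. Without
  it nothing is recoverable at desk scale, with any method.
* Open-chromatin tiers pool 250 samples each, putting adjacent-tier depth
  differences at planted NDRs near 0.6 Poisson SD — the regime where a
  magnitude-blind strict-monotonicity filter starts to retain dips at a
  usable rate (measured run-level sensitivity 0.92).

What the generator does **not** emulate: GC and mappability bias, fragment
length distributions (the ~166 bp nucleosome ladder is not modeled; all
fragments are 40 bp intervals), sequencing error, and real genomic
sequence outside the planted flanks. A green test therefore establishes
that the *statistics* behave as designed under the stated mixture, not
that the pipeline is robust to real-data artifacts.

## Numerical and design choices

**Fitted-error rule at two depth regimes.** The literal qualifying rule for
a fetal-specific position is: maximum per-group relative residual
$|d_g - \hat d_g| / \hat d_g < 1.5\%$, positive slope, minimum raw merged
depth $\ge 2$. This is meaningful when counting noise is far below 1.5% of
the fitted depth — true for analytic expected tracks and for very deep
merged libraries, and `call_fetal_regions()` /
`scan_fetal_regions()` default to it. At scaled-down depth the per-base
Poisson CV is 10--30%, so the same rule would reject everything. The
scanner therefore exposes two noise-aware options used by the analysis
scripts: `noise_z` widens the band to
$1.5\% \cdot \hat d + z\sqrt{\hat d}$ (Poisson allowance, $z=4$), and
`slope_alpha` requires the slope to be significantly positive (one-sided
$t$, $p < 10^{-5}$, which controls genome-wide false positives at the
~10-per-genome level). Both reduce to the literal rule as depth grows.

**Depth mode.** Whether "per-base depth" counts covering reads or read
starts is not fixed by the design; both are implemented. Coverage is the
default (profiles look like the published smoothed tracks); the noiseless
exact-recovery checks use read-start mode, where a fetal-only locus's
called footprint coincides with the locus itself (coverage mode dilates it
by read length − 1 to the right).

**`min_reads` interpretation.** "At least 2 reads covered" is applied to
raw merged depth, minimum across groups; regression uses depth normalized
to the mean group total. The error functional (max vs mean relative
residual) is switchable via `error_type`.

**AneuFC share correction.** The naive dosage form
$2(f_{obs}/f_{exp} - 1)$ ignores that an extra chromosome copy
renormalizes all read shares. On a human chr21 (1.3% of the genome) the
error is negligible; on the toy genome's chr3 (~19%) it attenuates AneuFC
by ~20% and biases the reference. The default estimator inverts the
renormalization exactly,
$2(r-1)/\left[(1-f_{exp}) - f_{exp}(r-1)\right]$, and reduces to the naive
form as $f_{exp} \to 0$; `share_correction = FALSE` restores the naive
form.

**Differential coverage.** With two merged libraries and no replicates, the
RNA-seq-style count test reduces to an exact conditional binomial: given
the position total $x_1+x_2$, $x_1$ is Binomial with success probability
$t_1/(t_1+t_2)$ under the null, two-sided p-value by the minimum-likelihood
convention, BH-adjusted. These p-values annotate candidates; they do not
gate window-run calling, because the monotonic filter is explicitly
magnitude-blind and per-base counts at desk scale are individually
non-significant even at planted dips.

**Fetal-specific intersection of monotone candidates.** In the generative
model, NDR dips are maternal-background positions with *depleted* fetal
coverage — disjoint by construction from the fetal-specific (slope-up)
loci. Intersecting the two, as the full-scale analysis does, would be empty
here; `window_runs(restrict = )` implements the intersection but the
analysis runs unrestricted, and the vignette records this as a known
divergence between the toy world and the real genome (where "fetal
specific" regions are broad and contain informative sub-structure).

**Scoring conventions.** The signed sum uses counts-per-million within
sample (raw sums would confound library size with phenotype). The reference
is blind (whole cohort) by default — ranking is invariant to switching to
labeled controls, which is tested. The quantile is the type-7
order-statistic quantile with linear interpolation and the call is a strict
exceedance; both are configurable because tie and interpolation conventions
change the exceedance count near the threshold. The reporting adjustment is
exactly $\max(0, z+4)$.

**Jackknife details.** "Jackknife" means the described delete-$d$ scheme
(random 5% deletion × 1,000 rounds, elementwise median), not classical
leave-one-out. Rounds with rank-deficient designs fall back to the
minimum-norm SVD solution and are counted. Counts are normalized to CPM
before fitting by default (`normalize = "raw"` matches the literal
equation); the fit is deterministic given its seed.

**chrY calibration.** The chrY-dosage estimator interpolates between the
generator's own measured female-background and pure-fetal chrY shares
(`chry_calibration()`); no human calibration constants are hard-coded.

## Known limitations

* At the scaled-down default depth, chrY itself falls below the 2-read
  rule (its per-base fetal coverage is < 1), so the chrY-anchor mode is
  informative only on expected tracks or at full-scale read counts; the
  genome-wide scan with noise-aware settings is the workhorse.
* The combined Z-score's exact functional form is a design choice of this
  package (standardized discordance, best-available independent estimate
  first); it realizes the published description but was never validated
  clinically, and the flags are annotations only.
* Enrichment replaces a web-service analysis with an internal
  hypergeometric test against a user-supplied term annotation; published
  p-values from service-specific backgrounds are not comparable and are
  not reproduced — only the overlap-percentage arithmetic is.
* PPV evaluation excludes unknown outcomes from the denominator; with few
  calls the estimate is unstable, which mirrors its clinical counterpart.
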