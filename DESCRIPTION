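Package: niptcov
Title: Coverage-Based Fetal Signal Analysis for NIPT Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis toolkit for low-pass maternal plasma cell-free DNA
    (NIPT) coverage data: discovery of fetal-specific genomic regions from
    fetal-fraction-stratified merged libraries, a region-count linear model
    of fetal fraction fitted by delete-d jackknife resampling, a combined
    Z-score screen for confined placental mosaicism among aneuploidy-positive
    calls, inference of fetal open-chromatin candidates from coverage
    monotonicity across fetal-fraction tiers, and a signed-sum coverage score
    for phenotype prediction. Includes a synthetic maternal/fetal cfDNA
    cohort generator that emulates the statistical structure every stage
    assumes, so the whole pipeline is testable without access-restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
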