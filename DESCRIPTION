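Package: acidscreen
Title: pH-Dependent Gene Essentiality from Pooled CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for genome-wide CRISPR-Cas9 viability screens run
    under varying extracellular pH (pHe). Provides a synthetic-data generator for
    pooled-screen count matrices, growth plates and medium photometry traces;
    differential gene-essentiality scoring between pHe conditions (guide-level
    empirical-Bayes Z-scores, gene-level normZ, directional Benjamini-Hochberg
    FDR, hit calling, set overlaps and gene-set overrepresentation); a
    five-parameter biphasic Hill model of growth versus pHe with pH50
    extraction, censored extrapolation and bootstrap group comparison; and
    media-chemistry utilities (Henderson-Hasselbalch bicarbonate/CO2 design,
    buffering capacity, ratiometric dye calibration, Stern-Volmer oxygen,
    metabolic flux summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
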