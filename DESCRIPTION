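Package: mirscar
Title: Paired Scar/Normal miRNA Microarray Analysis with
    Distance-Correlation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for paired case/control miRNA microarray
    studies of hypertrophic scar versus normal skin: background subtraction
    and MA-lowess normalization, per-miRNA paired t-tests with
    Benjamini-Hochberg false discovery rate control, sure independence
    screening based on the distance correlation (DC-SIS) with model size
    6*floor(n/log(n)), hypergeometric gene-set over-representation against
    user-supplied GMT collections, and Table-style summaries of the three
    selection criteria. Includes a synthetic paired-design data generator
    with planted differential miRNAs, additive background and
    intensity-dependent per-array bias, so the whole analysis can be
    exercised and validated end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
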