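Package: esdeg
Title: Motif Enrichment in Small Promoter Sets from Differential Expression
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests transcription-factor binding-motif over-representation in
    the promoters of small differentially-expressed-gene (DEG) sets, where
    Fisher-style contingency tests lack power. Position weight matrices are
    calibrated against the whole promoter universe on a grid of expected
    recognition rates (ERRs); per-threshold site frequencies in the
    foreground promoters are compared with Monte-Carlo resampled background
    groups via Z-scores and normal tail probabilities; per-threshold
    p-values are unified across the grid with Hartung's dependent-p
    combination and corrected over the motif collection with
    Benjamini-Hochberg. Includes promoter extraction around transcription
    start sites, a HOCOMOCO-format matrix parser, a permutation test for
    pairwise motif similarity, and a synthetic-data generator with planted
    sites for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
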