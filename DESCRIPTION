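Package: rbpknn
Title: Homology-Weighted Nearest-Neighbor Inference of RNA-Binding
    Protein Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the RNA sequence preference (position weight matrix)
    of a poorly characterized RNA-binding protein as the
    sequence-similarity-weighted average of the motifs of its K nearest
    homologs, with K selected by cross-validation on probe intensities or
    fixed for proteins without binding data. Includes a windowed-product
    arcsinh-gated motif scan for scoring RNA sequences, a mirror-tree
    co-evolution statistic with permutation and parametric tests,
    conversion of a motif into a frozen k-mer score table for a logistic
    binding model, an evaluation harness (intensity clamping, probe-set
    splitting, Pearson correlation, ROC AUC, paired tests), seeded
    generators for co-evolved synthetic protein/motif families, readers
    and writers for MEME minimal and tabular motif formats, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
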