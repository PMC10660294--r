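Package: pephash
Title: Recursive Multi-Level Hashing for Peptide k-mers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A recursive (rolling) hash function for amino-acid k-mers built
    from per-residue 64-bit seed tables and a split-register bit rotation with
    period 1023.  Three hash levels encode biochemical similarity: level 1
    hashes each residue distinctly, while levels 2 and 3 share seeds within
    BLOSUM62-derived degeneracy groups so that conservative substitutions
    leave the hash unchanged.  Per-position levels combine into multi-level
    patterns analogous to spaced seeds.  Includes multi-hashing for Bloom
    filter membership, a minimal Bloom filter, synthetic peptide generation,
    FASTA input/output, and a statistical validation harness (histogram
    uniformity, Kolmogorov-Smirnov, Box-Muller normality and independence,
    and Bloom-filter false-positive-rate experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
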