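Package: hapbwt
Title: Positional Burrows-Wheeler Transform for Haplotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Linear-time construction of positional prefix and divergence
    arrays over phased bi-allelic haplotype panels, run-length-compressed
    storage with checkpointed binary indexes, and exact haplotype
    matching: all long matches and all set-maximal matches within a
    panel, and set-maximal matches of new query sequences against an
    indexed panel.  Includes readers for phased VCF and 0/1 text panels,
    frequency-based site thinning, a copying-model simulator for
    LD-structured test panels, and a command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
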