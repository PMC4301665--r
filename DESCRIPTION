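Package: orthodiverge
Title: Ortholog Pairing and Transcriptome Divergence Analysis for Two Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative transcriptome divergence analysis between
    two species: reciprocal-best-hit ortholog pairing with a translated rescue
    step, ORF-based transcript partitioning into 5'UTR/CDS/3'UTR, codon-aware
    pairwise alignment, per-site classification by codon degeneracy and CpG
    context, region-by-context divergence statistics (including
    transition/transversion ratios and GC/CpG content), Ka/Ks estimation by
    Nei-Gojobori counting and a Yang-Nielsen-style approximate method,
    Fisher-exact significance, positive-selection binning, and sliding-window
    Ka/Ks scans. Includes a codon-level ortholog-pair simulator (HKY-like
    mutation with CpG transition hypermutability and selection intensity
    omega) with recorded truth, so the whole pipeline can be validated
    end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
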