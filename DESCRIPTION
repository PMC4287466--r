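Package: rrqtl
Title: Round-Robin Bulk-Segregant QTL Mapping from Pooled Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bulk-segregant (X-QTL) analysis for multi-parent round-robin
    crosses of Saccharomyces cerevisiae. Simulates recombinant haploid
    segregant pools under viability selection and mating-type sorting,
    converts pooled sequencing counts into allele-frequency tracks and
    selection-versus-control or mating-type contrasts, scores those
    contrasts with a binned latent-allele-frequency hidden Markov model
    that yields per-bin LOD scores, calls QTL peaks with 2-LOD support
    intervals, merges calls across replicate selections, stress dosages and
    crosses, and associates the cross-segregation pattern of candidate
    variants with per-cross LOD profiles to narrow causal variants. Also
    provides growth normalization, a midparent (epistasis) test, and
    coverage-ratio copy-number estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
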