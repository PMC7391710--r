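Package: ldcheck
Title: Sample-Swap Detection for Sequencing Data Using Linkage-Disequilibrium Blocks
Version: 0.1.0
Authors@R: person("ldcheck", "developers", email = "ldcheck@example.org", role = c("aut", "cre"))
Description: Quantifies whether two next-generation sequencing datasets derive
    from the same donor by comparing diploid genotype likelihoods computed over
    linkage-disequilibrium (LD) haplotype blocks, and reports a per-block-capped
    base-10 log-odds (LOD) score. Includes construction and validation of
    haplotype maps from phased genotype panels (MAF filtering, anchor pruning,
    LD-score-ordered greedy block building), fingerprint extraction from
    aligned reads with strict read and base filters, fingerprint persistence as
    VCF, database-scale swap screening with representative selection and donor
    nomination, a contamination-mixture harness, and a seeded synthetic-data
    generator (phased panels with block LD structure, related individuals,
    Poisson-coverage reads) used by the test suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
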