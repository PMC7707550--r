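Package: wsstrack
Title: Window-Based SNV Similarity Strain Tracking for Longitudinal Metagenomes
Version: 0.1.0
Authors@R:
    person("wsstrack", "developers", email = "wsstrack@example.org", role = c("aut", "cre"))
Description: Tracks persistence and replacement of dominant microbial strains in
    paired longitudinal gut-metagenome samples. From per-species multi-sample
    variant calls (VCF) and per-base depth tracks, computes genome-wide
    window-based SNV similarity (WSS) scores between sample pairs, calibrates
    per-species related/unrelated cutoffs from score distributions, classifies
    strain persistence versus extinction per individual, and cross-checks calls
    against a neighbor-joining tree built from SNV p-distances. Includes a
    seeded synthetic-cohort generator (haplotypes, drift or strain replacement,
    depth dropout, genotype-call error) that writes standard FASTA, VCF and
    depth files so the whole real-data path is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
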