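# wsstrack

Strain-level tracking of dominant gut-microbial genotypes across
longitudinal metagenome samples. Given the standard outputs of an
alignment + variant-calling pipeline for one microbial species — a
reference FASTA, per-base depth tracks (`samtools depth` TSV) and a
multi-sample VCF — `wsstrack` answers, per individual and sample pair:
did the dominant strain **persist** (related) or was it **replaced**
(unrelated)?

It is aimed at microbiome researchers studying strain persistence and
extinction around perturbations (bowel cleansing, metformin and other
drugs, diarrhea) and, more generally, at anyone needing a genome-wide
SNV-similarity "fingerprint" comparison between metagenome samples.

## The score

The window-based SNV similarity (WSS) between samples *a* and *b* on one
species reference tiles the genome into windows of *w* bp (default
1000) and averages per-window SNV agreement:

    WSS(a,b) = (1/|W|) * sum over usable windows k of  m_k / c_k

where `c_k` counts comparable variant positions in window *k* (the union of
the pair's variant positions, excluding positions unknowable in either
sample) and `m_k` those with equal allele states. A position with no call
but depth ≥ 5 contributes the reference state; a window is unusable for a
pair when more than 50% of its bases have depth < 5 in either sample, or
when it has no comparable position. Samples with breadth < 30% or mean
depth < 3.5 are excluded outright. A pair is **related** iff
`WSS > cutoff`, with per-species cutoffs either supplied (species table) or
calibrated from within- vs between-individual score distributions
(midpoint of the gap when disjoint, kernel-density crossing otherwise).
A neighbor-joining tree on genome-wide SNV p-distances provides an
independent cross-method check.

Because the real inputs are terabyte-scale read sets, the package ships a
seeded synthetic-cohort generator (strain haplotypes, per-site drift vs
strain replacement, Poisson depth with dropout, genotype-call error) that
writes FASTA + VCF + depth TSVs, so the full pipeline is testable offline.

## Worked example

```r
library(wsstrack)

cfg <- simulation_config(genome_length = 20000L, n_individuals = 6L,
                         replacement_prob = 0.25, seed = 7L)
dir <- file.path(tempdir(), "demo")
cohort <- simulate_cohort(cfg, dir = dir)   # writes FASTA/VCF/depth TSVs
data <- read_cohort(dir)                    # back through the real-data path

w <- make_windows(cfg$genome_length)
cal <- collect_calibration_pairs(data$profiles, w)
head(cal$pairs[, c("sample_a", "sample_b", "score", "provenance")], 4)
#>   sample_a sample_b     score provenance
#> 1   I01_T1   I01_T2 0.9766071    related
#> 2   I01_T1   I02_T1 0.0000000  unrelated
#> 3   I01_T1   I02_T2 0.0000000  unrelated
#> 4   I01_T1   I03_T1 0.0000000  unrelated

model <- calibrate_cutoff(cal$related_scores, cal$unrelated_scores,
                          min_per_class = 3)
model
#> <cutoff_model> cutoff 0.4861 (midpoint); n_related 6, n_unrelated 60

calls <- classify_table(cal$pairs, setNames(model$cutoff, cfg$species_id),
                        dataset_id = "demo")
calls[calls$individual_a == calls$individual_b,
      c("individual_a", "score", "label")]
#>    individual_a     score   label
#> 1           I01 0.9766071 related
#> 22          I02 0.9711111 related
#> 39          I03 0.9653205 related
#> 52          I04 0.9792137 related
#> 61          I05 0.9755682 related
#> 66          I06 0.9709567 related
```

Within-individual pairs score ≈ 0.97 (same strain, 2% per-site drift plus
call error), between-individual pairs ≈ 0 (independent strains disagree at
almost every compared site), and the calibrated cutoff (0.486, midpoint of
the gap) classifies all six individuals as carrying a persistent strain —
matching the simulation's ground truth (`cohort$truth`). The
cross-method check agrees:

```r
tree <- build_nj_tree(snv_distance_matrix(data$profiles))
tree_relatedness(tree, "I01_T1", "I01_T2", threshold = 1 - model$cutoff)
#> [1] "related"
```

A command-line mirror of the pipeline is installed as `exec/wsstrack`
(subcommands `simulate`, `filter`, `wss`, `calibrate`, `classify`,
`report`, `concord`); see `?wss_cli`.

## Documentation

The methods vignette (`vignettes/strain-tracking-methods.Rmd`) describes
the score, filters, calibration, the NJ check, the synthetic world and its
limits, and every numerical design choice.
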