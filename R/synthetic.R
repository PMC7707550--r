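#' Simulation configuration for synthetic strain cohorts
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' Defaults describe a realistic per-species view of a ~20x gut metagenome:
#' a 50 kb reference, 1% of sites polymorphic in a strain, small per-site
#' drift between timepoints of a persisting strain, Poisson depth with a
#' modest dropout fraction, and a small genotype-call error rate.
#'
#' @param genome_length reference length in bp.
#' @param snv_density probability a site is polymorphic in a strain.
#' @param drift per-site probability a persisting strain's state changes
#'   between consecutive timepoints.
#' @param replacement_prob probability a later timepoint carries an
#'   independent replacement strain instead of the drifted one.
#' @param mean_depth Poisson mean of the per-base read depth.
#' @param dropout fraction of bases with forced zero depth.
#' @param call_error probability an observed site state is wrong.
#' @param n_individuals,n_timepoints cohort dimensions.
#' @param species_id,sequence_id identifiers used in generated files.
#' @param seed integer seed; a fixed seed makes the whole cohort (and its
#'   on-disk files) bit-identical across runs.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 50000L, snv_density = 0.01,
                              drift = 0.02, replacement_prob = 0.5,
                              mean_depth = 20, dropout = 0.05,
                              call_error = 0.005, n_individuals = 8L,
                              n_timepoints = 2L,
                              species_id = "synthetic_sp",
                              sequence_id = "synthetic_sp_ref",
                              seed = 1L) {
  probs <- c(snv_density = snv_density, drift = drift,
             replacement_prob = replacement_prob, dropout = dropout,
             call_error = call_error)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  stopifnot(genome_length >= 1L, mean_depth >= 0, n_individuals >= 1L,
            n_timepoints >= 1L)
  structure(list(genome_length = as.integer(genome_length),
                 snv_density = snv_density, drift = drift,
                 replacement_prob = replacement_prob,
                 mean_depth = mean_depth, dropout = dropout,
                 call_error = call_error,
                 n_individuals = as.integer(n_individuals),
                 n_timepoints = as.integer(n_timepoints),
                 species_id = species_id, sequence_id = sequence_id,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL uses the current stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

.BASES <- c("A", "C", "G", "T")

#' Simulate a reference sequence
#'
#' Uniform-random base composition, seeded.
#'
#' @param genome_length length in bp (>= 1).
#' @param seed integer seed (`NULL`: use the current RNG stream).
#' @param species_id,sequence_id identifiers for the genome.
#' @return a `reference_genome` carrying the sequence.
#' @export
simulate_reference <- function(genome_length, seed = NULL,
                               species_id = "synthetic_sp",
                               sequence_id = "synthetic_sp_ref") {
  if (genome_length < 1L) stop("genome_length must be >= 1")
  seq <- .with_seed(seed,
                    paste(sample(.BASES, genome_length, replace = TRUE),
                          collapse = ""))
  new_reference_genome(species_id, sequence_id, genome_length,
                       cutoff = NA_real_, sequence = seq)
}

#' Simulate a strain haplotype
#'
#' Each reference site is independently polymorphic with probability
#' `snv_density`; the alternate base is drawn uniformly from the three
#' non-reference bases.
#'
#' @param reference a `reference_genome` with its sequence.
#' @param snv_density per-site polymorphism probability.
#' @param seed integer seed (`NULL`: current stream).
#' @return a `haplotype`: list with integer `pos` and character `alt`.
#' @export
simulate_strain <- function(reference, snv_density, seed = NULL) {
  .with_seed(seed, {
    pos <- which(runif(reference$length) < snv_density)
    ref_b <- .ref_bases(reference, pos)
    alt <- vapply(ref_b, function(r) sample(setdiff(.BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    structure(list(pos = pos, alt = alt), class = "haplotype")
  })
}

.ref_bases <- function(reference, pos) {
  if (!length(pos)) return(character(0))
  substring(reference$sequence, pos, pos)
}

#' Evolve a haplotype or replace the strain
#'
#' The generative dichotomy of longitudinal strain tracking: with probability
#' `replacement_prob` the next timepoint carries a fresh independent strain
#' (extinction + replacement, truth label `unrelated`); otherwise the strain
#' persists and each polymorphic site's state is resampled to a different
#' base with probability `drift` (truth label `related`). Resampling may
#' revert a site to the reference base, in which case the site drops out of
#' the haplotype.
#'
#' @param haplotype a `haplotype` from [simulate_strain()].
#' @param drift per-site change probability under persistence.
#' @param replacement_prob probability of strain replacement.
#' @param reference the `reference_genome`.
#' @param snv_density density used for a replacement strain.
#' @param seed integer seed (`NULL`: current stream).
#' @return list with `haplotype` and `truth_label` (`related`/`unrelated`).
#' @export
evolve_or_replace <- function(haplotype, drift, replacement_prob, reference,
                              snv_density, seed = NULL) {
  .with_seed(seed, {
    if (runif(1) < replacement_prob) {
      list(haplotype = simulate_strain(reference, snv_density),
           truth_label = "unrelated")
    } else {
      pos <- haplotype$pos
      alt <- haplotype$alt
      if (length(pos)) {
        flip <- runif(length(pos)) < drift
        if (any(flip)) {
          ref_b <- .ref_bases(reference, pos[flip])
          alt[flip] <- vapply(seq_along(which(flip)), function(k) {
            i <- which(flip)[k]
            sample(setdiff(.BASES, alt[i]), 1L)  # any different base, incl. ref
          }, character(1))
          back <- alt == .ref_bases(reference, pos)
          pos <- pos[!back]; alt <- alt[!back]
        }
      }
      list(haplotype = structure(list(pos = pos, alt = alt),
                                 class = "haplotype"),
           truth_label = "related")
    }
  })
}

#' Observe a haplotype as a sequenced sample
#'
#' Sequencing model: per-base depth is Poisson(`mean_depth`) with an
#' independent dropout mask forcing a `dropout` fraction of bases to zero. A
#' variant site is called only where its depth is at least 1; with
#' probability `call_error` the observed base is perturbed to a different
#' base (a perturbation landing on the reference base erases the call).
#'
#' @param haplotype a `haplotype`.
#' @param reference the `reference_genome`.
#' @param mean_depth,dropout,call_error observation parameters.
#' @param sample_id,individual_id,timepoint profile metadata.
#' @param seed integer seed (`NULL`: current stream).
#' @return a `sample_profile` (single-sample allele coding: every called
#'   site has state 1 and carries its observed alt base; use
#'   [harmonize_states()] before cross-sample comparison).
#' @export
observe <- function(haplotype, reference, mean_depth = 20, dropout = 0.05,
                    call_error = 0.005, sample_id = "S1",
                    individual_id = sample_id, timepoint = "",
                    seed = NULL) {
  .with_seed(seed, {
    depth <- rpois(reference$length, mean_depth)
    if (dropout > 0)
      depth[runif(reference$length) < dropout] <- 0L
    pos <- haplotype$pos
    alt <- haplotype$alt
    covered <- depth[pos] >= 1L
    pos <- pos[covered]; alt <- alt[covered]
    if (call_error > 0 && length(pos)) {
      err <- runif(length(pos)) < call_error
      if (any(err)) {
        alt[err] <- vapply(which(err), function(i)
          sample(setdiff(.BASES, alt[i]), 1L), character(1))
        back <- alt == .ref_bases(reference, pos)
        pos <- pos[!back]; alt <- alt[!back]
      }
    }
    calls <- data.frame(pos = pos, ref = .ref_bases(reference, pos),
                        alt = alt, state = rep(1L, length(pos)),
                        dp = depth[pos], stringsAsFactors = FALSE)
    new_sample_profile(sample_id, reference, calls, depth,
                       individual_id = individual_id, timepoint = timepoint)
  })
}

#' Harmonize allele indices across profiles
#'
#' Recodes per-sample genotype states so that, at every position, the same
#' alternate base has the same allele index in every profile — the coding a
#' joint multi-sample VCF would produce. Allele order at a position is the
#' order of first appearance across profiles (in list order).
#'
#' @param profiles list of `sample_profile`s on one reference.
#' @return list of profiles with consistent `state` values; the allele table
#'   is attached as attribute `alleles` (data.frame `pos`, `alt`, `state`).
#' @export
harmonize_states <- function(profiles) {
  allp <- do.call(rbind, lapply(profiles, function(p)
    p$calls[, c("pos", "alt"), drop = FALSE]))
  if (is.null(allp) || nrow(allp) == 0L) {
    attr(profiles, "alleles") <- data.frame(pos = integer(),
                                            alt = character(),
                                            state = integer())
    return(profiles)
  }
  alleles <- allp[!duplicated(paste(allp$pos, allp$alt)), , drop = FALSE]
  alleles <- alleles[order(alleles$pos), , drop = FALSE]
  alleles$state <- as.integer(stats::ave(seq_len(nrow(alleles)), alleles$pos,
                                         FUN = seq_along))
  key <- paste(alleles$pos, alleles$alt)
  out <- lapply(profiles, function(p) {
    if (nrow(p$calls)) {
      p$calls$state <- alleles$state[match(paste(p$calls$pos, p$calls$alt),
                                           key)]
    }
    p
  })
  names(out) <- names(profiles)
  attr(out, "alleles") <- alleles
  out
}

#' Simulate a longitudinal strain-tracking cohort
#'
#' For each individual: a baseline strain at timepoint 1, then for each later
#' timepoint either drifted persistence or independent replacement (see
#' [evolve_or_replace()]); every haplotype is observed through the
#' depth/dropout/error model. Truth labels are recorded for every
#' within-individual timepoint pair: related iff no replacement event lies
#' between the two timepoints. Allele states are harmonized across the whole
#' cohort (joint VCF coding). Fully deterministic under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory: when given, the cohort is also written to
#'   disk via [write_cohort()].
#' @return list of class `synthetic_cohort`: `profiles` (named list),
#'   `truth` (data.frame `individual_id`, `species_id`, `sample_a`,
#'   `sample_b`, `timepoint_a`, `timepoint_b`, `truth_label`), `reference`,
#'   `config`, and `dir` when written.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- .with_seed(config$seed, {
    ref <- simulate_reference(config$genome_length,
                              species_id = config$species_id,
                              sequence_id = config$sequence_id)
    profiles <- list()
    truth <- list()
    for (i in seq_len(config$n_individuals)) {
      ind <- sprintf("I%02d", i)
      haps <- vector("list", config$n_timepoints)
      labels <- character(config$n_timepoints)  # transition into timepoint t
      haps[[1]] <- simulate_strain(ref, config$snv_density)
      if (config$n_timepoints > 1L) for (t in 2:config$n_timepoints) {
        ev <- evolve_or_replace(haps[[t - 1L]], config$drift,
                                config$replacement_prob, ref,
                                config$snv_density)
        haps[[t]] <- ev$haplotype
        labels[t] <- ev$truth_label
      }
      for (t in seq_len(config$n_timepoints)) {
        sid <- sprintf("%s_T%d", ind, t)
        profiles[[sid]] <- observe(haps[[t]], ref, config$mean_depth,
                                   config$dropout, config$call_error,
                                   sample_id = sid, individual_id = ind,
                                   timepoint = sprintf("T%d", t))
      }
      if (config$n_timepoints > 1L)
        for (t1 in 1:(config$n_timepoints - 1L))
          for (t2 in (t1 + 1L):config$n_timepoints) {
            lab <- if (any(labels[(t1 + 1L):t2] == "unrelated"))
              "unrelated" else "related"
            truth[[length(truth) + 1L]] <- data.frame(
              individual_id = ind, species_id = config$species_id,
              sample_a = sprintf("%s_T%d", ind, t1),
              sample_b = sprintf("%s_T%d", ind, t2),
              timepoint_a = sprintf("T%d", t1),
              timepoint_b = sprintf("T%d", t2),
              truth_label = lab, stringsAsFactors = FALSE)
          }
    }
    profiles <- harmonize_states(profiles)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(individual_id = character(), species_id = character(),
                 sample_a = character(), sample_b = character(),
                 timepoint_a = character(), timepoint_b = character(),
                 truth_label = character())
    structure(list(profiles = profiles, truth = truth, reference = ref,
                   config = config, dir = NULL),
              class = "synthetic_cohort")
  })
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    cohort$dir <- dir
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d profiles (%d individuals x %d timepoints), %d bp reference\n",
    length(x$profiles), x$config$n_individuals, x$config$n_timepoints,
    x$reference$length))
  invisible(x)
}
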