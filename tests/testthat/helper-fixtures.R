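# Small in-code fixtures shared across test files.

# reference with a fixed (repeating) sequence so base identities are known
make_ref <- function(length = 100L, species_id = "sp1",
                     sequence_id = "sp1_ref", cutoff = NA_real_) {
  seq <- paste(rep_len(c("A", "C", "G", "T"), length), collapse = "")
  wsstrack:::new_reference_genome(species_id, sequence_id, length, cutoff, seq)
}

# profile from explicit call positions/states and a depth vector
make_profile <- function(ref, pos = integer(), state = integer(),
                         depth = rep(10L, ref$length), sample_id = "S1",
                         individual_id = sample_id, timepoint = "") {
  state <- rep_len(state, length(pos))
  ref_b <- if (length(pos)) substring(ref$sequence, pos, pos) else character()
  alt_of <- function(r, s) setdiff(c("A", "C", "G", "T"), r)[s]
  calls <- data.frame(pos = as.integer(pos), ref = ref_b,
                      alt = mapply(alt_of, ref_b, state, USE.NAMES = FALSE),
                      state = as.integer(state),
                      dp = depth[as.integer(pos)],
                      stringsAsFactors = FALSE)
  if (!length(pos))
    calls <- data.frame(pos = integer(), ref = character(), alt = character(),
                        state = integer(), dp = integer())
  wsstrack:::new_sample_profile(sample_id, ref, calls, as.integer(depth),
                                individual_id, timepoint)
}

# depth vector with an exact breadth and mean depth over `length` positions
make_depth <- function(length, breadth, mean_depth) {
  n_cov <- round(breadth * length)
  depth <- integer(length)
  if (n_cov > 0) {
    total <- round(mean_depth * length)
    base <- total %/% n_cov
    extra <- total - base * n_cov
    depth[seq_len(n_cov)] <- base
    if (extra > 0) depth[seq_len(extra)] <- depth[seq_len(extra)] + 1L
  }
  depth
}

# two jointly-coded observations of related/unrelated strains on one genome
make_pair <- function(seed, related = TRUE, genome_length = 20000L,
                      snv_density = 0.01, drift = 0.02, mean_depth = 20,
                      dropout = 0.05, call_error = 0.005) {
  wsstrack:::.with_seed(seed, {
    ref <- simulate_reference(genome_length)
    h1 <- simulate_strain(ref, snv_density)
    ev <- evolve_or_replace(h1, drift, if (related) 0 else 1, ref, snv_density)
    a <- observe(h1, ref, mean_depth, dropout, call_error, sample_id = "A")
    b <- observe(ev$haplotype, ref, mean_depth, dropout, call_error,
                 sample_id = "B")
    p <- harmonize_states(list(A = a, B = b))
    list(a = p$A, b = p$B, ref = ref, truth = ev$truth_label)
  })
}

# hand-written multi-sample VCF fixture for the reader tests
write_test_vcf <- function(path, chrom = "sp1_ref", records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

write_test_fasta <- function(path, seqs) {
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

write_species_table <- function(path, species_id, sequence_id, cutoff) {
  writeLines(c("species_id\tsequence_id\tcutoff",
               paste(species_id, sequence_id, cutoff, sep = "\t")), path)
  path
}
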