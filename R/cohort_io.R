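#' Write a synthetic cohort to standard files
#'
#' Emits the exact file set the real-data path consumes: `reference.fasta`,
#' `species_table.tsv` (header `species_id  sequence_id  cutoff`, cutoff
#' `NA`), one `<sample>.depth.tsv` per sample (samtools-depth dialect,
#' zero-depth positions omitted), a joint multi-sample `cohort.vcf`
#' (VCF 4.2, haploid GT + per-site DP), `samples.tsv` (sample metadata) and
#' `truth.tsv` (ground-truth pair labels). Output is byte-deterministic
#' given the cohort.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- cohort$reference

  fa <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$sequence_id))
  Biostrings::writeXStringSet(fa, file.path(dir, "reference.fasta"),
                              width = 70L)

  write.table(
    data.frame(species_id = ref$species_id, sequence_id = ref$sequence_id,
               cutoff = ifelse(is.na(ref$cutoff), "NA",
                               format(ref$cutoff, digits = 15))),
    file.path(dir, "species_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  for (p in cohort$profiles) {
    covered <- which(p$depth >= 1L)
    write.table(
      data.frame(chrom = rep(ref$sequence_id, length(covered)),
                 pos = covered, depth = p$depth[covered]),
      file.path(dir, paste0(p$sample_id, ".depth.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  meta <- data.frame(
    sample_id = vapply(cohort$profiles, `[[`, character(1), "sample_id"),
    individual_id = vapply(cohort$profiles, `[[`, character(1), "individual_id"),
    timepoint = vapply(cohort$profiles, `[[`, character(1), "timepoint"))
  write.table(meta, file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  .write_vcf(cohort$profiles, ref, file.path(dir, "cohort.vcf"))
  invisible(dir)
}

# minimal deterministic multi-sample VCF 4.2 writer (haploid GT, DP)
.write_vcf <- function(profiles, reference, path) {
  samples <- vapply(profiles, `[[`, character(1), "sample_id")
  alleles <- attr(profiles, "alleles")
  if (is.null(alleles)) {
    profiles <- harmonize_states(profiles)
    alleles <- attr(profiles, "alleles")
  }
  pos <- sort(unique(alleles$pos))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wsstrack-simulator",
    sprintf("##contig=<ID=%s,length=%d>", reference$sequence_id,
            reference$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(pos, function(pp) {
    al <- alleles[alleles$pos == pp, , drop = FALSE]
    al <- al[order(al$state), , drop = FALSE]
    cells <- vapply(profiles, function(p) {
      i <- match(pp, p$calls$pos)
      dp <- p$depth[pp]
      gt <- if (!is.na(i)) as.character(p$calls$state[i])
            else if (dp >= 1L) "0" else "."
      paste0(gt, ":", dp)
    }, character(1))
    paste(c(reference$sequence_id, pp, ".",
            substring(reference$sequence, pp, pp),
            paste(al$alt, collapse = ","), ".", "PASS", ".", "GT:DP", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read a cohort directory back into sample profiles
#'
#' Re-reads files written by [write_cohort()] through the ordinary real-data
#' path ([read_reference_catalog()], [read_depth()],
#' [read_variant_profiles()]), so a write/read round trip exercises every
#' I/O operation.
#'
#' @param dir cohort directory.
#' @return list with `profiles`, `truth`, `reference`, `catalog`.
#' @export
read_cohort <- function(dir) {
  catalog <- read_reference_catalog(file.path(dir, "reference.fasta"),
                                    file.path(dir, "species_table.tsv"))
  ref <- catalog[[1]]
  meta <- read.table(file.path(dir, "samples.tsv"), header = TRUE, sep = "\t",
                     colClasses = "character")
  depths <- lapply(meta$sample_id, function(s)
    read_depth(file.path(dir, paste0(s, ".depth.tsv")), ref))
  names(depths) <- meta$sample_id
  profiles <- read_variant_profiles(file.path(dir, "cohort.vcf"), ref,
                                    depths, sample_meta = meta)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    read.table(truth_path, header = TRUE, sep = "\t",
               colClasses = "character") else NULL
  list(profiles = profiles, truth = truth, reference = ref, catalog = catalog)
}
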