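#' Read a species reference catalog
#'
#' Loads a reference FASTA and its companion species table into a catalog of
#' reference genomes. The species table is a TSV with header
#' `species_id  sequence_id  cutoff`; the cutoff column is optional and the
#' string `"NA"` (or an empty cell) means no published cutoff is available for
#' that species (the `CO:NA` state, under which sample pairs cannot be
#' classified).
#'
#' @param fasta_path path to a (multi-)FASTA of per-species reference
#'   sequences. Record IDs (first whitespace-delimited token) must match the
#'   table's `sequence_id` column one-to-one.
#' @param species_table_path path to the species table TSV.
#' @return A named list of `reference_genome` objects keyed by `species_id`,
#'   of class `reference_catalog`. Each genome carries `species_id`,
#'   `sequence_id`, `length`, `cutoff` (`NA` when absent) and the `sequence`
#'   itself.
#' @export
read_reference_catalog <- function(fasta_path, species_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence IDs in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))

  tab <- read.table(species_table_path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "")
  if (!all(c("species_id", "sequence_id") %in% names(tab)))
    stop("species table needs columns species_id and sequence_id")
  if (anyDuplicated(tab$species_id))
    stop("duplicate species_id in species table")
  if (anyDuplicated(tab$sequence_id))
    stop("duplicate sequence_id in species table")
  missing_fa <- setdiff(tab$sequence_id, names(seqs))
  missing_tab <- setdiff(names(seqs), tab$sequence_id)
  if (length(missing_fa) || length(missing_tab))
    stop("FASTA/table sequence_id mismatch; missing from FASTA: [",
         paste(missing_fa, collapse = ","), "]; missing from table: [",
         paste(missing_tab, collapse = ","), "]")

  cutoff <- if ("cutoff" %in% names(tab))
    suppressWarnings(as.numeric(tab$cutoff)) else rep(NA_real_, nrow(tab))
  bad <- !is.na(cutoff) & (cutoff <= 0 | cutoff >= 1)
  if (any(bad))
    stop("cutoff values must lie strictly in (0,1): ",
         paste(tab$species_id[bad], collapse = ", "))

  cat <- lapply(seq_len(nrow(tab)), function(i) {
    s <- seqs[[tab$sequence_id[i]]]
    new_reference_genome(species_id = tab$species_id[i],
                         sequence_id = tab$sequence_id[i],
                         length = length(s),
                         cutoff = cutoff[i],
                         sequence = as.character(s))
  })
  names(cat) <- tab$species_id
  structure(cat, class = "reference_catalog")
}

new_reference_genome <- function(species_id, sequence_id, length,
                                 cutoff = NA_real_, sequence = NULL) {
  stopifnot(length >= 1)
  if (!is.na(cutoff)) stopifnot(cutoff > 0, cutoff < 1)
  structure(list(species_id = species_id, sequence_id = sequence_id,
                 length = as.integer(length), cutoff = cutoff,
                 sequence = sequence),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s (%s), %d bp, cutoff %s\n",
              x$species_id, x$sequence_id, x$length,
              ifelse(is.na(x$cutoff), "CO:NA", format(x$cutoff))))
  invisible(x)
}

#' Read a per-base depth track
#'
#' Reads a three-column depth TSV (`chrom  pos  depth`, the `samtools depth`
#' dialect, 1-based positions, no header) into a dense per-base integer
#' vector over the reference. Positions absent from the file have depth 0;
#' rows for other chromosomes are ignored.
#'
#' @param depth_tsv_path path to the depth TSV (may be empty).
#' @param reference a `reference_genome`.
#' @return Integer vector of length `reference$length` (class `depth_track`).
#' @export
read_depth <- function(depth_tsv_path, reference) {
  depth <- integer(reference$length)
  info <- file.info(depth_tsv_path)
  if (is.na(info$size)) stop("no such depth file: ", depth_tsv_path)
  if (info$size > 0) {
    tab <- read.table(depth_tsv_path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "pos", "depth"),
                      colClasses = c("character", "integer", "integer"))
    tab <- tab[tab$chrom == reference$sequence_id, , drop = FALSE]
    if (nrow(tab)) {
      if (any(tab$pos < 1L | tab$pos > reference$length))
        stop("depth position outside reference [1,", reference$length, "]")
      if (any(tab$depth < 0L)) stop("negative depth value")
      depth[tab$pos] <- tab$depth
    }
  }
  structure(depth, class = "depth_track", sequence_id = reference$sequence_id)
}

new_sample_profile <- function(sample_id, reference, calls, depth,
                               individual_id = sample_id, timepoint = "") {
  stopifnot(length(depth) == reference$length)
  calls <- calls[order(calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  if (anyDuplicated(calls$pos)) stop("more than one call at a position")
  if (nrow(calls) && (any(calls$pos < 1L) || any(calls$pos > reference$length)))
    stop("call position outside reference")
  if (nrow(calls) && any(calls$state < 1L))
    stop("stored calls must be non-reference (state >= 1)")
  structure(list(
    sample_id = sample_id, individual_id = individual_id,
    timepoint = timepoint, reference = reference,
    calls = calls, depth = as.integer(depth),
    breadth = mean(depth >= 1L),
    mean_depth = sum(as.numeric(depth)) / reference$length
  ), class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "<sample_profile> %s (indiv %s, t=%s) on %s: %d SNV calls, breadth %.3f, mean depth %.2f\n",
    x$sample_id, x$individual_id, x$timepoint, x$reference$species_id,
    nrow(x$calls), x$breadth, x$mean_depth))
  invisible(x)
}

#' Read sample profiles from a multi-sample VCF
#'
#' Builds one [sample profile][read_variant_profiles] per sample column of a
#' multi-sample VCF called against one species reference. A sample's variant
#' calls are the records where its genotype carries a non-reference allele;
#' haploid (`1`) and diploid-style (`0/1`, `1/1`) genotypes are both accepted,
#' the recorded state being the first non-reference allele index (dominant
#' strain semantics). Indel and other non-SNV records are skipped with a
#' warning. Breadth and mean depth are computed from the supplied depth
#' tracks, not from the VCF.
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF 4.x file.
#' @param reference a `reference_genome`; the VCF records must sit on
#'   `reference$sequence_id`.
#' @param sample_depths named list of depth tracks (see [read_depth()]), one
#'   per VCF sample.
#' @param sample_meta optional data.frame with columns `sample_id`,
#'   `individual_id`, `timepoint` attaching study metadata to samples.
#' @return list of `sample_profile`, one per VCF sample column.
#' @export
read_variant_profiles <- function(vcf_path, reference, sample_depths,
                                  sample_meta = NULL) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- as.character(GenomeInfoDb::seqnames(rr))
  if (length(rr) && !all(chroms == reference$sequence_id))
    stop("VCF chrom(s) [", paste(unique(chroms), collapse = ","),
         "] do not match reference ", reference$sequence_id)

  pos <- BiocGenerics::start(rr)
  ref_al <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_along(alt_list), function(i) as.character(alt_list[[i]]))

  is_snv <- nchar(ref_al) == 1L &
    vapply(alt_chr, function(a) length(a) >= 1L && all(nchar(a) == 1L), logical(1))
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0)
    warning(n_skipped, " non-SNV record(s) skipped (SNV-only analysis)")

  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  missing_depth <- setdiff(samples, names(sample_depths))
  if (length(missing_depth))
    stop("no depth track for sample(s): ", paste(missing_depth, collapse = ", "))

  keep <- which(is_snv)
  profiles <- lapply(samples, function(s) {
    depth <- sample_depths[[s]]
    states <- vapply(gt[keep, s], .gt_state, integer(1), USE.NAMES = FALSE)
    has_call <- !is.na(states) & states >= 1L
    idx <- keep[has_call]
    st <- states[has_call]
    calls <- data.frame(
      pos = pos[idx],
      ref = ref_al[idx],
      alt = vapply(seq_along(idx), function(j) {
        a <- alt_chr[[idx[j]]]
        a[min(st[j], length(a))]
      }, character(1)),
      state = st,
      dp = as.integer(depth)[pos[idx]],
      stringsAsFactors = FALSE
    )
    meta <- .sample_meta_row(sample_meta, s)
    new_sample_profile(s, reference, calls, as.integer(depth),
                       individual_id = meta$individual_id,
                       timepoint = meta$timepoint)
  })
  names(profiles) <- samples
  profiles
}

# first non-reference allele index of a GT string; NA when missing
.gt_state <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
  al <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
  al <- al[!is.na(al)]
  if (!length(al)) return(NA_integer_)
  nz <- al[al > 0L]
  if (length(nz)) nz[1] else 0L
}

.sample_meta_row <- function(sample_meta, s) {
  if (!is.null(sample_meta) && s %in% sample_meta$sample_id) {
    i <- match(s, sample_meta$sample_id)
    list(individual_id = as.character(sample_meta$individual_id[i]),
         timepoint = as.character(sample_meta$timepoint[i]))
  } else list(individual_id = s, timepoint = "")
}

#' Sample-level QC filter
#'
#' A sample is excluded from pairwise comparison when its breadth of coverage
#' or its mean depth against the species reference is too low. Thresholds are
#' strict: a sample fails iff `breadth < breadth_min` or
#' `mean_depth < depth_min`, so boundary values are retained.
#'
#' @param profile a `sample_profile`.
#' @param breadth_min minimum breadth of coverage (default 0.30).
#' @param depth_min minimum mean depth (default 3.5).
#' @param depth_over_covered if `TRUE`, mean depth is averaged over covered
#'   positions only instead of the whole reference (default `FALSE`,
#'   genome-wide mean).
#' @return A `qc_decision`: list with `sample_id`, `passed`, and a `reasons`
#'   data.frame (`metric`, `value`, `threshold`) that is empty iff passed.
#' @export
qc_filter <- function(profile, breadth_min = 0.30, depth_min = 3.5,
                      depth_over_covered = FALSE) {
  md <- if (depth_over_covered) {
    cov <- profile$depth >= 1L
    if (any(cov)) mean(profile$depth[cov]) else 0
  } else profile$mean_depth
  reasons <- data.frame(metric = character(), value = numeric(),
                        threshold = numeric(), stringsAsFactors = FALSE)
  if (profile$breadth < breadth_min)
    reasons <- rbind(reasons, data.frame(metric = "breadth",
                                         value = profile$breadth,
                                         threshold = breadth_min))
  if (md < depth_min)
    reasons <- rbind(reasons, data.frame(metric = "mean_depth",
                                         value = md, threshold = depth_min))
  structure(list(sample_id = profile$sample_id,
                 passed = nrow(reasons) == 0L, reasons = reasons),
            class = "qc_decision")
}

#' Merge sample profiles into one pooled sample
#'
#' Profile-level stand-in for pooling sequencing runs before variant calling
#' (e.g. merging all pre-treatment samples of an individual into a single
#' sample). Depth vectors are summed position-wise. At every position where
#' any input carries a variant call, the merged allele state is the
#' depth-weighted majority across inputs (inputs without a call vote for the
#' reference state with their site depth); ties go to the state held by the
#' input with the larger site depth, remaining ties to the lower allele
#' index. Breadth and mean depth are recomputed from the merged depth.
#'
#' @param profiles list of `sample_profile` on the same reference and
#'   individual.
#' @param sample_id id for the merged sample (default: ids joined by `+`).
#' @return a `sample_profile`.
#' @export
merge_profiles <- function(profiles, sample_id = NULL) {
  stopifnot(length(profiles) >= 1L)
  if (length(profiles) == 1L) {
    p <- profiles[[1]]
    return(new_sample_profile(p$sample_id, p$reference, p$calls, p$depth,
                              p$individual_id, p$timepoint))
  }
  seq_ids <- vapply(profiles, function(p) p$reference$sequence_id, character(1))
  if (length(unique(seq_ids)) != 1L)
    stop("cannot merge profiles on different references: ",
         paste(unique(seq_ids), collapse = ", "))
  indiv <- unique(vapply(profiles, function(p) p$individual_id, character(1)))
  if (length(indiv) != 1L)
    stop("cannot merge profiles from different individuals: ",
         paste(indiv, collapse = ", "))

  ref <- profiles[[1]]$reference
  depth <- Reduce(`+`, lapply(profiles, function(p) as.numeric(p$depth)))

  all_pos <- sort(unique(unlist(lapply(profiles, function(p) p$calls$pos))))
  rows <- lapply(all_pos, function(pp) {
    votes <- do.call(rbind, lapply(profiles, function(p) {
      i <- match(pp, p$calls$pos)
      sd <- as.numeric(p$depth[pp])
      if (is.na(i))
        data.frame(state = 0L, w = sd, sd = sd, ref = NA, alt = NA)
      else
        data.frame(state = p$calls$state[i], w = sd, sd = sd,
                   ref = p$calls$ref[i], alt = p$calls$alt[i])
    }))
    wsum <- tapply(votes$w, votes$state, sum)
    top <- as.integer(names(wsum)[wsum == max(wsum)])
    if (length(top) > 1L) {
      # tie: state of the deepest input, then lower allele index
      best_sd <- tapply(votes$sd, votes$state, max)[as.character(top)]
      top <- top[best_sd == max(best_sd)]
      top <- min(top)
    }
    if (top == 0L) return(NULL)
    src <- votes[votes$state == top & !is.na(votes$alt), , drop = FALSE][1, ]
    data.frame(pos = pp, ref = src$ref, alt = src$alt, state = top,
               dp = as.integer(depth[pp]), stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(pos = integer(), ref = character(), alt = character(),
                        state = integer(), dp = integer())
  if (is.null(sample_id))
    sample_id <- paste(vapply(profiles, `[[`, character(1), "sample_id"),
                       collapse = "+")
  new_sample_profile(sample_id, ref, calls, as.integer(round(depth)),
                     individual_id = indiv,
                     timepoint = paste(unique(vapply(
                       profiles, `[[`, character(1), "timepoint")),
                       collapse = "+"))
}
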