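#' Classify a WSS result against a species cutoff
#'
#' A pair is *related* (same dominant strain persisting) when its WSS score
#' is strictly above the species cutoff, and *unrelated* (strain replaced)
#' when the score is at or below it: related is defined strictly as
#' `score > cutoff`, so exact equality is labeled unrelated. Species without
#' a cutoff cannot be classified (`not_classifiable`, the `CO:NA` state, and
#' this takes precedence over a missing score); pairs without a score are
#' `no_score` (the `NS` state).
#'
#' @param result a `wss_result` (or any list with `score` and the pair ids).
#' @param cutoff species cutoff in (0,1), or `NA` when none is available.
#' @param dataset_id,comparison_label optional reporting keys (e.g. a study
#'   name and "pre vs post 2-month").
#' @param individual_a,individual_b optional individual ids for reporting.
#' @return A `strain_call`: the result fields plus `cutoff`, `label`,
#'   `dataset_id`, `comparison_label`.
#' @export
classify <- function(result, cutoff = NA_real_, dataset_id = NA_character_,
                     comparison_label = NA_character_,
                     individual_a = NA_character_,
                     individual_b = NA_character_) {
  label <- if (is.na(cutoff)) "not_classifiable"
  else if (is.na(result$score)) "no_score"
  else if (result$score > cutoff) "related"
  else "unrelated"
  structure(list(sample_a = result$sample_a, sample_b = result$sample_b,
                 species_id = result$species_id, score = result$score,
                 windows_used = result$windows_used %||% NA_integer_,
                 windows_total = result$windows_total %||% NA_integer_,
                 cutoff = cutoff, label = label, dataset_id = dataset_id,
                 comparison_label = comparison_label,
                 individual_a = individual_a, individual_b = individual_b),
            class = "strain_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a table of WSS scores
#'
#' Vectorized [classify()] over a scores table (as produced by
#' [pairwise_wss()]), joining per-species cutoffs.
#'
#' @param scores data.frame with at least `sample_a`, `sample_b`,
#'   `species_id`, `score` (optionally `individual_a`, `individual_b`).
#' @param cutoffs either a named numeric vector (names = species_id) or a
#'   data.frame with columns `species_id`, `cutoff`.
#' @param dataset_id,comparison_label reporting keys recycled across rows.
#' @return data.frame of calls, one row per score, with a `label` column.
#' @export
classify_table <- function(scores, cutoffs, dataset_id = NA_character_,
                           comparison_label = NA_character_) {
  if (is.data.frame(cutoffs))
    cutoffs <- setNames(as.numeric(cutoffs$cutoff), cutoffs$species_id)
  co <- unname(cutoffs[scores$species_id])
  label <- ifelse(is.na(co), "not_classifiable",
                  ifelse(is.na(scores$score), "no_score",
                         ifelse(scores$score > co, "related", "unrelated")))
  out <- scores
  out$cutoff <- co
  out$label <- label
  out$dataset_id <- dataset_id
  out$comparison_label <- comparison_label
  if (is.null(out$individual_a)) out$individual_a <- out$sample_a
  if (is.null(out$individual_b)) out$individual_b <- out$sample_b
  out
}

#' Summarize strain calls into per-group counts and percentages
#'
#' Per grouping cell: counts of related and unrelated pairs, their relative
#' abundance (%) over classifiable pairs, and the number of excluded pairs
#' (`not_classifiable` + `no_score`), which never enter the percentage
#' denominator. Percentages are `NA` when a group has no classifiable pair.
#'
#' @param calls data.frame of strain calls (see [classify_table()]).
#' @param group_by character vector of grouping columns present in `calls`.
#' @return data.frame with the grouping keys plus `n_related`,
#'   `n_unrelated`, `n_excluded`, `pct_related`, `pct_unrelated`.
#' @export
summarize_calls <- function(calls,
                            group_by = c("dataset_id", "species_id",
                                         "comparison_label")) {
  group_by <- intersect(group_by, names(calls))
  if (nrow(calls) == 0L) {
    out <- calls[, group_by, drop = FALSE]
    out$n_related <- integer(); out$n_unrelated <- integer()
    out$n_excluded <- integer()
    out$pct_related <- numeric(); out$pct_unrelated <- numeric()
    return(out)
  }
  keycols <- lapply(calls[, group_by, drop = FALSE], function(x)
    ifelse(is.na(x), "", as.character(x)))   # NA grouping values form a group
  key <- interaction(keycols, drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    g <- calls[key == k, , drop = FALSE]
    n_rel <- sum(g$label == "related")
    n_unrel <- sum(g$label == "unrelated")
    n_exc <- sum(g$label %in% c("not_classifiable", "no_score"))
    denom <- n_rel + n_unrel
    cbind(g[1, group_by, drop = FALSE],
          data.frame(n_related = n_rel, n_unrelated = n_unrel,
                     n_excluded = n_exc,
                     pct_related = if (denom > 0) 100 * n_rel / denom else NA_real_,
                     pct_unrelated = if (denom > 0) 100 * n_unrel / denom else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[, group_by, drop = FALSE]), , drop = FALSE]
}

#' Long-format plot table of strain calls
#'
#' Lossless reshaping of calls into the long table behind per-individual
#' score scatter plots: one row per call, deterministically sorted by
#' (species, individual, sample pair).
#'
#' @param calls data.frame of strain calls.
#' @return data.frame with columns `individual`, `species`, `sample_a`,
#'   `sample_b`, `score`, `cutoff`, `label`, `comparison`.
#' @export
export_plot_table <- function(calls) {
  out <- data.frame(individual = calls$individual_a,
                    species = calls$species_id,
                    sample_a = calls$sample_a, sample_b = calls$sample_b,
                    score = calls$score, cutoff = calls$cutoff,
                    label = calls$label,
                    comparison = calls$comparison_label,
                    stringsAsFactors = FALSE)
  out <- out[order(out$species, out$individual, out$sample_a, out$sample_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count individuals with at least one unrelated pair
#'
#' Per (dataset, species): the number of distinct individuals showing at
#' least one unrelated strain pair. An individual contributes at most once
#' per cell however many of its comparisons are unrelated.
#'
#' @param calls data.frame of strain calls with `dataset_id`, `species_id`,
#'   `individual_a`.
#' @return integer matrix, rows = datasets, columns = species.
#' @export
unrelated_count_matrix <- function(calls) {
  ds <- sort(unique(calls$dataset_id))
  sp <- sort(unique(calls$species_id))
  m <- matrix(0L, length(ds), length(sp), dimnames = list(ds, sp))
  u <- calls[calls$label == "unrelated", , drop = FALSE]
  if (nrow(u)) {
    key <- unique(u[, c("dataset_id", "species_id", "individual_a")])
    for (i in seq_len(nrow(key)))
      m[key$dataset_id[i], key$species_id[i]] <-
        m[key$dataset_id[i], key$species_id[i]] + 1L
  }
  m
}

#' Write / read a calls table with table sentinels
#'
#' TSV round-trip of a calls table preserving the field sentinels: a missing
#' score is written as `NS` and a missing cutoff as `CO:NA`.
#'
#' @param calls data.frame of strain calls.
#' @param path output TSV path.
#' @return `write_calls`: the path, invisibly. `read_calls`: the calls
#'   data.frame with numeric `score`/`cutoff` restored.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  out$score <- ifelse(is.na(out$score), "NS", format(out$score, digits = 15))
  out$cutoff <- ifelse(is.na(out$cutoff), "CO:NA",
                       format(out$cutoff, digits = 15))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "")
  tab$score <- suppressWarnings(as.numeric(ifelse(tab$score == "NS", NA,
                                                  tab$score)))
  tab$cutoff <- suppressWarnings(as.numeric(ifelse(tab$cutoff == "CO:NA", NA,
                                                   tab$cutoff)))
  for (col in intersect(c("windows_used", "windows_total"), names(tab)))
    tab[[col]] <- as.integer(tab[[col]])
  tab
}
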