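#' Tile a reference into analysis windows
#'
#' Non-overlapping fixed-size windows covering the whole reference; the last
#' window may be shorter. Coordinates are 0-based half-open internally
#' (window `i` covers 1-based positions `start+1 .. end`).
#'
#' @param reference_length reference length in bp (>= 1).
#' @param window_size window size in bp (default 1000).
#' @return data.frame with columns `index` (0-based), `start`, `end`, `size`.
#' @export
make_windows <- function(reference_length, window_size = 1000L) {
  if (reference_length < 1L || window_size < 1L)
    stop("reference_length and window_size must be positive")
  n <- ceiling(reference_length / window_size)
  start <- (seq_len(n) - 1L) * window_size
  end <- pmin(start + window_size, reference_length)
  data.frame(index = seq_len(n) - 1L, start = as.integer(start),
             end = as.integer(end), size = as.integer(end - start))
}

#' Pairwise window depth filter
#'
#' A window is excluded from the similarity computation when, in either
#' sample, strictly more than `low_frac` of its bases have read depth below
#' `site_depth_min`. Exactly half low is retained ("more than 50%" is
#' strict).
#'
#' @param depth_a,depth_b per-base depth vectors of the two samples.
#' @param window one row of [make_windows()] output (or any list with
#'   `start`, `end`).
#' @param site_depth_min per-base depth considered adequate (default 5).
#' @param low_frac maximum tolerated fraction of low-depth bases (default 0.5).
#' @return `TRUE` if the window is usable for this pair.
#' @export
window_passes_depth <- function(depth_a, depth_b, window,
                                site_depth_min = 5L, low_frac = 0.5) {
  idx <- (window$start + 1L):window$end
  fa <- mean(depth_a[idx] < site_depth_min)
  fb <- mean(depth_b[idx] < site_depth_min)
  !(fa > low_frac || fb > low_frac)
}

#' Per-window SNV similarity between two samples
#'
#' The comparison set is the union of the two samples' variant positions
#' inside the window, minus positions where either sample has no call *and*
#' site depth below `site_depth_min` (its state there is unknowable). At each
#' retained position a sample's state is its called allele index, or 0
#' (reference observed) when it has no call but adequate depth. Similarity is
#' the fraction of retained positions with equal states; with no retained
#' positions the window is uninformative and similarity is `NA`.
#'
#' @param profile_a,profile_b `sample_profile`s on the same reference.
#' @param window one row of [make_windows()] output.
#' @inheritParams window_passes_depth
#' @return list with `index`, `compared`, `matched`, `similarity`,
#'   `passed_depth_filter`.
#' @export
window_similarity <- function(profile_a, profile_b, window,
                              site_depth_min = 5L) {
  lo <- window$start + 1L; hi <- window$end
  pos <- sort(unique(c(
    profile_a$calls$pos[profile_a$calls$pos >= lo & profile_a$calls$pos <= hi],
    profile_b$calls$pos[profile_b$calls$pos >= lo & profile_b$calls$pos <= hi])))
  st <- .pair_states(profile_a, profile_b, pos, site_depth_min)
  compared <- sum(st$known)
  matched <- sum(st$known & st$a == st$b)
  list(index = window$index, compared = compared, matched = matched,
       similarity = if (compared > 0) matched / compared else NA_real_,
       passed_depth_filter = window_passes_depth(
         profile_a$depth, profile_b$depth, window, site_depth_min))
}

# states of two profiles at given positions; known = comparable position
.pair_states <- function(profile_a, profile_b, pos, site_depth_min) {
  ia <- match(pos, profile_a$calls$pos)
  ib <- match(pos, profile_b$calls$pos)
  a <- ifelse(is.na(ia), 0L, profile_a$calls$state[ia])
  b <- ifelse(is.na(ib), 0L, profile_b$calls$state[ib])
  known_a <- !is.na(ia) | profile_a$depth[pos] >= site_depth_min
  known_b <- !is.na(ib) | profile_b$depth[pos] >= site_depth_min
  list(a = a, b = b, known = known_a & known_b)
}

#' Window-based SNV similarity (WSS) score for one sample pair
#'
#' Genome-wide strain-relatedness score: the unweighted mean of per-window
#' SNV similarity over windows that (i) pass the pairwise depth filter and
#' (ii) contain at least one comparable variant position. If fewer than
#' `min_windows` windows are usable the pair has no score (`NS` state).
#'
#' @param profile_a,profile_b QC-passing `sample_profile`s on one reference.
#' @param windows window tiling from [make_windows()]; defaults to 1 kb
#'   windows over the shared reference.
#' @param min_windows minimum usable windows required to report a score.
#' @inheritParams window_passes_depth
#' @return A `wss_result`: list with `sample_a`, `sample_b`, `species_id`,
#'   `score` (`NA` when not computable), `windows_used`, `windows_total`.
#' @export
compute_wss <- function(profile_a, profile_b, windows = NULL,
                        min_windows = 1L, site_depth_min = 5L,
                        low_frac = 0.5) {
  if (profile_a$reference$sequence_id != profile_b$reference$sequence_id)
    stop("profiles are on different references")
  if (is.null(windows)) windows <- make_windows(profile_a$reference$length)

  pos <- sort(unique(c(profile_a$calls$pos, profile_b$calls$pos)))
  st <- .pair_states(profile_a, profile_b, pos, site_depth_min)

  # per-window count of low-depth bases via cumulative sums
  pass <- .window_pass_vec(profile_a$depth, profile_b$depth, windows,
                           site_depth_min, low_frac)

  wi <- findInterval(pos - 1L, windows$start)   # 1-based window row
  use <- st$known & pass[wi]
  score <- NA_real_
  used <- 0L
  if (any(use)) {
    m <- (st$a == st$b)[use]
    f <- factor(wi[use], levels = sort(unique(wi[use])))
    sims <- tapply(m, f, mean)
    used <- length(sims)
    if (used >= min_windows) score <- mean(sims)
  }
  if (used < min_windows) score <- NA_real_
  structure(list(sample_a = profile_a$sample_id,
                 sample_b = profile_b$sample_id,
                 species_id = profile_a$reference$species_id,
                 score = score, windows_used = used,
                 windows_total = nrow(windows)),
            class = "wss_result")
}

.window_pass_vec <- function(depth_a, depth_b, windows, site_depth_min,
                             low_frac) {
  ca <- c(0, cumsum(depth_a < site_depth_min))
  cb <- c(0, cumsum(depth_b < site_depth_min))
  la <- ca[windows$end + 1L] - ca[windows$start + 1L]
  lb <- cb[windows$end + 1L] - cb[windows$start + 1L]
  !(la / windows$size > low_frac | lb / windows$size > low_frac)
}

#' @export
print.wss_result <- function(x, ...) {
  cat(sprintf("<wss_result> %s vs %s (%s): score %s, windows %d/%d\n",
              x$sample_a, x$sample_b, x$species_id,
              ifelse(is.na(x$score), "NS", sprintf("%.4f", x$score)),
              x$windows_used, x$windows_total))
  invisible(x)
}

#' All-pairs WSS scores for one species
#'
#' Applies [qc_filter()] to every profile, then computes [compute_wss()] for
#' every unordered pair of passing profiles. With fewer than two passing
#' profiles an empty table is returned with a message.
#'
#' @param profiles list of `sample_profile` on one species reference.
#' @param windows window tiling; defaults to 1 kb windows.
#' @param breadth_min,depth_min sample QC thresholds (see [qc_filter()]).
#' @inheritParams compute_wss
#' @return data.frame with one row per unordered pair: `sample_a`,
#'   `sample_b`, `individual_a`, `individual_b`, `species_id`, `score`,
#'   `windows_used`, `windows_total`.
#' @export
pairwise_wss <- function(profiles, windows = NULL, breadth_min = 0.30,
                         depth_min = 3.5, min_windows = 1L,
                         site_depth_min = 5L, low_frac = 0.5) {
  empty <- data.frame(sample_a = character(), sample_b = character(),
                      individual_a = character(), individual_b = character(),
                      species_id = character(), score = numeric(),
                      windows_used = integer(), windows_total = integer(),
                      stringsAsFactors = FALSE)
  ok <- vapply(profiles, function(p)
    qc_filter(p, breadth_min, depth_min)$passed, logical(1))
  profiles <- profiles[ok]
  if (length(profiles) < 2L) {
    message("fewer than 2 QC-passing profiles; no pairs to score")
    return(empty)
  }
  # deterministic order regardless of input ordering
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  profiles <- profiles[order(ids)]
  if (is.null(windows)) windows <- make_windows(profiles[[1]]$reference$length)
  pairs <- combn(length(profiles), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- profiles[[ij[1]]]; b <- profiles[[ij[2]]]
    r <- compute_wss(a, b, windows, min_windows, site_depth_min, low_frac)
    data.frame(sample_a = r$sample_a, sample_b = r$sample_b,
               individual_a = a$individual_id, individual_b = b$individual_id,
               species_id = r$species_id, score = r$score,
               windows_used = r$windows_used, windows_total = r$windows_total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
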