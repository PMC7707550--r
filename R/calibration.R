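#' Collect related / unrelated calibration score pairs
#'
#' Emulates the reference-cohort calibration: WSS scores of within-individual
#' longitudinal pairs form the *related* class, scores of between-individual
#' pairs the *unrelated* class. Input profiles must carry `individual_id`.
#'
#' @param profiles list of QC-passing `sample_profile`s on one species, from
#'   at least two individuals.
#' @param windows window tiling (default 1 kb windows).
#' @inheritParams compute_wss
#' @return list with numeric vectors `related_scores` and `unrelated_scores`
#'   (NA scores dropped) and the underlying `pairs` table with a
#'   `provenance` column.
#' @export
collect_calibration_pairs <- function(profiles, windows = NULL,
                                      min_windows = 1L, site_depth_min = 5L,
                                      low_frac = 0.5) {
  tab <- pairwise_wss(profiles, windows, min_windows = min_windows,
                      site_depth_min = site_depth_min, low_frac = low_frac)
  if (nrow(tab) == 0L)
    return(list(related_scores = numeric(), unrelated_scores = numeric(),
                pairs = tab))
  tab$provenance <- ifelse(tab$individual_a == tab$individual_b,
                           "related", "unrelated")
  rel <- tab$score[tab$provenance == "related" & !is.na(tab$score)]
  unrel <- tab$score[tab$provenance == "unrelated" & !is.na(tab$score)]
  if (!length(unrel))
    message("no between-individual pairs: cutoff will be NA")
  list(related_scores = rel, unrelated_scores = unrel, pairs = tab)
}

#' Calibrate a per-species related/unrelated cutoff
#'
#' Estimates the score threshold separating the related (same individual)
#' from the unrelated (different individuals) WSS score distributions.
#' With fewer than `min_per_class` scores in either class no cutoff is
#' assigned (the `CO:NA` state). When the two classes are disjoint
#' (`max(unrelated) < min(related)`) the cutoff is the midpoint of the gap.
#' Otherwise it is the crossing point of Gaussian kernel density estimates of
#' the two classes (Silverman's rule-of-thumb bandwidth per class), searched
#' on a fixed 512-point grid between the two class means; among multiple
#' crossings the one closest to the midpoint of the class means is taken.
#' The procedure is deterministic.
#'
#' @param related_scores,unrelated_scores numeric vectors of WSS scores in
#'   \[0, 1\].
#' @param min_per_class minimum scores per class to attempt calibration.
#' @return A `cutoff_model`: list with `cutoff` (`NA` when not assignable),
#'   `method` (`"density_intersection"`, `"midpoint"` or `"none"`),
#'   `n_related`, `n_unrelated`, and the input score vectors.
#' @export
calibrate_cutoff <- function(related_scores, unrelated_scores,
                             min_per_class = 5L) {
  if (length(related_scores) && (min(related_scores) < 0 || max(related_scores) > 1))
    stop("related scores outside [0,1]")
  if (length(unrelated_scores) && (min(unrelated_scores) < 0 || max(unrelated_scores) > 1))
    stop("unrelated scores outside [0,1]")

  out <- list(cutoff = NA_real_, method = "none",
              n_related = length(related_scores),
              n_unrelated = length(unrelated_scores),
              related_scores = related_scores,
              unrelated_scores = unrelated_scores)
  class(out) <- "cutoff_model"
  if (length(related_scores) < min_per_class ||
      length(unrelated_scores) < min_per_class)
    return(out)

  m_rel <- mean(related_scores); m_unrel <- mean(unrelated_scores)
  if (m_rel == m_unrel) return(out)  # indistinguishable classes

  if (max(unrelated_scores) < min(related_scores)) {
    out$cutoff <- (max(unrelated_scores) + min(related_scores)) / 2
    out$method <- "midpoint"
    return(out)
  }

  lo <- min(m_rel, m_unrel); hi <- max(m_rel, m_unrel)
  grid <- seq(lo, hi, length.out = 512L)
  d_rel <- .kde_at(related_scores, grid)
  d_unrel <- .kde_at(unrelated_scores, grid)
  diff <- d_rel - d_unrel
  sgn <- sign(diff)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(cross)) {
    # densities never cross inside the mean interval: fall back to the point
    # of closest approach (rare; near-identical classes)
    out$cutoff <- grid[which.min(abs(diff))]
  } else {
    # linear interpolation of each sign change, pick closest to mean midpoint
    x <- vapply(cross, function(i) {
      grid[i] + (grid[i + 1] - grid[i]) * abs(diff[i]) /
        (abs(diff[i]) + abs(diff[i + 1]))
    }, numeric(1))
    out$cutoff <- x[which.min(abs(x - (lo + hi) / 2))]
  }
  # keep strictly inside the open mean interval
  out$cutoff <- min(max(out$cutoff, lo + 1e-12), hi - 1e-12)
  out$method <- "density_intersection"
  out
}

# Gaussian KDE evaluated at grid points; Silverman bandwidth with a floor so
# zero-variance classes still yield a finite density
.kde_at <- function(x, grid) {
  bw <- tryCatch(bw.nrd0(x), error = function(e) 0)
  bw <- max(bw, 1e-4)
  vapply(grid, function(g) mean(stats::dnorm((g - x) / bw)) / bw, numeric(1))
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf("<cutoff_model> cutoff %s (%s); n_related %d, n_unrelated %d\n",
              ifelse(is.na(x$cutoff), "CO:NA", sprintf("%.4f", x$cutoff)),
              x$method, x$n_related, x$n_unrelated))
  invisible(x)
}
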