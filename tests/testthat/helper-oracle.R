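# Independent brute-force oracles. Deliberately written as plain per-window /
# per-position loops, sharing no code with the package internals.

# state of one sample at one position: allele index, 0 = reference observed,
# NA = unknowable (no call and depth below site_depth_min)
oracle_state <- function(profile, pp, site_depth_min) {
  i <- which(profile$calls$pos == pp)
  if (length(i) == 1L) return(profile$calls$state[i])
  if (profile$depth[pp] >= site_depth_min) return(0L)
  NA_integer_
}

# whole-genome WSS by explicit per-window, per-position enumeration
oracle_wss <- function(a, b, window_size = 1000L, site_depth_min = 5L,
                       low_frac = 0.5, min_windows = 1L) {
  L <- a$reference$length
  n_win <- ceiling(L / window_size)
  sims <- numeric(0)
  for (w in seq_len(n_win)) {
    lo <- (w - 1L) * window_size + 1L
    hi <- min(w * window_size, L)
    fa <- sum(a$depth[lo:hi] < site_depth_min) / (hi - lo + 1L)
    fb <- sum(b$depth[lo:hi] < site_depth_min) / (hi - lo + 1L)
    if (fa > low_frac || fb > low_frac) next
    posns <- sort(unique(c(a$calls$pos, b$calls$pos)))
    posns <- posns[posns >= lo & posns <= hi]
    comp <- 0L; matched <- 0L
    for (pp in posns) {
      sa <- oracle_state(a, pp, site_depth_min)
      sb <- oracle_state(b, pp, site_depth_min)
      if (is.na(sa) || is.na(sb)) next
      comp <- comp + 1L
      if (sa == sb) matched <- matched + 1L
    }
    if (comp > 0L) sims <- c(sims, matched / comp)
  }
  if (length(sims) >= min_windows) mean(sims) else NA_real_
}

# KDE crossing point at 10x grid resolution via stats::density, the crossing
# closest to the midpoint of the class means
oracle_kde_crossing <- function(related, unrelated, n_grid = 5120L) {
  lo <- min(mean(related), mean(unrelated))
  hi <- max(mean(related), mean(unrelated))
  grid <- seq(lo, hi, length.out = n_grid)
  dr <- stats::density(related, bw = stats::bw.nrd0(related),
                       from = lo, to = hi, n = n_grid)$y
  du <- stats::density(unrelated, bw = stats::bw.nrd0(unrelated),
                       from = lo, to = hi, n = n_grid)$y
  dif <- dr - du
  s <- sign(dif)
  cross <- which(s[-1] * s[-length(s)] < 0)
  stopifnot(length(cross) >= 1L)
  x <- vapply(cross, function(i)
    grid[i] + (grid[i + 1] - grid[i]) * abs(dif[i]) /
      (abs(dif[i]) + abs(dif[i + 1])), numeric(1))
  x[which.min(abs(x - (lo + hi) / 2))]
}
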