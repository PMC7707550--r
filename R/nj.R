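#' Genome-wide SNV distance matrix across samples
#'
#' p-distances between all samples of one species: mismatched states divided
#' by compared positions over the whole genome, using the same comparison
#' rules as [window_similarity()] (union of variant positions, implicit
#' reference state where adequately covered, unknowable positions excluded)
#' but without windowing. Pairs with zero comparable positions get `NA`,
#' which [build_nj_tree()] rejects.
#'
#' @param profiles list of at least three `sample_profile`s on one species.
#' @inheritParams window_passes_depth
#' @return symmetric numeric matrix with zero diagonal, dimnames = sample
#'   ids, class `c("snv_dist", "matrix")`.
#' @export
snv_distance_matrix <- function(profiles, site_depth_min = 5L) {
  if (length(profiles) < 3L)
    stop("need at least 3 profiles for a distance matrix")
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- profiles[[i]]; b <- profiles[[j]]
    pos <- sort(unique(c(a$calls$pos, b$calls$pos)))
    st <- .pair_states(a, b, pos, site_depth_min)
    compared <- sum(st$known)
    d[i, j] <- d[j, i] <- if (compared > 0)
      sum(st$known & st$a != st$b) / compared else NA_real_
  }
  structure(d, class = c("snv_dist", "matrix"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining: iteratively join the pair minimizing the
#' Q-criterion, assign pendant branch lengths, and reduce the matrix until
#' three nodes remain. Negative branch lengths (possible on non-additive
#' input) are clamped to zero with the deficit moved to the sister branch so
#' the joined pair's path length is preserved. On additive matrices the
#' leaf-to-leaf path distances of the returned tree reproduce the input
#' exactly (up to round-off).
#'
#' @param d complete symmetric distance matrix (>= 3 taxa) with dimnames, as
#'   from [snv_distance_matrix()].
#' @return an unrooted `phylo` tree (ape-compatible) with branch lengths.
#' @export
build_nj_tree <- function(d) {
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa for neighbor joining")
  if (anyNA(d)) stop("distance matrix has missing entries")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # node bookkeeping: tips are 1..n; internal nodes get ids n+1, n+2, ...
  active <- seq_len(n)
  next_id <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  D <- d

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]  # deterministic tie-break
    i <- min(k); j <- max(k)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }   # deficit to sister
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, li, lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D, du), c(du, 0))
    keep <- setdiff(seq_len(m + 1L), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    active <- c(active, u)[keep]
  }

  # final star join of the last three nodes
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  br <- pmax(c(a, b, c3), 0)
  u <- next_id
  edges <- rbind(edges, c(u, active[1]), c(u, active[2]), c(u, active[3]))
  lens <- c(lens, br)

  .as_phylo(edges, lens, labels, n_tips = n, root = u)
}

# orient edges away from `root` and renumber internals to ape convention
.as_phylo <- function(edges, lens, labels, n_tips, root) {
  adj <- split(rep(seq_len(nrow(edges)), 2L),
               factor(c(edges[, 1], edges[, 2]),
                      levels = seq_len(max(edges))))
  adj <- lapply(adj, unique)
  n_nodes <- max(edges)
  newid <- integer(n_nodes)
  newid[seq_len(n_tips)] <- seq_len(n_tips)
  counter <- n_tips
  out_e <- matrix(0L, 0, 2); out_l <- numeric(0)
  # iterative preorder DFS from root
  stack <- list(list(node = root, from = 0L))
  while (length(stack)) {
    cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- cur$node
    if (v > n_tips) { counter <- counter + 1L; newid[v] <- counter }
    for (ei in adj[[v]]) {
      w <- if (edges[ei, 1] == v) edges[ei, 2] else edges[ei, 1]
      if (w == cur$from) next
      out_e <- rbind(out_e, c(v, w)); out_l <- c(out_l, lens[ei])
      stack[[length(stack) + 1L]] <- list(node = w, from = v)
    }
  }
  edge <- cbind(newid[out_e[, 1]], newid[out_e[, 2]])
  storage.mode(edge) <- "integer"
  structure(list(edge = edge, edge.length = out_l, tip.label = labels,
                 Nnode = counter - n_tips),
            class = "phylo", order = "cladewise")
}

#' Tree-based relatedness call for a sample pair
#'
#' Two samples are called related when the branch-length path distance
#' between their leaves is strictly below `threshold`. The default 0.001 is
#' the branch-length criterion used on marker-gene trees; on genome-wide
#' p-distance trees the appropriate threshold scales with the SNV distance
#' scale and should be set explicitly (e.g. `1 - cutoff` for a WSS cutoff).
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param sample_a,sample_b leaf labels.
#' @param threshold strict path-distance threshold (default 0.001).
#' @return `"related"` or `"unrelated"`.
#' @export
tree_relatedness <- function(tree, sample_a, sample_b, threshold = 0.001) {
  if (!all(c(sample_a, sample_b) %in% tree$tip.label))
    stop("unknown leaf: ",
         paste(setdiff(c(sample_a, sample_b), tree$tip.label), collapse = ", "))
  if (sample_a == sample_b) return("related")
  pd <- ape::cophenetic.phylo(tree)[sample_a, sample_b]
  if (pd < threshold) "related" else "unrelated"
}

#' Agreement between WSS calls and tree calls
#'
#' Matches two call sets on unordered sample pairs and reports the fraction
#' of pairs with identical labels plus the 2x2 related/unrelated
#' contingency.
#'
#' @param wss_calls,tree_calls data.frames with columns `sample_a`,
#'   `sample_b`, `label` (labels `related`/`unrelated`).
#' @return list with `agreement` (fraction), `n` (pairs compared) and
#'   `contingency` (2x2 table, rows = WSS, cols = tree).
#' @export
method_agreement <- function(wss_calls, tree_calls) {
  key <- function(x) paste(pmin(x$sample_a, x$sample_b),
                           pmax(x$sample_a, x$sample_b), sep = "\r")
  kw <- key(wss_calls); kt <- key(tree_calls)
  if (!setequal(kw, kt) || anyDuplicated(kw) || anyDuplicated(kt))
    stop("call sets are not keyed by the same sample pairs; unmatched: ",
         paste(gsub("\r", " vs ", union(setdiff(kw, kt), setdiff(kt, kw))),
               collapse = ", "))
  lw <- wss_calls$label[order(kw)]
  lt <- tree_calls$label[order(kt)]
  lv <- c("related", "unrelated")
  list(agreement = mean(lw == lt), n = length(lw),
       contingency = table(wss = factor(lw, lv), tree = factor(lt, lv)))
}
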