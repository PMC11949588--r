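# normalize mask input: accept sorted integer indices or a binary vector
as_edge_set <- function(x, name = "mask") {
  if (is.logical(x) || (is.numeric(x) && length(x) > 1 &&
                        all(x %in% c(0, 1)) && any(x == 0))) {
    which(as.logical(x))
  } else {
    sort(unique(as.integer(x)))
  }
}

#' Edge-set overlap and unique edges of two masks
#'
#' Counts the edges shared by two binary edge masks and exposes the unique
#' (set-difference) edge sets used for the unique-feature analyses.
#'
#' @param mask_a,mask_b Edge masks: integer edge indices, or binary 0/1
#'   vectors of equal length.
#' @return List: `x` (shared count), `shared`, `only_a`, `only_b` (edge
#'   indices), `K` and `N` (mask sizes).
#' @examples
#' mask_overlap(c(1, 2, 3), c(3, 4))$x
#' @export
mask_overlap <- function(mask_a, mask_b) {
  if ((is.logical(mask_a) || all(mask_a %in% c(0, 1))) &&
      (is.logical(mask_b) || all(mask_b %in% c(0, 1))) &&
      length(mask_a) > 2 && length(mask_b) > 2 &&
      length(mask_a) != length(mask_b)) {
    stop_input("binary masks must have equal length")
  }
  a <- as_edge_set(mask_a)
  b <- as_edge_set(mask_b)
  shared <- intersect(a, b)
  list(x = length(shared), shared = shared,
       only_a = setdiff(a, b), only_b = setdiff(b, a),
       K = length(a), N = length(b))
}

#' Upper-tail hypergeometric probability of an edge-mask overlap
#'
#' Probability of observing strictly more than `x` shared edges when two
#' masks of sizes `K` and `N` are drawn at random without replacement from
#' `M` edges: `p = P(X > x)` for `X ~ Hypergeometric(M, K, N)`. Note the
#' strict inequality — the observed count itself is excluded, matching the
#' `1 - hygcdf(x, M, K, N)` convention.
#'
#' @param x Observed shared-edge count.
#' @param M Total number of edges (35,778 for a 268-node parcellation).
#' @param K,N Sizes of the two masks.
#' @return Upper-tail probability.
#' @examples
#' hypergeom_overlap_p(21, 35778, 630, 659)  # 3.52e-3
#' @export
hypergeom_overlap_p <- function(x, M, K, N) {
  if (K > M || N > M) stop_input("mask sizes cannot exceed M")
  if (x > min(K, N) || x < 0) stop_input("x must lie in 0..min(K, N)")
  phyper(x, K, M - K, N, lower.tail = FALSE)
}

#' Overlap test between two edge masks
#'
#' Combines [mask_overlap()] and [hypergeom_overlap_p()] into the overlap
#' record reported for network pairs.
#'
#' @inheritParams mask_overlap
#' @param M Total number of edges in the connectome.
#' @return One-row tibble: `x`, `M`, `K`, `N`, `p`.
#' @export
overlap_test <- function(mask_a, mask_b, M) {
  ov <- mask_overlap(mask_a, mask_b)
  tibble::tibble(x = ov$x, M = M, K = ov$K, N = ov$N,
                 p = hypergeom_overlap_p(ov$x, M, ov$K, ov$N))
}

# per-block edge counts of a mask under a node grouping; returns a
# groups x groups symmetric count matrix (upper storage mirrored)
block_counts <- function(edge_idx, groups, n_nodes, levels) {
  counts <- matrix(0L, length(levels), length(levels),
                   dimnames = list(levels, levels))
  if (length(edge_idx) == 0) return(counts)
  pr <- edge_pair(edge_idx, n_nodes)
  ga <- groups[pr$i]
  gb <- groups[pr$j]
  lo <- pmin(match(ga, levels), match(gb, levels))
  hi <- pmax(match(ga, levels), match(gb, levels))
  L <- length(levels)
  counts <- matrix(tabulate((hi - 1L) * L + lo, nbins = L * L), L, L,
                   dimnames = list(levels, levels))
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  counts
}

# possible edges per block: n_a * n_b off-diagonal, n_a(n_a-1)/2 within
block_sizes <- function(groups, levels) {
  n_per <- vapply(levels, function(l) sum(groups == l), integer(1))
  sz <- outer(n_per, n_per)
  base::diag(sz) <- n_per * (n_per - 1) / 2
  dimnames(sz) <- list(levels, levels)
  sz
}

#' Canonical-network contribution matrix with shuffle significance
#'
#' Summarizes where a model's predictive edges fall anatomically. For every
#' pair of node groups (canonical networks, or lobes with a lobe atlas) the
#' cell value is the number of positive-mask edges minus the number of
#' negative-mask edges in that block, normalized by the number of possible
#' edges in the block (`"block"`, default) or by the total attention-network
#' size (`"mask"`, `|pos| + |neg|`). Positive cells mean over-representation
#' in the high-attention network. Significance per cell comes from shuffling
#' edge identities within each mask separately — redrawing masks of the same
#' sizes uniformly from all edges — `n_perm` times; the two-sided empirical
#' p is `2 * min(P(null <= obs), P(null >= obs))` with the add-one
#' correction, uncorrected for multiple cells.
#'
#' @param pos_edges,neg_edges Edge masks (indices or binary).
#' @param atlas Tibble with columns `node` and `network` (use a lobe column
#'   renamed to `network` for lobe-level grouping).
#' @param n_nodes Parcellation size.
#' @param n_perm Number of shuffles.
#' @param seed Integer seed.
#' @param normalizer `"block"` or `"mask"`.
#' @return Object of class `cpm_contribution`: `contribution` and `p`
#'   (group x group matrices), `counts_pos`, `counts_neg`, `block_n`,
#'   `n_perm`, `seed`.
#' @export
contribution_matrix <- function(pos_edges, neg_edges, atlas, n_nodes,
                                n_perm = 1000, seed = 1,
                                normalizer = c("block", "mask")) {
  normalizer <- match.arg(normalizer)
  pos <- as_edge_set(pos_edges)
  neg <- as_edge_set(neg_edges)
  if (!all(c("node", "network") %in% names(atlas))) {
    stop_input("atlas needs columns `node` and `network`")
  }
  if (!all(seq_len(n_nodes) %in% atlas$node)) {
    miss <- setdiff(seq_len(n_nodes), atlas$node)[1]
    stop_input("node %d has no atlas label", miss)
  }
  groups <- atlas$network[match(seq_len(n_nodes), atlas$node)]
  levels <- sort(unique(groups))
  E <- n_edges(n_nodes)

  norm_mat <- switch(normalizer,
    block = block_sizes(groups, levels),
    mask = matrix(length(pos) + length(neg), length(levels), length(levels),
                  dimnames = list(levels, levels)))
  norm_mat[norm_mat == 0] <- NA  # empty blocks have no defined contribution

  cell_stat <- function(p_idx, n_idx) {
    (block_counts(p_idx, groups, n_nodes, levels) -
       block_counts(n_idx, groups, n_nodes, levels)) / norm_mat
  }
  obs <- cell_stat(pos, neg)

  ge <- le <- matrix(0L, length(levels), length(levels))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      null <- cell_stat(sample.int(E, length(pos)),
                        sample.int(E, length(neg)))
      ge <- ge + (null >= obs)
      le <- le + (null <= obs)
    }
  })
  pmat <- 2 * pmin((ge + 1) / (n_perm + 1), (le + 1) / (n_perm + 1))
  pmat[pmat > 1] <- 1
  dimnames(pmat) <- dimnames(obs)

  structure(
    list(contribution = obs, p = pmat,
         counts_pos = block_counts(pos, groups, n_nodes, levels),
         counts_neg = block_counts(neg, groups, n_nodes, levels),
         block_n = block_sizes(groups, levels),
         normalizer = normalizer, n_perm = n_perm, seed = seed),
    class = "cpm_contribution"
  )
}

#' @export
print.cpm_contribution <- function(x, ...) {
  cat(sprintf("<cpm_contribution> %d groups, %d shuffles, normalizer = %s\n",
              nrow(x$contribution), x$n_perm, x$normalizer))
  print(round(x$contribution, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cpm_contribution <- function(x, ...) {
  lv <- rownames(x$contribution)
  grid <- expand.grid(network_a = lv, network_b = lv,
                      stringsAsFactors = FALSE)
  keep <- match(grid$network_a, lv) <= match(grid$network_b, lv)
  grid <- grid[keep, ]
  tibble::tibble(
    network_a = grid$network_a, network_b = grid$network_b,
    contribution = x$contribution[cbind(grid$network_a, grid$network_b)],
    n_pos = x$counts_pos[cbind(grid$network_a, grid$network_b)],
    n_neg = x$counts_neg[cbind(grid$network_a, grid$network_b)],
    p = x$p[cbind(grid$network_a, grid$network_b)]
  )
}
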