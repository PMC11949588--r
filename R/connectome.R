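#' Number of unique edges in an n-node connectome
#'
#' An undirected functional connectome on `n` nodes has `n * (n - 1) / 2`
#' unique edges (the strict upper triangle of the symmetric matrix). With the
#' 268-node parcellation used throughout, this is 35,778.
#'
#' @param n_nodes Number of parcellation nodes.
#' @return Integer edge count.
#' @examples
#' n_edges(268)
#' @export
n_edges <- function(n_nodes) {
  if (length(n_nodes) != 1 || is.na(n_nodes) || n_nodes < 2 ||
      n_nodes != round(n_nodes)) {
    stop_input("`n_nodes` must be a single integer >= 2, got %s", n_nodes[1])
  }
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' Canonical edge indexing for the upper triangle
#'
#' Maps a node pair (i, j), i < j, to its position in the canonical edge
#' vector and back. The canonical order is row-major over the strict upper
#' triangle: (1,2), (1,3), ..., (1,n), (2,3), ... Node and edge indices are
#' 1-based. The mapping is a bijection, so every edgewise statistic in the
#' package refers to the same flattening.
#'
#' @param i,j Node indices with `i < j` (vectorized).
#' @param k Edge indices in 1..n_edges(n_nodes) (vectorized).
#' @param n_nodes Number of nodes.
#' @return `edge_index()`: integer edge indices. `edge_pair()`: a tibble with
#'   columns `i`, `j`.
#' @examples
#' edge_index(1, 2, 268)     # first edge
#' edge_pair(35778, 268)     # last edge is (267, 268)
#' @export
edge_index <- function(i, j, n_nodes) {
  if (any(i >= j) || any(i < 1) || any(j > n_nodes)) {
    stop_input("edge_index requires 1 <= i < j <= n_nodes")
  }
  as.integer((i - 1) * n_nodes - i * (i - 1) / 2 + (j - i))
}

#' @rdname edge_index
#' @export
edge_pair <- function(k, n_nodes) {
  E <- n_edges(n_nodes)
  if (any(k < 1) || any(k > E)) {
    stop_input("edge index out of range 1..%d", E)
  }
  # edges before row i: offset(i) = (i-1)*n - i*(i-1)/2
  offsets <- vapply(seq_len(n_nodes - 1), function(i) {
    (i - 1) * n_nodes - i * (i - 1) / 2
  }, numeric(1))
  i <- findInterval(k - 1, offsets)
  j <- i + (k - offsets[i])
  tibble::tibble(i = as.integer(i), j = as.integer(j))
}

#' Vectorize a connectome into the canonical edge order, and back
#'
#' `vectorize_edges()` extracts the strict upper triangle of a symmetric
#' matrix in canonical row-major order (see [edge_index()]).
#' `matrixify_edges()` is its inverse, rebuilding a symmetric matrix with a
#' chosen diagonal. The round trip is lossless for off-diagonal content.
#'
#' @param m Symmetric numeric matrix.
#' @param e Numeric edge vector of length `n_edges(n_nodes)`.
#' @param n_nodes Number of nodes for the rebuilt matrix.
#' @param diag Value placed on the diagonal of the rebuilt matrix.
#' @return `vectorize_edges()`: numeric vector; `matrixify_edges()`: symmetric
#'   matrix.
#' @export
vectorize_edges <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_input("`m` must be a square matrix")
  }
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop_input("`m` must be symmetric")
  }
  # row-major upper triangle of m == column-major lower triangle of t(m)
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' @rdname vectorize_edges
#' @export
matrixify_edges <- function(e, n_nodes, diag = 0) {
  E <- n_edges(n_nodes)
  if (length(e) != E) {
    stop_input("edge vector has length %d; expected %d for %d nodes",
               length(e), E, n_nodes)
  }
  m <- matrix(0, n_nodes, n_nodes)
  m[lower.tri(m)] <- e          # fills t(m)'s upper triangle row-major
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  base::diag(m) <- diag
  m
}

#' Functional connectome from parcellated time series
#'
#' Computes the pairwise Pearson correlation of node time courses — the
#' functional connectivity matrix for one run — with an optional Fisher
#' z-transform (`atanh`) of the off-diagonal entries. Correlations of
#' magnitude 1 (e.g., duplicated nodes) are clipped to `1 - 1e-7` before the
#' transform so z stays finite while preserving edge order.
#'
#' @param ts Numeric matrix, nodes x timepoints.
#' @param transform `"fisher"` (default) or `"raw"`.
#' @return Symmetric nodes x nodes matrix with attribute `"transform"`.
#'   Diagonal is 1 for `"raw"` and 0 for `"fisher"`.
#' @examples
#' ts <- matrix(rnorm(5 * 20), 5, 20)
#' cm <- compute_connectome(ts)
#' length(vectorize_edges(cm))  # 10 edges for 5 nodes
#' @export
compute_connectome <- function(ts, transform = c("fisher", "raw")) {
  transform <- match.arg(transform)
  if (!is.matrix(ts) || !is.numeric(ts)) {
    stop_input("`ts` must be a numeric nodes x timepoints matrix")
  }
  if (ncol(ts) < 3) stop_input("need >= 3 timepoints, got %d", ncol(ts))
  sds <- apply(ts, 1, sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- which(sds == 0 | is.na(sds))[1]
    stop_input("node %d has a constant time course; correlation undefined", bad)
  }
  r <- cor(t(ts))
  if (transform == "fisher") {
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
    r <- atanh(r)
    base::diag(r) <- 0
  } else {
    base::diag(r) <- 1
  }
  attr(r, "transform") <- transform
  r
}

#' Read atlas labels mapping nodes to canonical networks and lobes
#'
#' Expects a delimited file with columns `node`, `network` and optionally
#' `lobe`. Node numbering may be 0- or 1-based; 0-based input is shifted up
#' and the convention recorded in the `"origin"` attribute. Every node must
#' be labeled exactly once.
#'
#' @param path CSV file path.
#' @return Tibble with columns `node`, `network` (and `lobe` if present).
#' @export
read_atlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("node", "network") %in% names(df))) {
    stop_input("atlas file must have columns `node` and `network`")
  }
  origin <- if (min(df$node) == 0) 0L else 1L
  if (origin == 0L) df$node <- df$node + 1L
  if (anyDuplicated(df$node)) {
    stop_input("node %d labeled more than once", df$node[duplicated(df$node)][1])
  }
  out <- tibble::as_tibble(df[order(df$node), , drop = FALSE])
  attr(out, "origin") <- origin
  out
}
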