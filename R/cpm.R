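#' Edgewise feature selection for connectome-based predictive modeling
#'
#' For every edge, correlates edge strength with behavior across runs
#' (Pearson) and selects edges whose two-tailed p-value from the t
#' distribution falls strictly below `alpha`, split by correlation sign:
#' positive-network ("high attention") edges correlate positively with
#' performance, negative-network ("low attention") edges negatively. With a
#' covariate, the partial Pearson correlation is used (both edge and
#' behavior residualized on the covariate; degrees of freedom reduced
#' accordingly) — the construction used when retraining networks while
#' partialing out the other modality's performance.
#'
#' @param edges Numeric runs x E matrix of edge values.
#' @param behavior Numeric per-run behavior vector.
#' @param alpha Selection threshold on the two-tailed p-value (strict `<`).
#' @param covariate Optional per-run vector (or matrix of columns) to
#'   partial out of the edge-behavior correlations.
#' @return List of class `edge_selection`: `pos` and `neg` (sorted integer
#'   edge indices), `r` and `p` (per-edge statistics), `n` (runs), `alpha`.
#' @export
select_edges <- function(edges, behavior, alpha = 0.01, covariate = NULL) {
  if (!is.matrix(edges)) stop_input("`edges` must be a runs x E matrix")
  n <- nrow(edges)
  if (length(behavior) != n) {
    stop_input("behavior length %d != %d runs", length(behavior), n)
  }
  if (n < 4) stop_input("need >= 4 runs for edge selection")
  if (sd(behavior) == 0) stop_input("behavior is constant")
  q <- 0L
  if (!is.null(covariate)) {
    covariate <- as.matrix(covariate)
    if (nrow(covariate) != n) stop_input("covariate length mismatch")
    if (any(apply(covariate, 2, sd) == 0)) {
      stop_input("constant covariate")
    }
    q <- ncol(covariate)
    # residualize behavior and every edge on the covariate(s)
    Q <- qr.Q(qr(cbind(1, covariate)))
    behavior <- behavior - Q %*% crossprod(Q, behavior)
    edges_r <- edges - Q %*% crossprod(Q, edges)
  } else {
    edges_r <- edges
  }
  sds <- matrixStats_colSds(edges_r)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warn(sprintf("%d constant edge(s) never selected", sum(const)))
  }
  r <- unname(suppressWarnings(cor(edges_r, behavior))[, 1])
  r[const] <- NA_real_
  df <- n - 2 - q
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  sel <- !is.na(p) & p < alpha
  structure(
    list(pos = which(sel & r > 0), neg = which(sel & r < 0),
         r = r, p = p, n = n, alpha = alpha,
         covariate = if (q > 0) q else NULL),
    class = "edge_selection"
  )
}

# column SDs without a hard dependency
matrixStats_colSds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(colSums(m^2) - n * mu^2, 0) / (n - 1))
}

#' Construct a CPM model from edge masks
#'
#' A fitted connectome-based predictive model is the pair of binary edge
#' masks (stored sparsely as edge indices), the linear calibration
#' `predicted = m * strength + b`, and training metadata. Masks must be
#' disjoint: an edge correlates with behavior with one sign only.
#'
#' @param pos_edges,neg_edges Integer edge indices (canonical order) of the
#'   positive (high-attention) and negative (low-attention) networks.
#' @param n_nodes Parcellation size the indices refer to.
#' @param alpha Selection threshold used in training (metadata).
#' @param m,b Calibration slope and intercept.
#' @param metadata Named list of training provenance (n runs, modality,
#'   covariate, seed, ...).
#' @return Object of class `cpm_model`.
#' @export
cpm_model <- function(pos_edges, neg_edges, n_nodes, alpha = 0.01,
                      m = 1, b = 0, metadata = list()) {
  pos_edges <- sort(unique(as.integer(pos_edges)))
  neg_edges <- sort(unique(as.integer(neg_edges)))
  E <- n_edges(n_nodes)
  if (length(pos_edges) && (min(pos_edges) < 1 || max(pos_edges) > E) ||
      length(neg_edges) && (min(neg_edges) < 1 || max(neg_edges) > E)) {
    stop_input("edge indices out of range 1..%d", E)
  }
  if (length(intersect(pos_edges, neg_edges)) > 0) {
    stop_input("positive and negative masks must be disjoint")
  }
  structure(
    list(pos_edges = pos_edges, neg_edges = neg_edges,
         n_nodes = as.integer(n_nodes), alpha = alpha, m = m, b = b,
         metadata = metadata),
    class = "cpm_model"
  )
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf("<cpm_model> %d nodes; %d positive / %d negative edges (alpha = %g)\n",
              x$n_nodes, length(x$pos_edges), length(x$neg_edges), x$alpha))
  cat(sprintf("  calibration: predicted = %.4g * strength + %.4g\n", x$m, x$b))
  invisible(x)
}

#' Train a CPM on run-level connectomes and behavior
#'
#' Runs edge selection at `alpha`, computes network strength on the
#' training runs, and fits the linear calibration of behavior on strength.
#' The training unit is the run: multiple runs per subject enter as
#' separate observations, matching external-validation practice for these
#' models.
#'
#' @inheritParams select_edges
#' @param n_nodes Parcellation size; inferred from `ncol(edges)` if omitted.
#' @param modality Optional label stored in metadata.
#' @return A [cpm_model()].
#' @examples
#' coh <- generate_cohort(cohort_config(n_nodes = 20, n_pos_edges = 6,
#'   n_neg_edges = 6, n_shared_pos = 2, n_shared_neg = 2,
#'   n_runs_per_modality = 30, effect_size = 0.6, seed = 2))
#' vis <- coh$runs$modality == "visual"
#' fit <- train_cpm(coh$edges[vis, ], coh$runs$behavior[vis])
#' fit
#' @export
train_cpm <- function(edges, behavior, alpha = 0.01, covariate = NULL,
                      n_nodes = NULL, modality = NULL) {
  if (is.null(n_nodes)) {
    # invert E = n(n-1)/2
    n_nodes <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
    if (n_nodes != round(n_nodes)) {
      stop_input("ncol(edges) = %d is not a triangular number; give `n_nodes`",
                 ncol(edges))
    }
  }
  sel <- select_edges(edges, behavior, alpha = alpha, covariate = covariate)
  if (length(sel$pos) == 0 || length(sel$neg) == 0) {
    stop_input("selection produced an empty %s mask at alpha = %g",
               if (length(sel$pos) == 0) "positive" else "negative", alpha)
  }
  model <- cpm_model(sel$pos, sel$neg, n_nodes = n_nodes, alpha = alpha,
                     metadata = list(n_runs = nrow(edges),
                                     modality = modality,
                                     covariate = !is.null(covariate)))
  s <- network_strength(edges, model)
  cal <- fit_calibration(s, behavior)
  model$m <- cal[["m"]]
  model$b <- cal[["b"]]
  model
}

#' Network strength of runs under a CPM
#'
#' Network strength is the mean edge value inside the positive
#' (high-attention) mask minus the mean inside the negative (low-attention)
#' mask — the single summary that CPM predictions are a linear function of.
#'
#' @param edges Edge vector (length E) or runs x E matrix.
#' @param model A [cpm_model()].
#' @return Numeric strength, one value per run.
#' @export
network_strength <- function(edges, model) {
  if (!inherits(model, "cpm_model")) stop_input("`model` must be a cpm_model")
  if (length(model$pos_edges) == 0 || length(model$neg_edges) == 0) {
    stop_input("network strength undefined for an empty mask")
  }
  if (!is.matrix(edges)) edges <- matrix(edges, nrow = 1)
  E <- n_edges(model$n_nodes)
  if (ncol(edges) != E) {
    stop_input("edge vector length %d != model's %d", ncol(edges), E)
  }
  rowMeans(edges[, model$pos_edges, drop = FALSE]) -
    rowMeans(edges[, model$neg_edges, drop = FALSE])
}

#' Linear calibration of behavior on network strength
#'
#' Ordinary least squares of observed behavior on training-set network
#' strength; the slope/intercept pair makes predictions behavior-scaled.
#' Because the calibration is monotone (for positive slope), rank
#' correlations between predicted and observed behavior equal those between
#' raw strength and observed behavior.
#'
#' @param strengths,behavior Per-run numeric vectors.
#' @return Named numeric `c(m = slope, b = intercept)`.
#' @export
fit_calibration <- function(strengths, behavior) {
  if (length(strengths) < 2) stop_input("need >= 2 runs")
  if (sd(strengths) == 0) stop_input("constant strengths; slope undefined")
  fit <- lm(behavior ~ strengths)
  c(m = unname(coef(fit)[2]), b = unname(coef(fit)[1]))
}

#' Predict from a CPM
#'
#' Computes per-run network strength under the model's masks, optionally
#' z-scored across the supplied runs (the within-dataset normalization used
#' when comparing predictions across datasets), and optionally mapped
#' through the linear calibration to the behavior scale.
#'
#' @param object A [cpm_model()].
#' @param edges Runs x E matrix (or single edge vector).
#' @param normalize Z-score strengths across the supplied runs (sample SD).
#' @param type `"strength"` (default) or `"behavior"` (apply calibration).
#' @param ... Unused.
#' @return Numeric vector, one value per run.
#' @export
predict.cpm_model <- function(object, edges, normalize = FALSE,
                              type = c("strength", "behavior"), ...) {
  type <- match.arg(type)
  s <- network_strength(edges, object)
  if (normalize) {
    if (length(s) < 2) stop_input("cannot normalize a single run")
    s <- (s - mean(s)) / sd(s)
  }
  if (type == "behavior") s <- object$m * s + object$b
  s
}

#' Serialize and read CPM models
#'
#' Models are stored as JSON holding sparse edge-index masks, the
#' parcellation size, threshold, calibration, and metadata.
#' `read_edge_pairs()` ingests published masks distributed as two-column
#' 1-based (i, j) node-pair lists and returns canonical edge indices.
#'
#' @param model A [cpm_model()].
#' @param path File path.
#' @param n_nodes Parcellation size for pair-list conversion.
#' @return `read_cpm_model()`: a `cpm_model`; `read_edge_pairs()`: integer
#'   edge indices.
#' @export
write_cpm_model <- function(model, path) {
  jsonlite::write_json(
    list(n_nodes = model$n_nodes, alpha = model$alpha,
         pos_edges = model$pos_edges, neg_edges = model$neg_edges,
         m = model$m, b = model$b, metadata = model$metadata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cpm_model
#' @export
read_cpm_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cpm_model(x$pos_edges, x$neg_edges, n_nodes = x$n_nodes,
            alpha = x$alpha %||% 0.01, m = x$m %||% 1, b = x$b %||% 0,
            metadata = as.list(x$metadata))
}

#' @rdname write_cpm_model
#' @export
read_edge_pairs <- function(path, n_nodes) {
  df <- utils::read.csv(path, header = FALSE)
  if (is.character(df[[1]])) df <- utils::read.csv(path, header = TRUE)
  i <- pmin(df[[1]], df[[2]])
  j <- pmax(df[[1]], df[[2]])
  sort(unique(edge_index(i, j, n_nodes)))
}

#' @exportS3Method generics::tidy
tidy.cpm_model <- function(x, ...) {
  k <- c(x$pos_edges, x$neg_edges)
  pr <- edge_pair(k, x$n_nodes)
  tibble::tibble(
    edge = k, i = pr$i, j = pr$j,
    network = rep(c("positive", "negative"),
                  c(length(x$pos_edges), length(x$neg_edges)))
  )
}

#' @exportS3Method generics::glance
glance.cpm_model <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes, n_pos = length(x$pos_edges),
    n_neg = length(x$neg_edges), alpha = x$alpha, m = x$m, b = x$b,
    n_runs = x$metadata$n_runs %||% NA_integer_
  )
}
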