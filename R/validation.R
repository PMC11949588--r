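#' Partial Spearman correlation with nuisance covariates
#'
#' The external-validation statistic: all variables are rank-transformed
#' (average ranks at ties), the x- and y-ranks are residualized on the
#' covariate ranks by least squares, and the Pearson correlation of the
#' residuals is returned with a t-based two-tailed p-value on
#' `n - 2 - n_covariates` degrees of freedom. With no covariates this is
#' ordinary Spearman correlation. Invariant to strictly increasing
#' transforms of x and of y.
#'
#' @param x,y Numeric per-run vectors (e.g., network strength and observed
#'   behavior).
#' @param covariates Optional vector, matrix, or data frame of per-run
#'   nuisance variables (e.g., mean framewise displacement; optionally also
#'   the other modality's performance).
#' @return One-row tibble: `rho`, `p`, `n`, `df`, `covariates` (comma-joined
#'   names or `""`).
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- x + rnorm(30); z <- rnorm(30)
#' partial_spearman(x, y, z)
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop_input("x and y lengths differ")
  n <- length(x)
  cov_names <- ""
  q <- 0L
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) stop_input("covariate length mismatch")
    q <- ncol(Z)
    cov_names <- paste(colnames(Z) %||% paste0("z", seq_len(q)),
                       collapse = ",")
  }
  if (n < q + 4) stop_input("need n >= covariates + 4, got n = %d", n)
  if (sd(x) == 0 || sd(y) == 0) stop_input("constant input")
  rx <- rank(x)
  ry <- rank(y)
  if (q > 0) {
    if (any(apply(Z, 2, sd) == 0)) stop_input("constant covariate")
    rz <- apply(Z, 2, rank)
    Q <- qr.Q(qr(cbind(1, rz)))
    rx <- rx - Q %*% crossprod(Q, rx)
    ry <- ry - Q %*% crossprod(Q, ry)
  } else {
    rx <- rx - mean(rx)
    ry <- ry - mean(ry)
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - q
  tstat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  tibble::tibble(rho = rho, p = 2 * pt(-abs(tstat), df), n = n, df = df,
                 covariates = cov_names)
}

# rank-residualized columns against fixed covariate ranks; used by the
# permutation routines so nulls share one projection
rank_resid <- function(v, Q) {
  r <- rank(v)
  if (is.null(Q)) r - mean(r) else r - Q %*% crossprod(Q, r)
}

#' Permutation test of modality specificity
#'
#' Tests whether within-modality predictions beat cross-modality
#' predictions. The observed statistic is the partial Spearman rho of the
#' within-modality predictions with observed behavior (controlling for
#' motion) minus that of the cross-modality predictions. The null shuffles
#' the two prediction vectors independently — observed behavior and the
#' motion covariate stay fixed — and recomputes the difference `n_perm`
#' times. The p-value is one-tailed, `(#\{null >= observed\} + 1) /
#' (n_perm + 1)`, so it is never exactly zero.
#'
#' @param pred_within,pred_cross Per-run predicted values (network
#'   strengths) from the within- and cross-modality models.
#' @param observed Observed per-run behavior.
#' @param motion Per-run motion covariate (mean FD).
#' @param n_perm Number of permutations.
#' @param seed Integer seed; results are reproducible given
#'   `(seed, n_perm)`.
#' @return Object of class `cpm_permutation`: `observed_diff`,
#'   `rho_within`, `rho_cross`, `null_diffs`, `p`, `n_perm`, `seed`.
#' @export
modality_specificity_test <- function(pred_within, pred_cross, observed,
                                      motion, n_perm = 5000, seed = 1) {
  n <- length(observed)
  if (length(pred_within) != n || length(pred_cross) != n ||
      length(motion) != n) {
    stop_input("all vectors must share one length")
  }
  if (n_perm < 1) stop_input("`n_perm` must be >= 1")
  rho_w <- partial_spearman(pred_within, observed, motion)$rho
  rho_c <- partial_spearman(pred_cross, observed, motion)$rho
  observed_diff <- rho_w - rho_c

  Q <- qr.Q(qr(cbind(1, rank(motion))))
  ry <- rank_resid(observed, Q)
  ny <- sqrt(sum(ry^2))
  rho_perm <- function(v, perm_mat) {
    # ranks of a permuted vector are the permuted ranks
    r <- rank(v)
    R <- matrix(r[perm_mat], n, ncol(perm_mat))
    R <- R - Q %*% crossprod(Q, R)
    colSums(R * as.vector(ry)) / (sqrt(colSums(R^2)) * ny)
  }
  null_diffs <- withr::with_seed(seed, {
    pw <- replicate(n_perm, sample.int(n))
    pc <- replicate(n_perm, sample.int(n))
    rho_perm(pred_within, pw) - rho_perm(pred_cross, pc)
  })
  structure(
    list(observed_diff = observed_diff, rho_within = rho_w,
         rho_cross = rho_c, null_diffs = null_diffs,
         p = (sum(null_diffs >= observed_diff) + 1) / (n_perm + 1),
         n_perm = n_perm, n = n, seed = seed),
    class = "cpm_permutation"
  )
}

#' @export
print.cpm_permutation <- function(x, ...) {
  cat(sprintf(
    "<cpm_permutation> observed diff = %.4f (rho within %.3f - cross %.3f)\n",
    x$observed_diff, x$rho_within %||% NA, x$rho_cross %||% NA))
  cat(sprintf("  one-tailed p = %.4g over %d permutations (seed %d)\n",
              x$p, x$n_perm, x$seed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cpm_permutation <- function(x, ...) {
  tibble::tibble(null_diff = x$null_diffs)
}

#' @exportS3Method generics::glance
glance.cpm_permutation <- function(x, ...) {
  tibble::tibble(observed_diff = x$observed_diff,
                 rho_within = x$rho_within %||% NA_real_,
                 rho_cross = x$rho_cross %||% NA_real_,
                 p = x$p, n_perm = x$n_perm, n = x$n, seed = x$seed)
}

#' Subsample-retraining control for unequal training sets
#'
#' Controls for training-set size by refitting the model on random
#' subsamples of `n_sub` runs (without replacement), evaluating each refit
#' model's generalization (partial Spearman rho, controlling for motion) on
#' one or more evaluation sets, and reporting whether the full-sample
#' model's rho lies within one SD of the subsample mean.
#'
#' @param train_edges Runs x E training edge matrix.
#' @param train_behavior Per-run training behavior.
#' @param eval_sets Named list; each element a list with `edges`,
#'   `behavior`, `motion`.
#' @param n_sub Subsample size (<= training runs).
#' @param n_iter Number of subsample refits.
#' @param alpha Selection threshold.
#' @param seed Integer seed.
#' @return List of class `cpm_subsample`: `summary` (tibble per eval set:
#'   `mean_rho`, `sd_rho`, `full_rho`, `within_1sd`), `draws` (iteration x
#'   eval-set tibble), `n_sub`, `n_iter`, `seed`.
#' @export
subsample_retrain <- function(train_edges, train_behavior, eval_sets,
                              n_sub = 50, n_iter = 1000, alpha = 0.01,
                              seed = 1) {
  n_train <- nrow(train_edges)
  if (n_sub > n_train) stop_input("n_sub %d > %d training runs", n_sub, n_train)
  full <- train_cpm(train_edges, train_behavior, alpha = alpha)
  eval_rho <- function(model) {
    vapply(eval_sets, function(es) {
      s <- network_strength(es$edges, model)
      partial_spearman(s, es$behavior, es$motion)$rho
    }, numeric(1))
  }
  full_rho <- eval_rho(full)
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n_iter), function(it) {
      idx <- sample.int(n_train, n_sub)
      sel <- select_edges(train_edges[idx, , drop = FALSE],
                          train_behavior[idx], alpha = alpha)
      if (length(sel$pos) == 0 || length(sel$neg) == 0) {
        return(rep(NA_real_, length(eval_sets)))
      }
      m <- cpm_model(sel$pos, sel$neg, n_nodes = full$n_nodes, alpha = alpha)
      eval_rho(m)
    })
  })
  draws <- do.call(rbind, draws)
  colnames(draws) <- names(eval_sets)
  n_failed <- sum(apply(draws, 1, function(r) anyNA(r)))
  if (n_failed > 0) {
    warn(sprintf("%d subsample refit(s) produced an empty mask; dropped",
                 n_failed))
  }
  summ <- tibble::tibble(
    eval_set = names(eval_sets),
    mean_rho = unname(colMeans(draws, na.rm = TRUE)),
    sd_rho = unname(apply(draws, 2, sd, na.rm = TRUE)),
    full_rho = unname(full_rho)
  )
  summ$within_1sd <- abs(summ$full_rho - summ$mean_rho) <= summ$sd_rho
  structure(
    list(summary = summ, draws = tibble::as_tibble(draws),
         n_sub = n_sub, n_iter = n_iter, seed = seed),
    class = "cpm_subsample"
  )
}

#' @export
print.cpm_subsample <- function(x, ...) {
  cat(sprintf("<cpm_subsample> %d refits of %d runs\n", x$n_iter, x$n_sub))
  print(x$summary)
  invisible(x)
}

#' Matched-size edge-subset comparison
#'
#' Asks whether a designated small edge set (e.g., the overlap of two
#' networks) predicts better than equal-sized random subsets of a parent
#' model's masks. Each draw samples `k_pos` positive and `k_neg` negative
#' edges from the model without replacement, computes network strength on
#' the evaluation runs, and records the partial Spearman rho with observed
#' behavior controlling for motion. The p-value is
#' `(#\{draw rho >= observed_rho\} + 1) / (n_draw + 1)`.
#'
#' @param model Parent [cpm_model()] to draw subsets from.
#' @param observed_rho Partial rho of the designated edge set on the same
#'   evaluation data (compute it with [partial_spearman()]).
#' @param k_pos,k_neg Subset sizes (the overlap sizes, e.g., 25 and 41).
#' @param edges,behavior,motion Evaluation runs.
#' @param n_draw Number of random subsets.
#' @param seed Integer seed.
#' @return Object of class `cpm_permutation` with `null_diffs` holding the
#'   draw rhos and `observed_diff` the reference rho.
#' @export
subset_match_test <- function(model, observed_rho, k_pos, k_neg,
                              edges, behavior, motion,
                              n_draw = 5000, seed = 1) {
  if (k_pos > length(model$pos_edges) || k_neg > length(model$neg_edges)) {
    stop_input("subset sizes exceed mask sizes (%d/%d available)",
               length(model$pos_edges), length(model$neg_edges))
  }
  Q <- qr.Q(qr(cbind(1, rank(motion))))
  ry <- rank_resid(behavior, Q)
  ny <- sqrt(sum(ry^2))
  draw_rhos <- withr::with_seed(seed, {
    vapply(seq_len(n_draw), function(d) {
      ps <- model$pos_edges[sample.int(length(model$pos_edges), k_pos)]
      ns <- model$neg_edges[sample.int(length(model$neg_edges), k_neg)]
      s <- rowMeans(edges[, ps, drop = FALSE]) -
        rowMeans(edges[, ns, drop = FALSE])
      rs <- rank_resid(s, Q)
      sum(rs * ry) / (sqrt(sum(rs^2)) * ny)
    }, numeric(1))
  })
  structure(
    list(observed_diff = observed_rho, rho_within = NULL, rho_cross = NULL,
         null_diffs = draw_rhos,
         p = (sum(draw_rhos >= observed_rho) + 1) / (n_draw + 1),
         n_perm = n_draw, n = length(behavior), seed = seed),
    class = "cpm_permutation"
  )
}
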