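test_that("partial Spearman matches the closed-form formula on ranks", {
  x <- c(3.2, 1.1, 5.6, 2.2, 4.8, 7.1, 0.4, 6.3, 2.9, 5.1, 8.0, 3.7)
  y <- c(2.1, 0.9, 4.4, 3.3, 5.0, 6.6, 1.2, 5.9, 2.0, 4.1, 7.7, 2.5)
  z <- c(0.3, 1.9, 0.8, 2.7, 1.1, 0.2, 2.2, 0.5, 1.4, 0.9, 0.1, 1.6)
  res <- partial_spearman(x, y, z)
  # oracle: (r_xy - r_xz r_zy) / sqrt((1 - r_xz^2)(1 - r_zy^2)) on ranks
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- pearson_by_hand(rx, ry)
  r_xz <- pearson_by_hand(rx, rz)
  r_zy <- pearson_by_hand(rz, ry)
  rho_hand <- (r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2) * (1 - r_zy^2))
  expect_equal(res$rho, rho_hand)
  t_hand <- rho_hand * sqrt((12 - 3) / (1 - rho_hand^2))
  expect_equal(res$p, 2 * pt(-abs(t_hand), 12 - 3))
  expect_identical(res$df, 9)
})

test_that("no-covariate partial Spearman is ordinary Spearman", {
  set.seed(5)
  x <- rnorm(25); y <- x + rnorm(25)
  expect_equal(partial_spearman(x, y)$rho,
               cor(x, y, method = "spearman"))
})

test_that("partial Spearman is invariant to increasing transforms", {
  set.seed(8)
  x <- rnorm(20); y <- x + rnorm(20); z <- rnorm(20)
  base <- partial_spearman(x, y, z)$rho
  expect_equal(partial_spearman(exp(x), y, z)$rho, base)
  expect_equal(partial_spearman(x, y^3 + 2 * y, z)$rho, base)
})

test_that("identical ranks with an orthogonal covariate give rho exactly 1", {
  x <- c(10, 20, 30, 40, 50, 60, 70, 80)
  y <- x^2                                   # same ranks as x
  z <- c(3, 5, 8, 2, 4, 7, 1, 6)             # ranks orthogonal to 1..8
  stopifnot(sum((rank(z) - 4.5) * (1:8 - 4.5)) == 0)
  expect_equal(partial_spearman(x, y, z)$rho, 1)
})

test_that("degenerate validation inputs error", {
  expect_error(partial_spearman(rep(1, 10), rnorm(10)), "constant")
  expect_error(partial_spearman(rnorm(10), rnorm(10), rep(2, 10)),
               "constant covariate")
  expect_error(partial_spearman(rnorm(4), rnorm(4), rnorm(4)), "n >=")
  expect_error(partial_spearman(rnorm(5), rnorm(6)), "lengths differ")
})

test_that("specificity test is symmetric under identical predictions and
           reproducible under a seed", {
  set.seed(19)
  obs <- rnorm(40); fd <- rnorm(40); pred <- rnorm(40)
  res <- modality_specificity_test(pred, pred, obs, fd,
                                   n_perm = 999, seed = 11)
  expect_equal(res$observed_diff, 0)
  expect_gt(res$p, 0.35)
  expect_lt(res$p, 0.65)
  res2 <- modality_specificity_test(pred, pred, obs, fd,
                                    n_perm = 999, seed = 11)
  expect_identical(res$null_diffs, res2$null_diffs)
  expect_identical(res$p, res2$p)
  expect_length(res$null_diffs, 999)
  expect_gt(res$p, 0)  # add-one estimator never returns zero
})

test_that("specificity is detected when only within-modality edges carry
           signal", {
  cfg <- small_config(seed = 3, n_shared_pos = 0, n_shared_neg = 0,
                      n_runs_per_modality = 60)
  train <- generate_cohort(cfg)
  eval_coh <- generate_cohort(small_config(
    seed = 4, n_shared_pos = 0, n_shared_neg = 0,
    n_runs_per_modality = 60), truth = train$truth)
  fit <- function(m) {
    rows <- train$runs$modality == m
    train_cpm(train$edges[rows, ], train$runs$behavior[rows], alpha = 1e-4)
  }
  vis_model <- fit("visual"); aud_model <- fit("auditory")
  rows <- eval_coh$runs$modality == "visual"
  res <- modality_specificity_test(
    pred_within = predict(vis_model, eval_coh$edges[rows, ]),
    pred_cross = predict(aud_model, eval_coh$edges[rows, ]),
    observed = eval_coh$runs$behavior[rows],
    motion = eval_coh$runs$mean_fd[rows],
    n_perm = 999, seed = 7)
  expect_gt(res$observed_diff, 0.5)
  expect_lt(res$p, 0.05)
})

test_that("subsample retraining degenerates correctly and tightens with
           subsample size", {
  coh <- generate_cohort(small_config(seed = 29))
  vis <- coh$runs$modality == "visual"
  ev <- list(auditory = list(edges = coh$edges[!vis, ],
                             behavior = coh$runs$behavior[!vis],
                             motion = coh$runs$mean_fd[!vis]))
  n_train <- sum(vis)
  res_full <- subsample_retrain(coh$edges[vis, ], coh$runs$behavior[vis],
                                ev, n_sub = n_train, n_iter = 5, seed = 2)
  expect_equal(res_full$summary$sd_rho, 0)
  expect_equal(res_full$summary$mean_rho, res_full$summary$full_rho)
  expect_true(res_full$summary$within_1sd)

  sd_at <- function(n_sub) {
    subsample_retrain(coh$edges[vis, ], coh$runs$behavior[vis], ev,
                      n_sub = n_sub, n_iter = 40, alpha = 1e-4,
                      seed = 5)$summary$sd_rho
  }
  expect_gt(sd_at(10), sd_at(35))
  expect_error(subsample_retrain(coh$edges[vis, ], coh$runs$behavior[vis],
                                 ev, n_sub = 999), "training runs")
})

test_that("matched-size subsets reproduce the full model at full size and
           detect concentrated signal", {
  coh <- generate_cohort(small_config(seed = 37))
  eval_coh <- generate_cohort(small_config(seed = 38), truth = coh$truth)
  vis <- coh$runs$modality == "visual"
  fit <- train_cpm(coh$edges[vis, ], coh$runs$behavior[vis], alpha = 1e-4)
  rows <- eval_coh$runs$modality == "visual"
  ev_edges <- eval_coh$edges[rows, ]
  ev_beh <- eval_coh$runs$behavior[rows]
  ev_fd <- eval_coh$runs$mean_fd[rows]
  full_rho <- partial_spearman(network_strength(ev_edges, fit),
                               ev_beh, ev_fd)$rho
  res <- subset_match_test(fit, full_rho,
                           k_pos = length(fit$pos_edges),
                           k_neg = length(fit$neg_edges),
                           ev_edges, ev_beh, ev_fd, n_draw = 50, seed = 1)
  expect_equal(res$p, 1)
  expect_true(all(res$null_diffs == full_rho))

  # dilute the true masks with null edges: the planted subset outperforms
  # random equal-sized subsets of the diluted model
  E <- ncol(coh$edges)
  null_pool <- setdiff(seq_len(E), unlist(coh$truth$visual))
  diluted <- cpm_model(c(coh$truth$visual$pos, null_pool[1:40]),
                       c(coh$truth$visual$neg, null_pool[41:80]),
                       n_nodes = coh$config$n_nodes)
  true_model <- cpm_model(coh$truth$visual$pos, coh$truth$visual$neg,
                          n_nodes = coh$config$n_nodes)
  rho_true <- partial_spearman(network_strength(ev_edges, true_model),
                               ev_beh, ev_fd)$rho
  res2 <- subset_match_test(diluted, rho_true,
                            k_pos = length(coh$truth$visual$pos),
                            k_neg = length(coh$truth$visual$neg),
                            ev_edges, ev_beh, ev_fd,
                            n_draw = 199, seed = 3)
  expect_lt(res2$p, 0.05)
  expect_error(subset_match_test(fit, 0, k_pos = 1e6, k_neg = 1,
                                 ev_edges, ev_beh, ev_fd), "exceed")
})

test_that("permutation objects tidy and glance", {
  set.seed(2)
  res <- modality_specificity_test(rnorm(20), rnorm(20), rnorm(20),
                                   rnorm(20), n_perm = 99, seed = 1)
  expect_identical(nrow(tidy(res)), 99L)
  gl <- glance(res)
  expect_identical(gl$n_perm, 99)
  expect_true(gl$p > 0 && gl$p <= 1)
})
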