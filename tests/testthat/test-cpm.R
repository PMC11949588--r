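# six-run, four-edge toy with hand-computable statistics
toy_edges <- function() {
  cbind(
    e1 = c(0.11, 0.19, 0.32, 0.38, 0.52, 0.59),   # tracks behavior closely
    e2 = c(0.55, 0.48, 0.36, 0.30, 0.22, 0.09),   # anti-tracks behavior
    e3 = c(0.05, -0.21, 0.33, 0.12, -0.08, 0.17), # unrelated
    e4 = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.25)    # constant
  )
}
toy_behavior <- c(1, 2, 3, 4, 5, 6)

test_that("edge selection matches the closed-form Pearson/t oracle", {
  edges <- toy_edges()
  b <- toy_behavior
  suppressWarnings(sel <- select_edges(edges, b, alpha = 0.01))
  n <- 6
  for (k in 1:3) {
    r_hand <- pearson_by_hand(edges[, k], b)
    expect_equal(unname(sel$r[k]), r_hand)
    t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
    expect_equal(unname(sel$p[k]), 2 * pt(-abs(t_hand), n - 2))
  }
  expect_identical(sel$pos, 1L)   # only e1 is significant and positive
  expect_identical(sel$neg, 2L)   # only e2 significant and negative
  expect_true(is.na(sel$p[4]))    # constant edge never selected
})

test_that("negating behavior swaps the masks exactly", {
  coh <- generate_cohort(small_config(seed = 13))
  vis <- coh$runs$modality == "visual"
  a <- select_edges(coh$edges[vis, ], coh$runs$behavior[vis])
  b <- select_edges(coh$edges[vis, ], -coh$runs$behavior[vis])
  expect_identical(a$pos, b$neg)
  expect_identical(a$neg, b$pos)
})

test_that("selection is monotone in alpha with the right limits", {
  coh <- generate_cohort(small_config(seed = 17, n_runs_per_modality = 20))
  vis <- coh$runs$modality == "visual"
  edges <- coh$edges[vis, ]
  b <- coh$runs$behavior[vis]
  full <- select_edges(edges, b, alpha = 1)
  expect_identical(sort(c(full$pos, full$neg)), seq_len(ncol(edges)))
  none <- select_edges(edges, b, alpha = 1e-300)
  expect_length(c(none$pos, none$neg), 0)
  mid1 <- select_edges(edges, b, alpha = 0.01)
  mid2 <- select_edges(edges, b, alpha = 0.10)
  expect_true(all(mid1$pos %in% mid2$pos))
  expect_true(all(mid1$neg %in% mid2$neg))
})

test_that("partial selection residualizes out the covariate", {
  # edge = covariate + tiny noise: raw correlation with a behavior that
  # equals the covariate is near 1, partial correlation collapses
  set.seed(41)
  z <- rnorm(30)
  edges <- cbind(z + rnorm(30, sd = 0.05), rnorm(30))
  b <- z + rnorm(30, sd = 0.05)
  raw <- select_edges(edges, b, alpha = 0.01)
  expect_identical(raw$pos, 1L)
  part <- select_edges(edges, b, alpha = 0.01, covariate = z)
  expect_length(part$pos, 0)
  expect_error(select_edges(edges, b, covariate = rep(1, 30)), "constant")
  expect_error(select_edges(edges, rep(2, 30)), "constant")
})

test_that("network strength is the mean-positive minus mean-negative", {
  m <- cpm_model(pos_edges = c(1, 2), neg_edges = 3, n_nodes = 4)
  expect_equal(network_strength(c(0.5, 0.3, 0.1, 9, 9, 9), m), 0.4 - 0.1)
  # constant connectome -> zero strength; constant shift invariance
  expect_equal(network_strength(rep(0.7, 6), m), 0)
  e <- c(0.5, 0.3, 0.1, 0.2, 0, 0)
  expect_equal(network_strength(e + 5, m), network_strength(e, m))
  # linearity in the edge vector
  e2 <- c(1, -1, 0.4, 0, 0.3, 2)
  a <- 0.3
  expect_equal(network_strength(a * e + (1 - a) * e2, m),
               a * network_strength(e, m) + (1 - a) * network_strength(e2, m))
  expect_error(network_strength(e, cpm_model(1, integer(0), 4)), "empty")
})

test_that("masks must be disjoint and in range", {
  expect_error(cpm_model(1:3, 3:4, n_nodes = 5), "disjoint")
  expect_error(cpm_model(1, 99, n_nodes = 5), "out of range")
})

test_that("calibration is ordinary least squares", {
  s <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(fit_calibration(s, 2 * s + 1), c(m = 2, b = 1))
  # normal-equation oracle on a noisy 5-point toy
  b <- c(1.2, 0.7, 1.9, 2.4, 2.2)
  cal <- fit_calibration(s, b)
  sx <- s - mean(s)
  m_hand <- sum(sx * (b - mean(b))) / sum(sx^2)
  expect_equal(unname(cal["m"]), m_hand)
  expect_equal(unname(cal["b"]), mean(b) - m_hand * mean(s))
  expect_error(fit_calibration(rep(1, 5), b), "constant")
})

test_that("prediction normalization is a within-dataset z-score and leaves
           rank statistics untouched", {
  coh <- generate_cohort(small_config(seed = 23))
  vis <- coh$runs$modality == "visual"
  fit <- train_cpm(coh$edges[vis, ], coh$runs$behavior[vis], alpha = 1e-5)
  s <- predict(fit, coh$edges[!vis, ])
  z <- predict(fit, coh$edges[!vis, ], normalize = TRUE)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(cor(s, coh$runs$behavior[!vis], method = "spearman"),
               cor(z, coh$runs$behavior[!vis], method = "spearman"))
  expect_error(predict(fit, coh$edges[1, , drop = FALSE], normalize = TRUE),
               "single run")
  # behavior-scale predictions apply the linear calibration
  expect_equal(predict(fit, coh$edges[!vis, ], type = "behavior"),
               fit$m * s + fit$b)
})

test_that("recovered masks converge to the planted truth with sample size", {
  recall_at <- function(n) {
    coh <- generate_cohort(small_config(
      seed = 31, n_runs_per_modality = n, effect_size = 0.35, noise_sd = 0.3))
    vis <- coh$runs$modality == "visual"
    sel <- select_edges(coh$edges[vis, ], coh$runs$behavior[vis])
    truth <- c(coh$truth$visual$pos, coh$truth$visual$neg)
    length(intersect(c(sel$pos, sel$neg), truth)) / length(truth)
  }
  rec <- vapply(c(12, 40, 160), recall_at, numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_gt(rec[3], 0.9)
})

test_that("models serialize to JSON and ingest (i, j) pair lists", {
  fit <- cpm_model(c(2, 5), c(9, 11), n_nodes = 8, alpha = 0.01,
                   m = 1.5, b = -0.2, metadata = list(n_runs = 40))
  f <- withr::local_tempfile(fileext = ".json")
  write_cpm_model(fit, f)
  back <- read_cpm_model(f)
  expect_identical(back$pos_edges, fit$pos_edges)
  expect_identical(back$neg_edges, fit$neg_edges)
  expect_equal(back$m, 1.5)
  expect_equal(back$metadata$n_runs, 40)

  # 1-based pair list: (1,3) and (2,4) at n = 5 are edges 2 and 6
  pairs <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,3", "4,2"), pairs)  # order within a pair is free
  expect_identical(read_edge_pairs(pairs, 5), c(2L, 6L))
})

test_that("tidy and glance expose the model structure", {
  fit <- cpm_model(c(1, 3), 5, n_nodes = 4, m = 2, b = 0.5,
                   metadata = list(n_runs = 10))
  td <- tidy(fit)
  expect_identical(nrow(td), 3L)
  expect_identical(td$network, c("positive", "positive", "negative"))
  expect_identical(td$i[1], 1L)  # edge 1 is the (1,2) pair
  expect_identical(td$j[1], 2L)
  gl <- glance(fit)
  expect_identical(gl$n_pos, 2L)
  expect_identical(gl$n_runs, 10)
})
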