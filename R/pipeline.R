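#' Pipeline configuration
#'
#' Assembles the settings for an end-to-end analysis: the synthetic-cohort
#' configs for a training cohort and an evaluation cohort, the thresholds
#' of the study design (selection alpha 0.01; motion cutoffs 0.15 mm mean
#' FD, 4 mm maximum displacement, 50% censored frames; 2.5-SD behavioral
#' rule), and the permutation budgets (5,000 specificity permutations,
#' 1,000 contribution shuffles). Accepts a YAML file with the same field
#' names.
#'
#' @param train,eval Lists of [cohort_config()] arguments (seeds are derived
#'   from `seed` when absent).
#' @param alpha Edge-selection threshold.
#' @param fd_max,disp_max,censor_max,k_sd QC thresholds.
#' @param n_perm Specificity-test permutations.
#' @param n_perm_contrib Contribution-matrix shuffles.
#' @param n_networks Number of canonical networks in the synthetic atlas.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param yaml Optional path to a YAML file supplying any of the above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(train = list(), eval = list(),
                            alpha = 0.01, fd_max = 0.15, disp_max = 4,
                            censor_max = 0.5, k_sd = 2.5,
                            n_perm = 5000, n_perm_contrib = 1000,
                            n_networks = 8, seed = 1, yaml = NULL) {
  cfg <- list(train = train, eval = eval, alpha = alpha, fd_max = fd_max,
              disp_max = disp_max, censor_max = censor_max, k_sd = k_sd,
              n_perm = n_perm, n_perm_contrib = n_perm_contrib,
              n_networks = n_networks, seed = as.integer(seed))
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) stop_input("config file `%s` not found", yaml)
    user <- yaml::read_yaml(yaml)
    cfg[names(user)] <- user
  }
  if (cfg$alpha <= 0 || cfg$fd_max <= 0) {
    stop_input("thresholds must be positive")
  }
  cfg$train <- do.call(cohort_config,
                       utils::modifyList(list(seed = sub_seed(cfg$seed, 11L)),
                                         cfg$train))
  cfg$eval <- do.call(cohort_config,
                      utils::modifyList(list(seed = sub_seed(cfg$seed, 12L)),
                                        cfg$eval))
  structure(cfg, class = "pipeline_config")
}

# round-robin node -> canonical-network assignment for synthetic atlases
synthetic_atlas <- function(n_nodes, n_networks = 8) {
  tibble::tibble(
    node = seq_len(n_nodes),
    network = paste0("net", (seq_len(n_nodes) - 1) %% n_networks + 1)
  )
}

#' Run the full modality-generalization analysis on synthetic cohorts
#'
#' Executes the analysis graph end to end: generate a training and an
#' evaluation cohort; apply QC; train a visual and an auditory CPM on the
#' training cohort; predict network strength for every evaluation run;
#' compute within- and cross-modality generalization (partial Spearman,
#' controlling for the motion surrogate); run the one-tailed modality
#' specificity permutation test per modality; test the overlap of the two
#' trained networks against the hypergeometric null; and summarize
#' canonical-network contributions with shuffle significance. Deterministic
#' given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `cpm_pipeline` with elements `models`, `qc`,
#'   `generalization` (tibble), `specificity` (list of `cpm_permutation`),
#'   `overlap` (tibble), `contribution`, `truth_recovery` (tibble), and
#'   `config`.
#' @export
run_cpm_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_input("`config` must come from pipeline_config()")
  }
  train_coh <- generate_cohort(config$train)
  # the evaluation cohort is a new sample from the same planted truth
  eval_coh <- generate_cohort(config$eval, truth = train_coh$truth)

  # QC on the motion surrogate (synthetic runs carry no censoring/max-disp,
  # so those fields are zero-filled and only the FD rule can bite)
  qc_tab <- function(coh) {
    runs <- dplyr::mutate(coh$runs, max_disp = 0, censored_frac = 0,
                          performance = .data$behavior)
    qc_runs(runs, fd_max = config$fd_max, disp_max = config$disp_max,
            censor_max = config$censor_max, k = config$k_sd)
  }
  train_qc <- qc_tab(train_coh)
  eval_qc <- qc_tab(eval_coh)

  models <- lapply(c(visual = "visual", auditory = "auditory"), function(m) {
    keep <- !train_qc$excluded & train_qc$modality == m
    train_cpm(train_coh$edges[keep, , drop = FALSE],
              train_qc$behavior[keep], alpha = config$alpha, modality = m)
  })

  truth_recovery <- purrr::map_dfr(c("visual", "auditory"), function(m) {
    tr <- train_coh$truth[[m]]
    fit <- models[[m]]
    prec <- function(got, want) {
      if (length(got) == 0) return(NA_real_)
      length(intersect(got, want)) / length(got)
    }
    tibble::tibble(
      modality = m,
      precision = prec(c(fit$pos_edges, fit$neg_edges), c(tr$pos, tr$neg)),
      recall = length(intersect(c(fit$pos_edges, fit$neg_edges),
                                c(tr$pos, tr$neg))) /
        length(c(tr$pos, tr$neg))
    )
  })

  ev <- eval_qc[!eval_qc$excluded, ]
  ev_edges <- eval_coh$edges[!eval_qc$excluded, , drop = FALSE]
  pred <- lapply(models, function(mod) predict(mod, ev_edges))

  gen <- purrr::map_dfr(c("visual", "auditory"), function(target) {
    rows <- ev$modality == target
    purrr::map_dfr(c("visual", "auditory"), function(trained) {
      res <- partial_spearman(pred[[trained]][rows], ev$behavior[rows],
                              ev$mean_fd[rows])
      dplyr::mutate(res, trained_on = trained, evaluated_on = target,
                    .before = 1)
    })
  })

  specificity <- lapply(c(visual = "visual", auditory = "auditory"),
    function(target) {
      rows <- ev$modality == target
      other <- setdiff(c("visual", "auditory"), target)
      modality_specificity_test(
        pred_within = pred[[target]][rows],
        pred_cross = pred[[other]][rows],
        observed = ev$behavior[rows], motion = ev$mean_fd[rows],
        n_perm = config$n_perm, seed = sub_seed(config$seed, 21L))
    })

  M <- n_edges(config$train$n_nodes)
  overlap <- dplyr::bind_rows(
    dplyr::mutate(overlap_test(models$visual$pos_edges,
                               models$auditory$pos_edges, M),
                  networks = "high_attention", .before = 1),
    dplyr::mutate(overlap_test(models$visual$neg_edges,
                               models$auditory$neg_edges, M),
                  networks = "low_attention", .before = 1)
  )

  atlas <- synthetic_atlas(config$train$n_nodes, config$n_networks)
  contribution <- contribution_matrix(
    models$visual$pos_edges, models$visual$neg_edges, atlas,
    n_nodes = config$train$n_nodes, n_perm = config$n_perm_contrib,
    seed = sub_seed(config$seed, 22L))

  structure(
    list(models = models, qc = list(train = train_qc, eval = eval_qc),
         generalization = gen, specificity = specificity, overlap = overlap,
         contribution = contribution, truth_recovery = truth_recovery,
         config = config),
    class = "cpm_pipeline"
  )
}

#' @export
print.cpm_pipeline <- function(x, ...) {
  cat("<cpm_pipeline>\n")
  cat("Generalization (partial Spearman, motion-controlled):\n")
  print(x$generalization)
  cat("\nNetwork overlap:\n")
  print(x$overlap)
  invisible(x)
}

#' Write a machine-readable pipeline manifest
#'
#' Serializes every statistic the pipeline computed — generalization rhos,
#' specificity permutation results, overlap tests, contribution cells,
#' truth recovery, QC ledgers, mask sizes, seeds and thresholds — to a
#' single JSON file sufficient to re-run any stage.
#'
#' @param result A `cpm_pipeline` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  cfg <- result$config
  out <- list(
    config = list(alpha = cfg$alpha, fd_max = cfg$fd_max,
                  disp_max = cfg$disp_max, censor_max = cfg$censor_max,
                  k_sd = cfg$k_sd, n_perm = cfg$n_perm,
                  n_perm_contrib = cfg$n_perm_contrib, seed = cfg$seed,
                  train = unclass(cfg$train), eval = unclass(cfg$eval)),
    models = lapply(result$models, function(m) {
      list(n_pos = length(m$pos_edges), n_neg = length(m$neg_edges),
           m = m$m, b = m$b)
    }),
    qc = lapply(result$qc, function(q) {
      as.list(table(q$reason))
    }),
    generalization = result$generalization,
    specificity = lapply(result$specificity, function(s) glance(s)),
    overlap = result$overlap,
    truth_recovery = result$truth_recovery,
    contribution = list(cells = result$contribution$contribution,
                        p = result$contribution$p)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
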