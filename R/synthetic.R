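#' Configuration for a synthetic dual-modality cohort
#'
#' Describes a simulated study in which every run has a connectome (as a
#' canonical edge vector), a behavioral score in one of two perceptual
#' modalities ("visual" or "auditory"), and a head-motion surrogate. A known
#' set of edges is planted to carry behavioral signal: per modality,
#' `n_pos_edges` edges correlate positively and `n_neg_edges` negatively
#' with that modality's behavior, of which `n_shared_pos` / `n_shared_neg`
#' are common to both modalities (the supramodal edges). Behavior for
#' modality m is `b_m = sqrt(w) * g + sqrt(1 - w) * e_m` with `g` the
#' supramodal trait and `e_m` modality-specific, all standard normal, so the
#' cross-modal behavior correlation converges to `w`.
#'
#' Defaults mirror the study conditions the package emulates: a 268-node
#' parcellation (35,778 edges), network sizes of 581 positive / 659 negative
#' edges with 25 / 41 shared, ~50 runs per modality, and a supramodal weight
#' of 0.55 placing the cross-modal rank correlation in the observed
#' 0.50-0.59 range.
#'
#' @param n_runs_per_modality Runs simulated per modality.
#' @param n_nodes Parcellation size.
#' @param n_pos_edges,n_neg_edges Planted edges per modality and sign.
#' @param n_shared_pos,n_shared_neg Planted edges shared by both modalities.
#' @param effect_size Behavior effect on a planted edge, in edge units per
#'   behavior SD.
#' @param w Supramodal weight in \[0, 1\]: fraction of behavior variance from
#'   the shared latent trait.
#' @param noise_sd Run-level edge noise SD.
#' @param baseline_sd SD of per-edge baselines (Fisher-z-like scale).
#' @param motion_behavior_corr Target correlation between the motion
#'   surrogate and behavior (head motion tends to accompany poor
#'   performance, hence the negative default).
#' @param runs_per_subject Runs per simulated subject; above 1, run behavior
#'   adds subject-level repetition around the subject trait.
#' @param run_noise_sd Run-level behavior noise when `runs_per_subject > 1`.
#' @param press_streams If `TRUE`, also simulate gradCPT press streams per
#'   run.
#' @param n_trials Trials per simulated press stream.
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_runs_per_modality = 50,
                          n_nodes = 268,
                          n_pos_edges = 581,
                          n_neg_edges = 659,
                          n_shared_pos = 25,
                          n_shared_neg = 41,
                          effect_size = 0.15,
                          w = 0.55,
                          noise_sd = 0.3,
                          baseline_sd = 0.3,
                          motion_behavior_corr = -0.2,
                          runs_per_subject = 1,
                          run_noise_sd = 0.3,
                          press_streams = FALSE,
                          n_trials = 100,
                          seed = 1) {
  cfg <- list(
    n_runs_per_modality = as.integer(n_runs_per_modality),
    n_nodes = as.integer(n_nodes),
    n_pos_edges = as.integer(n_pos_edges),
    n_neg_edges = as.integer(n_neg_edges),
    n_shared_pos = as.integer(n_shared_pos),
    n_shared_neg = as.integer(n_shared_neg),
    effect_size = effect_size, w = w, noise_sd = noise_sd,
    baseline_sd = baseline_sd,
    motion_behavior_corr = motion_behavior_corr,
    runs_per_subject = as.integer(runs_per_subject),
    run_noise_sd = run_noise_sd,
    press_streams = isTRUE(press_streams),
    n_trials = as.integer(n_trials),
    seed = as.integer(seed)
  )
  E <- n_edges(cfg$n_nodes)
  if (cfg$w < 0 || cfg$w > 1) stop_input("`w` must lie in [0, 1]")
  if (abs(cfg$motion_behavior_corr) > 1) {
    stop_input("`motion_behavior_corr` must lie in [-1, 1]")
  }
  if (cfg$n_shared_pos > cfg$n_pos_edges ||
      cfg$n_shared_neg > cfg$n_neg_edges) {
    stop_input("shared edge counts cannot exceed per-modality mask sizes")
  }
  # the six planted sets (shared +/-, two modality-unique per sign) are
  # drawn disjointly from the edge pool
  need <- cfg$n_shared_pos + cfg$n_shared_neg +
    2 * (cfg$n_pos_edges - cfg$n_shared_pos) +
    2 * (cfg$n_neg_edges - cfg$n_shared_neg)
  if (need > E) {
    stop_input("planted edge sets need %d edges; only %d exist", need, E)
  }
  if (cfg$n_runs_per_modality < 4) stop_input("need >= 4 runs per modality")
  if (cfg$n_runs_per_modality %% cfg$runs_per_subject != 0) {
    stop_input("`n_runs_per_modality` must be a multiple of `runs_per_subject`")
  }
  if (cfg$effect_size < 0 || cfg$noise_sd < 0) {
    stop_input("`effect_size` and `noise_sd` must be non-negative")
  }
  structure(cfg, class = "cohort_config")
}

# deterministic sub-seeds so stages can be re-run in isolation
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
               2147483629)
}

#' Generate a synthetic cohort with planted predictive edges
#'
#' Draws the cohort described by a [cohort_config()]: latent traits, run
#' behavior per modality, a run x edge matrix in which the planted edges
#' carry `s_k * effect_size * b_m` (s_k = +1 for positive, -1 for negative
#' edges) on top of a fixed per-edge baseline and Gaussian run noise, a
#' motion surrogate with the configured behavior correlation, and optional
#' simulated press streams. Fully deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @param truth Optional planted-truth object from a previous cohort (its
#'   `$truth` element), so an external-validation cohort shares the same
#'   predictive edges as the training cohort while drawing new subjects.
#'   Edge counts and `n_nodes` must match the config.
#' @return An object of class `synthetic_cohort`: list with `edges`
#'   (runs x E matrix), `runs` (tibble: run, subject, modality, behavior,
#'   mean_fd, and press-derived scores if requested), `truth` (per-modality
#'   planted positive/negative edge indices and the shared sets), `latent`
#'   (per-subject traits), `press_streams` (optional), and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_nodes = 20, n_pos_edges = 6,
#'   n_neg_edges = 6, n_shared_pos = 2, n_shared_neg = 2,
#'   n_runs_per_modality = 10, seed = 7))
#' dim(coh$edges)
#' @export
generate_cohort <- function(config, truth = NULL) {
  if (!inherits(config, "cohort_config")) {
    stop_input("`config` must come from cohort_config()")
  }
  cfg <- config
  E <- n_edges(cfg$n_nodes)
  n_subj <- cfg$n_runs_per_modality / cfg$runs_per_subject

  if (!is.null(truth)) {
    ok <- all(vapply(c("visual", "auditory"), function(m) {
      length(truth[[m]]$pos) == cfg$n_pos_edges &&
        length(truth[[m]]$neg) == cfg$n_neg_edges &&
        max(truth[[m]]$pos, truth[[m]]$neg, 0) <= E
    }, logical(1)))
    if (!ok) stop_input("supplied `truth` does not match the config")
  } else truth <- withr::with_seed(sub_seed(cfg$seed, 1L), {
    n_uniq_pos <- cfg$n_pos_edges - cfg$n_shared_pos
    n_uniq_neg <- cfg$n_neg_edges - cfg$n_shared_neg
    pool <- sample.int(E, cfg$n_shared_pos + cfg$n_shared_neg +
                          2 * n_uniq_pos + 2 * n_uniq_neg)
    take <- function(k) {
      if (k == 0) return(integer(0))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      sort(out)
    }
    shared_pos <- take(cfg$n_shared_pos)
    shared_neg <- take(cfg$n_shared_neg)
    list(
      visual = list(pos = sort(c(shared_pos, take(n_uniq_pos))),
                    neg = sort(c(shared_neg, take(n_uniq_neg)))),
      auditory = list(pos = sort(c(shared_pos, take(n_uniq_pos))),
                      neg = sort(c(shared_neg, take(n_uniq_neg)))),
      shared = list(pos = shared_pos, neg = shared_neg)
    )
  })

  latent <- withr::with_seed(sub_seed(cfg$seed, 2L), {
    tibble::tibble(
      subject = seq_len(n_subj),
      supramodal = rnorm(n_subj),
      visual_specific = rnorm(n_subj),
      auditory_specific = rnorm(n_subj)
    )
  })
  trait <- function(mod) {
    spec <- if (mod == "visual") latent$visual_specific else
      latent$auditory_specific
    sqrt(cfg$w) * latent$supramodal + sqrt(1 - cfg$w) * spec
  }

  runs <- withr::with_seed(sub_seed(cfg$seed, 3L), {
    per_mod <- function(mod) {
      subj <- rep(latent$subject, each = cfg$runs_per_subject)
      b <- rep(trait(mod), each = cfg$runs_per_subject)
      if (cfg$runs_per_subject > 1) {
        b <- b + rnorm(length(b), sd = cfg$run_noise_sd)
      }
      tibble::tibble(subject = subj, modality = mod, behavior = b)
    }
    out <- dplyr::bind_rows(per_mod("visual"), per_mod("auditory"))
    rho <- cfg$motion_behavior_corr
    z <- rho * scale(out$behavior)[, 1] +
      sqrt(1 - rho^2) * rnorm(nrow(out))
    out$mean_fd <- pmax(0.01, 0.09 + 0.025 * z)  # mm, plausible FD scale
    dplyr::mutate(out, run = dplyr::row_number(), .before = 1)
  })

  edges <- withr::with_seed(sub_seed(cfg$seed, 4L), {
    baseline <- rnorm(E, 0, cfg$baseline_sd)
    m <- matrix(rnorm(nrow(runs) * E, 0, cfg$noise_sd),
                nrow(runs), E, byrow = FALSE)
    m <- sweep(m, 2, baseline, "+")
    for (mod in c("visual", "auditory")) {
      rows <- which(runs$modality == mod)
      b <- runs$behavior[rows]
      tm <- truth[[mod]]
      m[rows, tm$pos] <- m[rows, tm$pos] + cfg$effect_size * b
      m[rows, tm$neg] <- m[rows, tm$neg] - cfg$effect_size * b
    }
    m
  })

  press_streams <- NULL
  if (cfg$press_streams) {
    press_streams <- purrr::map(seq_len(nrow(runs)), function(r) {
      trials <- make_trials(cfg$n_trials, seed = sub_seed(cfg$seed, 100L + r))
      stream <- generate_press_stream(trials, trait = runs$behavior[r],
                                      seed = sub_seed(cfg$seed, 200L + r))
      list(trials = trials, presses = stream)
    })
    scored <- purrr::map_dfr(press_streams, function(ps) {
      score_run(assign_gradcpt_presses(ps$trials, ps$presses))
    })
    runs <- dplyr::bind_cols(runs, scored)
  }

  structure(
    list(edges = edges, runs = runs, truth = truth, latent = latent,
         press_streams = press_streams, config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d runs x %d edges (%d nodes), seed %d\n",
    nrow(x$edges), ncol(x$edges), x$config$n_nodes, x$config$seed))
  cat(sprintf("  planted edges per modality: %d pos / %d neg (%d / %d shared)\n",
              x$config$n_pos_edges, x$config$n_neg_edges,
              x$config$n_shared_pos, x$config$n_shared_neg))
  invisible(x)
}

#' Simulate a gradCPT press stream for a given attentional trait
#'
#' Generates key-press times for one run of a continuous performance task.
#' A frequent trial receives a press (a hit) with probability
#' `pnorm(hit_intercept + trait)`; an infrequent trial receives an erroneous
#' press (a false alarm) with probability `pnorm(-fa_intercept - trait)`.
#' Higher trait therefore yields higher hit rates and fewer false alarms; in
#' the limit of large trait the scored d' attains the maximum allowed by the
#' extreme-rate correction. Press times fall inside the trial's gradCPT
#' response window so that assignment recovers them.
#'
#' @param trials Trial table from [make_trials()].
#' @param trait Attentional trait (behavior scale, ~ standard normal).
#' @param seed Integer seed; identical seeds give identical streams.
#' @param ramp Stimulus transition duration (s).
#' @param hit_intercept,fa_intercept Probit intercepts for hit and
#'   false-alarm probabilities at trait 0.
#' @param rt_mean,rt_sd Press-latency distribution relative to trial onset
#'   (s), truncated to the response window.
#' @return Sorted numeric vector of press times.
#' @export
generate_press_stream <- function(trials, trait, seed, ramp = 1.6,
                                  hit_intercept = 1.0, fa_intercept = 1.0,
                                  rt_mean = 1.68, rt_sd = 0.25) {
  check_trials(trials)
  withr::with_seed(seed, {
    win <- gradcpt_window(trials$onset, ramp)
    p_press <- ifelse(trials$category == "frequent",
                      pnorm(hit_intercept + trait),
                      pnorm(-fa_intercept - trait))
    pressed <- runif(nrow(trials)) < p_press
    rt <- rnorm(sum(pressed), rt_mean, rt_sd)
    lo <- win[pressed, "start"] - trials$onset[pressed] + 1e-3
    hi <- win[pressed, "end"] - trials$onset[pressed] - 1e-3
    rt <- pmin(pmax(rt, lo), hi)
    sort(trials$onset[pressed] + rt)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `edges.tsv` (runs x edges, tab-delimited), `runs.csv` (run table),
#' and `truth.json` (planted edge indices plus the config) under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(cohort$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.csv(cohort$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(truth = cohort$truth, config = unclass(cohort$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
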