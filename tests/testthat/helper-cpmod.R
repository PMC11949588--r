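# small planted cohort used across tests: 30 nodes (435 edges), 10/10
# planted edges per sign with 3/3 shared, strong effect
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_nodes = 30, n_pos_edges = 10, n_neg_edges = 10,
         n_shared_pos = 3, n_shared_neg = 3, n_runs_per_modality = 40,
         effect_size = 0.8, noise_sd = 0.15, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# two-network toy atlas over n nodes, first half "A", second half "B"
toy_atlas <- function(n) {
  tibble::tibble(node = seq_len(n),
                 network = rep(c("A", "B"), each = n / 2))
}

# subject-wise visual/auditory behavior columns without assuming run order
behavior_by_subject <- function(runs) {
  v <- runs[runs$modality == "visual", c("subject", "behavior")]
  a <- runs[runs$modality == "auditory", c("subject", "behavior")]
  d <- merge(v, a, by = "subject", suffixes = c("_v", "_a"))
  tibble::tibble(visual = d$behavior_v, auditory = d$behavior_a)
}

# independent Pearson r via explicit sums (oracle, no call to cor())
pearson_by_hand <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
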