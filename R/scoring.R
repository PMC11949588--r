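#' Build a trial sequence for a continuous performance task
#'
#' Constructs the trial table the scoring functions consume: one row per
#' trial with onset time (s) and category (`"frequent"` or `"infrequent"`).
#' By default trials follow the gradual-onset CPT timing (a new stimulus
#' reaches maximum visibility every 1.6 s) with a 90/10 frequent/infrequent
#' split.
#'
#' @param n_trials Number of trials.
#' @param p_infrequent Probability that a trial is infrequent (rare target).
#' @param trial_dur Trial spacing in seconds (1.6 for gradCPT, 1.2 for the
#'   audio-visual CPT).
#' @param first_onset Onset of the first trial (s).
#' @param seed Optional seed controlling category placement; with `NULL` the
#'   current RNG state is used.
#' @return Tibble with columns `trial`, `onset`, `category`.
#' @export
make_trials <- function(n_trials, p_infrequent = 0.1, trial_dur = 1.6,
                        first_onset = 0, seed = NULL) {
  draw <- function() {
    cats <- ifelse(runif(n_trials) < p_infrequent, "infrequent", "frequent")
    tibble::tibble(
      trial = seq_len(n_trials),
      onset = first_onset + (seq_len(n_trials) - 1) * trial_dur,
      category = cats
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

check_trials <- function(trials) {
  req <- c("trial", "onset", "category")
  if (!all(req %in% names(trials))) {
    stop_input("trial table needs columns %s", paste(req, collapse = ", "))
  }
  if (is.unsorted(trials$onset, strictly = TRUE)) {
    stop_input("trial onsets must be strictly increasing")
  }
  if (!all(trials$category %in% c("frequent", "infrequent"))) {
    stop_input("trial categories must be 'frequent' or 'infrequent'")
  }
  invisible(trials)
}

check_presses <- function(presses) {
  if (is.data.frame(presses)) presses <- presses$time
  presses <- as.numeric(presses)
  if (is.unsorted(presses)) presses <- sort(presses)
  presses
}

# response-window of a gradCPT trial: from 70% presented (on-ramp) to 40%
# disappeared (off-ramp of the same stimulus); boundaries inclusive
gradcpt_window <- function(onset, ramp) {
  cbind(start = onset + 0.7 * ramp, end = onset + ramp + 0.4 * ramp)
}

#' Assign gradCPT key presses to trials
#'
#' In the gradual-onset CPT, stimuli cross-fade continuously, so a press
#' cannot simply be binned by trial boundaries. Assignment is iterative.
#' Pass 1 assigns unambiguous presses — those falling inside the window from
#' 70% presented to 40% disappeared of a stimulus — to that trial. Pass 2
#' takes the remaining presses in ascending time order and assigns each to
#' an adjacent unanswered trial: if only one neighbor is unanswered it
#' receives the press; if both are unanswered and either is infrequent the
#' press goes to the adjacent frequent trial, otherwise to the closer trial
#' (ties to the earlier trial). Presses before the first trial or after the
#' last window, or with no unanswered neighbor, stay unassigned. Each press
#' maps to at most one trial and each trial receives at most one press.
#'
#' @param trials Trial table from [make_trials()] (1.6-s spacing assumed
#'   unless `ramp` says otherwise).
#' @param presses Numeric vector of press times (s), or a data frame with a
#'   `time` column.
#' @param ramp Stimulus transition duration in seconds.
#' @return Tibble `trial`, `onset`, `category`, `pressed`, `press_time`,
#'   `rt` (press time minus trial onset). Attribute `"unassigned"` holds the
#'   times of presses that could not be assigned.
#' @export
assign_gradcpt_presses <- function(trials, presses, ramp = 1.6) {
  check_trials(trials)
  presses <- check_presses(presses)
  n <- nrow(trials)
  win <- gradcpt_window(trials$onset, ramp)
  assigned_trial <- rep(NA_integer_, length(presses))
  answered <- rep(FALSE, n)

  # pass 1: in-window presses to the current trial
  for (p in seq_along(presses)) {
    t <- presses[p]
    cur <- which(t >= win[, "start"] & t <= win[, "end"])
    if (length(cur) == 1 && !answered[cur]) {
      assigned_trial[p] <- cur
      answered[cur] <- TRUE
    }
  }

  # pass 2: ambiguous presses to adjacent unanswered trials
  for (p in which(is.na(assigned_trial))) {
    t <- presses[p]
    if (t < trials$onset[1] || t > win[n, "end"]) next  # out of task, logged
    cur <- which(t >= win[, "start"] & t <= win[, "end"])
    if (length(cur) == 1) {
      cand <- c(cur - 1L, cur + 1L)           # window trial already answered
    } else {
      prev <- max(which(win[, "end"] < t), 0L)  # gap between windows
      cand <- c(prev, prev + 1L)
    }
    cand <- cand[cand >= 1L & cand <= n]
    cand <- cand[!answered[cand]]
    if (length(cand) == 0) next
    pick <- if (length(cand) == 1) {
      cand
    } else if (sum(trials$category[cand] == "frequent") == 1) {
      cand[trials$category[cand] == "frequent"]
    } else {
      d <- pmax(0, win[cand, "start"] - t, t - win[cand, "end"])
      cand[which.min(d)]                      # which.min ties -> earlier
    }
    assigned_trial[p] <- pick
    answered[pick] <- TRUE
  }

  press_time <- rep(NA_real_, n)
  ok <- !is.na(assigned_trial)
  press_time[assigned_trial[ok]] <- presses[ok]
  out <- dplyr::mutate(trials,
    pressed = !is.na(press_time),
    press_time = press_time,
    rt = press_time - .data$onset
  )
  attr(out, "unassigned") <- presses[!ok]
  out
}

#' Assign and reassign audio-visual CPT key presses
#'
#' The audio-visual CPT presents a stimulus every 1.2 s; a correct response
#' to a frequent trial is a press within 1,200 ms of trial start. To allow
#' for reaction times longer than the trial, the first press of a trial is
#' reassigned to the previous frequent-category trial when all of: (a) the
#' trial received more than one press, (b) the first press came less than
#' 100 ms after trial start, and (c) no response had been made to that
#' previous frequent trial. The number of reassignments is recorded.
#'
#' @param trials Trial table (1.2-s grid).
#' @param presses Press times (s) or data frame with `time` column.
#' @param trial_dur Trial duration (s).
#' @param fast_press Fast-press threshold for reassignment (s).
#' @return Tibble as in [assign_gradcpt_presses()], plus attributes
#'   `"n_reassigned"` and `"unassigned"`.
#' @export
assign_avcpt_presses <- function(trials, presses, trial_dur = 1.2,
                                 fast_press = 0.1) {
  check_trials(trials)
  presses <- check_presses(presses)
  n <- nrow(trials)
  # baseline: bin presses by trial window [onset, onset + trial_dur)
  idx <- findInterval(presses, trials$onset)
  in_win <- idx >= 1 & idx <= n &
    presses < trials$onset[pmin(idx, n)] + trial_dur
  by_trial <- split(presses[in_win], idx[in_win])

  press_time <- rep(NA_real_, n)
  extra <- lapply(seq_len(n), function(i) numeric(0))
  for (nm in names(by_trial)) {
    i <- as.integer(nm)
    ps <- sort(by_trial[[nm]])
    press_time[i] <- ps[1]
    extra[[i]] <- ps[-1]
  }

  n_reassigned <- 0L
  for (i in seq_len(n)) {
    if (trials$category[i] != "frequent") next
    if (length(extra[[i]]) == 0 || is.na(press_time[i])) next
    first_rt <- press_time[i] - trials$onset[i]
    if (first_rt >= fast_press) next
    prev <- which(trials$category[seq_len(i - 1)] == "frequent")
    if (length(prev) == 0) next
    prev <- max(prev)
    if (!is.na(press_time[prev])) next
    press_time[prev] <- press_time[i]         # fast press answers prior trial
    press_time[i] <- extra[[i]][1]
    extra[[i]] <- extra[[i]][-1]
    n_reassigned <- n_reassigned + 1L
  }

  out <- dplyr::mutate(trials,
    pressed = !is.na(press_time),
    press_time = press_time,
    rt = press_time - .data$onset
  )
  attr(out, "n_reassigned") <- n_reassigned
  attr(out, "unassigned") <- presses[!in_win]
  out
}

#' Sensitivity (d') from hit and false-alarm counts
#'
#' d' is the inverse-normal-transformed hit rate minus the
#' inverse-normal-transformed false-alarm rate. Extreme rates are corrected
#' before the transform — a rate of 0 becomes `1/(2N)` and a rate of 1
#' becomes `1 - 1/(2N)`, with N the number of trials of that type — so d'
#' stays finite at ceiling performance. Negative d' (false alarms exceeding
#' hits) is admitted.
#'
#' @param n_hits,n_frequent Hits and total frequent (go) trials.
#' @param n_fas,n_infrequent False alarms and total infrequent (no-go)
#'   trials.
#' @return A single numeric d' value.
#' @examples
#' score_sensitivity(5, 10, 5, 10)   # chance -> 0
#' @export
score_sensitivity <- function(n_hits, n_frequent, n_fas, n_infrequent) {
  if (n_frequent <= 0 || n_infrequent <= 0) {
    stop_input("trial counts must be positive")
  }
  if (n_hits < 0 || n_fas < 0 || n_hits > n_frequent || n_fas > n_infrequent) {
    stop_input("counts out of range")
  }
  correct <- function(x, n) {
    r <- x / n
    if (r == 0) r <- 1 / (2 * n)
    if (r == 1) r <- 1 - 1 / (2 * n)
    r
  }
  qnorm(correct(n_hits, n_frequent)) - qnorm(correct(n_fas, n_infrequent))
}

#' Inverse reaction-time variability
#'
#' Mean RT divided by its standard deviation (sample SD, n - 1). Higher
#' values indicate more consistent responding; used as the sustained
#' attention measure where sensitivity is at ceiling (rare-target oddball
#' tasks). Scale-invariant in the RT unit.
#'
#' @param rts Numeric vector of reaction times (>= 2 values, SD > 0).
#' @return A single numeric score.
#' @examples
#' score_rt_variability(c(0.4, 0.5, 0.6))  # 5
#' @export
score_rt_variability <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 2) stop_input("need >= 2 reaction times")
  s <- sd(rts)
  if (s == 0) stop_input("RT standard deviation is zero; score undefined")
  mean(rts) / s
}

#' Run-level performance from a scored response map
#'
#' Summarizes an assigned trial/press map into the run-level measures used
#' for model training and validation: hit rate, false-alarm rate, d', RT
#' mean/SD, and inverse RT variability (when >= 2 RTs are available).
#'
#' @param responses Output of [assign_gradcpt_presses()] or
#'   [assign_avcpt_presses()].
#' @return One-row tibble with columns `n_frequent`, `n_infrequent`,
#'   `n_hits`, `n_fas`, `hit_rate`, `fa_rate`, `d_prime`, `rt_mean`,
#'   `rt_sd`, `inv_rt_var`, `n_reassigned`.
#' @export
score_run <- function(responses) {
  freq <- responses$category == "frequent"
  n_frequent <- sum(freq)
  n_infrequent <- sum(!freq)
  n_hits <- sum(responses$pressed & freq)
  n_fas <- sum(responses$pressed & !freq)
  rts <- responses$rt[responses$pressed & freq]
  rts <- rts[!is.na(rts)]
  tibble::tibble(
    n_frequent = n_frequent,
    n_infrequent = n_infrequent,
    n_hits = n_hits,
    n_fas = n_fas,
    hit_rate = n_hits / n_frequent,
    fa_rate = n_fas / n_infrequent,
    d_prime = score_sensitivity(n_hits, n_frequent, n_fas, n_infrequent),
    rt_mean = if (length(rts) >= 1) mean(rts) else NA_real_,
    rt_sd = if (length(rts) >= 2) sd(rts) else NA_real_,
    inv_rt_var = if (length(rts) >= 2 && sd(rts) > 0)
      score_rt_variability(rts) else NA_real_,
    n_reassigned = attr(responses, "n_reassigned") %||% 0L
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
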