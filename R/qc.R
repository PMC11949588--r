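#' Motion-based run exclusions
#'
#' Flags runs whose head motion disqualifies them: mean framewise
#' displacement above 0.15 mm, maximum displacement above 4 mm, or more than
#' half of frames censored. Thresholds are strict ("exceeded"): a run at
#' exactly the boundary is kept. Every run receives a machine-readable
#' reason (`"kept"` or a `;`-joined list of failed rules).
#'
#' @param runs Data frame with columns `mean_fd`, `max_disp`,
#'   `censored_frac` (an identifying column such as `run` is carried
#'   through).
#' @param fd_max Mean-FD threshold (mm).
#' @param disp_max Maximum-displacement threshold (mm).
#' @param censor_max Censored-frame fraction threshold.
#' @return Input tibble with added logical `excluded` and character
#'   `reason`.
#' @export
apply_motion_exclusions <- function(runs, fd_max = 0.15, disp_max = 4,
                                    censor_max = 0.5) {
  runs <- tibble::as_tibble(runs)
  for (f in c("mean_fd", "max_disp", "censored_frac")) {
    if (!f %in% names(runs)) stop_input("run table lacks field `%s`", f)
    if (anyNA(runs[[f]])) {
      bad <- which(is.na(runs[[f]]))[1]
      id <- if ("run" %in% names(runs)) runs$run[bad] else bad
      stop_input("run %s has missing `%s`", id, f)
    }
  }
  reasons <- purrr::pmap_chr(
    list(runs$mean_fd, runs$max_disp, runs$censored_frac),
    function(fd, disp, cen) {
      r <- c(if (fd > fd_max) "mean_fd", if (disp > disp_max) "max_disp",
             if (cen > censor_max) "censored_frac")
      if (length(r) == 0) "kept" else paste(r, collapse = ";")
    })
  dplyr::mutate(runs, excluded = reasons != "kept", reason = reasons)
}

#' Low-outlier exclusions by standard-deviation rule
#'
#' Excludes values more than `k` standard deviations below the mean, with
#' mean and SD computed once over the full input (no re-iteration after
#' removal). Applied to hit rates (task-compliance screen) and to the
#' run-level performance measure.
#'
#' @param values Numeric vector of per-run values.
#' @param k SD multiplier (2.5 by default).
#' @return Tibble with columns `value`, `excluded`, `reason` (`"kept"` or
#'   `"low_outlier"`).
#' @export
apply_deviation_exclusions <- function(values, k = 2.5) {
  if (length(values) < 2) stop_input("need >= 2 values for the SD rule")
  m <- mean(values)
  s <- sd(values)
  if (is.na(s)) {
    warn("SD undefined; no deviation exclusions applied")
    excl <- rep(FALSE, length(values))
  } else {
    excl <- values < m - k * s
  }
  tibble::tibble(value = values, excluded = excl,
                 reason = ifelse(excl, "low_outlier", "kept"))
}

#' Full run-level quality control
#'
#' Applies the exclusion cascade in the study's narrative order: motion
#' rules first; then, among surviving runs, the 2.5-SD low-hit-rate rule
#' (computed within modality, when a `hit_rate` column is present); then the
#' 2.5-SD low-performance rule (computed across all surviving runs, when a
#' `performance` column is present). SD references are computed over runs
#' surviving the earlier stages, in a single pass per rule.
#'
#' @param runs Run table with motion columns, optionally `hit_rate`,
#'   `performance` and `modality`.
#' @param k SD multiplier for the behavioral rules.
#' @inheritParams apply_motion_exclusions
#' @return Run table with `excluded` and `reason` columns; the reason names
#'   the first rule that removed the run.
#' @export
qc_runs <- function(runs, fd_max = 0.15, disp_max = 4, censor_max = 0.5,
                    k = 2.5) {
  out <- apply_motion_exclusions(runs, fd_max, disp_max, censor_max)
  if ("hit_rate" %in% names(out)) {
    keep <- !out$excluded
    grp <- if ("modality" %in% names(out)) out$modality[keep] else
      rep("all", sum(keep))
    idx <- which(keep)
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      if (length(ii) < 2) next
      dev <- apply_deviation_exclusions(out$hit_rate[ii], k)
      hit <- ii[dev$excluded]
      out$excluded[hit] <- TRUE
      out$reason[hit] <- "low_hit_rate"
    }
  }
  if ("performance" %in% names(out)) {
    ii <- which(!out$excluded)
    if (length(ii) >= 2) {
      dev <- apply_deviation_exclusions(out$performance[ii], k)
      hit <- ii[dev$excluded]
      out$excluded[hit] <- TRUE
      out$reason[hit] <- "low_performance"
    }
  }
  out
}
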