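#' Remove trials with excessive response times
#'
#' Drops single trials slower than the threshold (default 20 s), the task's
#' only exclusion rule; rows with missing response times are kept, and order
#' is preserved.
#'
#' @param trials Data frame with an `rt_ms` column (milliseconds).
#' @param threshold_s Threshold in seconds.
#' @return A list: `kept` (the surviving rows) and `n_removed`.
#' @export
filter_long_trials <- function(trials, threshold_s = 20) {
  rt <- trials$rt_ms
  if (is.null(rt)) return(list(kept = trials, n_removed = 0L))
  if (any(rt < 0, na.rm = TRUE)) {
    stop("filter_long_trials: negative response time")
  }
  drop <- !is.na(rt) & rt > threshold_s * 1000
  list(kept = trials[!drop, , drop = FALSE], n_removed = sum(drop))
}

good_indicator <- function(block) {
  as.integer(block$choice == block$good_lake[1L])
}

#' Immediate cue following: the choice on trial 5
#'
#' Indicator that the first post-cue trial (trial `cue_after_trial + 1`,
#' trial 5 in the standard design) chose the good lake. When that trial was
#' removed by the response-time filter the result is `NA` (absence of
#' evidence, not failure to follow).
#'
#' @param block One block's trials.
#' @param cue_after_trial Cue position (defaults to the block's own column,
#'   else 4).
#' @return 0, 1 or `NA`.
#' @export
immediate_follow <- function(block, cue_after_trial = NULL) {
  cue <- cue_after_trial %||% block$cue_after_trial[1L] %||% 4L
  i <- which(block$trial == cue + 1L)
  if (!length(i)) return(NA_integer_)
  good_indicator(block)[i[1L]]
}

#' Long-term performance: good-lake choice share over trials 6-15
#'
#' Mean of the good-lake indicator over the surviving post-cue trials
#' (from `cue_after_trial + 2` through the end of the block).
#'
#' @inheritParams immediate_follow
#' @return A proportion in \[0, 1\] (`NaN` if no trial survives).
#' @export
longterm_performance <- function(block, cue_after_trial = NULL) {
  cue <- cue_after_trial %||% block$cue_after_trial[1L] %||% 4L
  keep <- block$trial >= cue + 2L
  mean(good_indicator(block)[keep])
}

#' First trial of a run of consecutive good choices
#'
#' The block is said to have converged at the first position (in the
#' surviving-trial sequence, original order) at which the good lake was
#' chosen `run_length` times in a row. Blocks that never converge are
#' censored: the value is `n_trials + 1` with `converged = FALSE`, so cohort
#' summaries remain computable.
#'
#' @param block One block's trials.
#' @param run_length Required run length (default 3).
#' @param n_trials Block length used for the censor code.
#' @return A list: `trial` (position of the run start, or `n_trials + 1`) and
#'   `converged` (logical).
#' @export
convergence_trial <- function(block, run_length = 3, n_trials = 15) {
  g <- good_indicator(block[order(block$trial), , drop = FALSE])
  n <- length(g)
  if (n >= run_length) {
    runs <- vapply(seq_len(n - run_length + 1L),
                   function(t) all(g[t:(t + run_length - 1L)] == 1L),
                   logical(1))
    t0 <- which(runs)
    if (length(t0)) return(list(trial = t0[1L], converged = TRUE))
  }
  list(trial = n_trials + 1L, converged = FALSE)
}

#' U-value: normalized entropy of the choice sequence
#'
#' Choice stochasticity as the normalized first-order Shannon entropy of the
#' block's binary choices: with `p` the proportion of choices of lake A,
#' `U = -(p log2 p + (1-p) log2 (1-p))`, taking `0 log 0 = 0`. 0 for a
#' constant sequence, 1 at `p = 0.5`; symmetric in `p` and `1 - p`. Scored
#' over all surviving trials of the block by default.
#'
#' @param block One block's trials (or a 0/1 vector of choices).
#' @param trials_window Optional trial indices to score (e.g. `6:15`).
#' @return U in \[0, 1\].
#' @export
u_value <- function(block, trials_window = NULL) {
  ch <- if (is.data.frame(block)) {
    b <- block
    if (!is.null(trials_window)) b <- b[b$trial %in% trials_window, ,
                                        drop = FALSE]
    b$choice
  } else block
  if (!length(ch)) return(NA_real_)
  p <- mean(ch)
  if (p <= 0 || p >= 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

#' Performance bonus in pence
#'
#' 20 pence per completed block of 50 fish caught, capped at 180 pence
#' (the £1.80 maximum bonus).
#'
#' @param total_fish Total fish caught (>= 0).
#' @param rate_pence Pence paid per block of fish.
#' @param block_fish Fish per pay block.
#' @param cap_pence Maximum bonus.
#' @param pro_rata Pay fractional blocks proportionally instead of flooring.
#' @return Bonus in pence.
#' @export
bonus_pence <- function(total_fish, rate_pence = 20, block_fish = 50,
                        cap_pence = 180, pro_rata = FALSE) {
  if (any(total_fish < 0)) stop("bonus_pence: negative fish count")
  raw <- if (pro_rata) total_fish / block_fish * rate_pence
         else floor(total_fish / block_fish) * rate_pence
  pmin(raw, cap_pence)
}

#' Per-block behavioural measures for a cohort
#'
#' Applies the response-time filter, then computes for every
#' participant-condition block the preregistered-style measures: immediate
#' cue following (trial 5), long-term performance (trials 6-15), convergence
#' trial (first run of three consecutive good choices, censored at
#' `n_trials + 1`), U-value choice stochasticity, trials excluded, and the
#' block's bonus.
#'
#' @param data Trials data frame (multiple participants).
#' @param config A [task_config()].
#' @param rt_threshold_s Exclusion threshold in seconds; `Inf` disables.
#' @return A data frame with one row per participant-condition.
#' @export
cohort_measures <- function(data, config = task_config(),
                            rt_threshold_s = 20) {
  flt <- filter_long_trials(data, rt_threshold_s)
  kept <- flt$kept
  key_all <- interaction(data$participant_id, data$condition, drop = TRUE)
  removed <- table(key_all) - table(factor(
    interaction(kept$participant_id, kept$condition, drop = TRUE),
    levels = levels(key_all)))
  out <- lapply(split(kept, list(kept$participant_id, kept$condition),
                      drop = TRUE), function(b) {
    cv <- convergence_trial(b, n_trials = config$n_trials)
    data.frame(participant_id = b$participant_id[1L],
               condition = b$condition[1L],
               immediate_follow = immediate_follow(
                 b, config$cue_after_trial),
               longterm_perf = longterm_performance(
                 b, config$cue_after_trial),
               convergence_trial = cv$trial,
               converged_flag = cv$converged,
               u_value = u_value(b),
               bonus_pence = bonus_pence(sum(b$reward)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$n_excluded <- as.integer(removed[paste(res$participant_id,
                                             res$condition, sep = ".")])
  rownames(res) <- NULL
  res
}

#' Bootstrap cohort summaries by condition
#'
#' Per-condition means of each behavioural measure with percentile bootstrap
#' confidence intervals over participants, plus paired condition differences
#' (computed on participants contributing both conditions). A lightweight
#' stand-in for mixed-effects inference: it summarises directions and
#' uncertainty, not significance tests.
#'
#' @param measures Output of [cohort_measures()].
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Coverage of the percentile interval.
#' @return A list of data frames `means` (condition x measure) and
#'   `differences` (pairwise condition contrasts per measure).
#' @export
summarize_cohort <- function(measures, n_boot = 2000, seed = 1L,
                             conf = 0.95) {
  stopifnot(length(unique(measures$participant_id)) >= 2)
  set.seed(seed)
  cols <- c("immediate_follow", "longterm_perf", "convergence_trial",
            "u_value")
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  boot_ci <- function(v) {
    v <- v[!is.na(v)]
    reps <- vapply(seq_len(n_boot),
                   function(i) mean(v[sample.int(length(v),
                                                 replace = TRUE)]),
                   numeric(1))
    c(mean = mean(v), quantile(reps, probs))
  }
  means <- list()
  for (cond in sort(unique(measures$condition))) {
    m <- measures[measures$condition == cond, , drop = FALSE]
    for (col in cols) {
      ci <- boot_ci(m[[col]])
      means[[length(means) + 1L]] <- data.frame(
        condition = cond, measure = col, mean = ci[[1L]],
        ci_lo = ci[[2L]], ci_hi = ci[[3L]], n = sum(!is.na(m[[col]])))
    }
  }
  diffs <- list()
  conds <- sort(unique(measures$condition))
  if (length(conds) >= 2) {
    prs <- utils::combn(conds, 2, simplify = FALSE)
    for (pr in prs) {
      a <- measures[measures$condition == pr[2L], , drop = FALSE]
      b <- measures[measures$condition == pr[1L], , drop = FALSE]
      ids <- intersect(a$participant_id, b$participant_id)
      for (col in cols) {
        d <- a[[col]][match(ids, a$participant_id)] -
          b[[col]][match(ids, b$participant_id)]
        ci <- boot_ci(d)
        diffs[[length(diffs) + 1L]] <- data.frame(
          contrast = paste(pr[2L], "-", pr[1L]), measure = col,
          mean = ci[[1L]], ci_lo = ci[[2L]], ci_hi = ci[[3L]],
          n = sum(!is.na(d)))
      }
    }
  }
  list(means = do.call(rbind, means), differences = do.call(rbind, diffs))
}
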