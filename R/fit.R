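#' Settings for per-participant maximum-likelihood fitting
#'
#' Estimation minimises the summed session negative log-likelihood over the
#' six model parameters inside the box bounds of [param_bounds()], using
#' L-BFGS-B from `n_starts` random starting points (deterministic given
#' `start_seed`) plus the midpoint of the bounds box.
#'
#' @param n_starts Number of random multi-start points (>= 1); the bounds-box
#'   midpoint is always added.
#' @param start_seed Integer seed from which the start points are drawn.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence tolerance (see [stats::optim()]).
#' @param ceiling_tol Tie tolerance (nats) for the boundary refinement of the
#'   post-cue precision estimates: when a fully greedy-consistent post-cue
#'   sequence makes the likelihood flat-to-machine-precision in `bboost`, the
#'   true maximum sits at the ceiling even though the quasi-Newton gradient
#'   underflows; the ceiling is accepted whenever it is within this tolerance
#'   of the best multi-start value.
#' @return An object of class `"fit_control"`.
#' @export
fit_control <- function(n_starts = 10, start_seed = 1L, maxit = 500,
                        factr = 1e7, ceiling_tol = 1e-9) {
  stopifnot(n_starts >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 start_seed = as.integer(start_seed),
                 maxit = maxit, factr = factr, ceiling_tol = ceiling_tol),
            class = "fit_control")
}

#' Classify a fitted post-cue precision as exploiter ("high") or explorer
#'
#' A participant-condition is classified `"high"` when the estimated
#' post-cue precision is close to its ceiling of 50 — strictly above 40.
#' Exactly 40 is `"low"`.
#'
#' @param bboost_hat Fitted post-cue precision(s) in \[0.1, 50\].
#' @return Character vector of `"high"` / `"low"`.
#' @export
classify_bboost <- function(bboost_hat) {
  if (any(bboost_hat < 0.1 - 1e-9 | bboost_hat > 50 + 1e-9)) {
    stop("classify_bboost: estimate outside [0.1, 50]")
  }
  ifelse(bboost_hat > 40, "high", "low")
}

# split one participant's trials into the list-of-blocks form used by the
# likelihood, sorted by trial within block
split_blocks <- function(trials) {
  lapply(split(trials, trials$condition),
         function(b) b[order(b$trial), , drop = FALSE])
}

#' Fit the boosted Q-learning model to one participant
#'
#' Constrained maximum-likelihood estimation of the six parameters from the
#' participant's blocks (jointly: control identifies `alpha` and `beta`, each
#' social block identifies its own boost pair). Runs `n_starts` seeded random
#' starts plus the bounds-box midpoint of L-BFGS-B, keeps the best, then
#' checks the precision-boost ceiling as a boundary candidate (see
#' [fit_control()]). Never throws on optimizer failure: if every start fails
#' the result is flagged unconverged.
#'
#' @param blocks A list of block data frames (one per condition), or a single
#'   data frame holding one participant's trials with a `condition` column.
#'   Trials should already be response-time filtered (see
#'   [filter_long_trials()]).
#' @param settings A [fit_control()].
#' @param config A [task_config()].
#' @return An object of class `"bandit_fit"`: list with `params_hat`
#'   ([agent_params()]), `nll`, `n_trials_used`, `n_starts`, `converged`,
#'   `bboost_class_advice`, `bboost_class_observation`.
#' @export
fit_participant <- function(blocks, settings = fit_control(),
                            config = task_config()) {
  if (is.data.frame(blocks)) blocks <- split_blocks(blocks)
  args <- lapply(blocks, function(b) {
    condition <- match.arg(b$condition[1L], CONDITIONS)
    social <- condition != "control"
    list(trial = as.integer(b$trial), choice = as.integer(b$choice),
         reward = as.numeric(b$reward), social = social,
         cue_target = if (social) as.integer(b$cue_target[1L]) else 0L,
         condition = condition)
  })
  bnds <- param_bounds()
  lower <- bnds$lower
  upper <- bnds$upper
  obs <- config$q_max_mode == "observed_max"

  objective <- function(p) {
    nll <- 0
    for (a in args) {
      qb <- switch(a$condition, advice = c(p[3L], p[5L]),
                   observation = c(p[4L], p[6L]), control = c(0, 0))
      nll <- nll + block_nll_cpp(a$trial, a$choice, a$reward, a$social,
                                 a$cue_target, config$cue_after_trial,
                                 p[1L], p[2L], qb[1L], qb[2L],
                                 config$q_init, obs, config$q_max_fixed)
    }
    nll
  }

  midpoint <- (lower + upper) / 2
  set.seed(settings$start_seed)
  starts <- c(list(midpoint),
              replicate(settings$n_starts,
                        runif(6, lower, upper), simplify = FALSE))
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      optim(s, objective, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = settings$maxit, factr = settings$factr,
                           parscale = upper - lower)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) {
    best <- list(par = midpoint, value = objective(midpoint))
    converged <- FALSE
  }
  par <- clamp(best$par, lower, upper)
  val <- best$value
  # boundary refinement: accept the bboost ceiling on a likelihood tie
  for (i in c(5L, 6L)) {
    cand <- par
    cand[i] <- upper[i]
    v <- objective(cand)
    if (v <= val + settings$ceiling_tol) {
      par <- cand
      val <- min(val, v)
    }
  }
  params_hat <- agent_params(par[1L], par[2L], par[3L], par[4L],
                             par[5L], par[6L])
  structure(list(
    params_hat = params_hat,
    nll = val,
    n_trials_used = sum(vapply(args, function(a) length(a$choice),
                               integer(1))),
    n_starts = length(starts),
    converged = converged,
    bboost_class_advice = classify_bboost(par[5L]),
    bboost_class_observation = classify_bboost(par[6L])
  ), class = "bandit_fit")
}

#' @export
print.bandit_fit <- function(x, ...) {
  cat("Boosted Q-learning fit (", x$n_trials_used, " trials, ",
      x$n_starts, " starts, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(round(unclass(x$params_hat), 4))
  cat("NLL:", format(x$nll, digits = 6), "nats;",
      "advice:", x$bboost_class_advice,
      "| observation:", x$bboost_class_observation, "\n")
  invisible(x)
}

four_group <- function(class_adv, class_obs) {
  ifelse(class_adv == "high" & class_obs == "high", "both",
         ifelse(class_adv == "high", "advice",
                ifelse(class_obs == "high", "observation", "none")))
}

#' Fit the boosted Q-learning model to a cohort of participants
#'
#' The main model-fitting entry point. Takes a trials table (one row per
#' trial, as produced by [generate_cohort()] or read from CSV), applies the
#' response-time exclusion rule, fits every participant independently by
#' constrained multi-start maximum likelihood, classifies each social
#' condition's post-cue precision as exploiter (`high`, > 40 of a ceiling of
#' 50) or explorer (`low`), and partitions the cohort into the four boost
#' groups (none / observation / advice / both).
#'
#' @param data Trials data frame with columns `participant_id`, `condition`,
#'   `trial`, `choice`, `reward`, `good_lake`, `cue_target`, and optionally
#'   `rt_ms`.
#' @param config A [task_config()].
#' @param control A [fit_control()]; each participant's start seed is derived
#'   deterministically from `control$start_seed` and their position, so the
#'   whole fit is reproducible.
#' @param rt_threshold_s Response-time exclusion threshold in seconds
#'   (trials slower than this are dropped before fitting); `Inf` disables.
#' @return An object of class `"social_qlearn"` with a `fits` data frame
#'   (one row per participant: estimates, `nll`, `converged`, classes and
#'   `group4`) and supporting metadata. Participants missing one of the three
#'   conditions are skipped with a warning.
#' @seealso [summary.social_qlearn()], [coef.social_qlearn()],
#'   [predict.social_qlearn()], [simulate.social_qlearn()]
#' @export
social_qlearn <- function(data, config = task_config(),
                          control = fit_control(), rt_threshold_s = 20) {
  cl <- match.call()
  if (is.finite(rt_threshold_s) && "rt_ms" %in% names(data)) {
    data <- filter_long_trials(data, rt_threshold_s)$kept
  }
  ids <- unique(data$participant_id)
  rows <- vector("list", length(ids))
  results <- vector("list", length(ids))
  skipped <- character(0)
  for (k in seq_along(ids)) {
    pt <- data[data$participant_id == ids[k], , drop = FALSE]
    if (!setequal(unique(pt$condition), CONDITIONS)) {
      skipped <- c(skipped, as.character(ids[k]))
      next
    }
    st <- control
    st$start_seed <- mix_seed(control$start_seed, k)
    f <- fit_participant(pt, st, config)
    results[[k]] <- f
    p <- f$params_hat
    rows[[k]] <- data.frame(
      participant_id = ids[k],
      alpha_hat = p[["alpha"]], beta_hat = p[["beta"]],
      qboost_adv_hat = p[["qboost_advice"]],
      qboost_obs_hat = p[["qboost_observation"]],
      bboost_adv_hat = p[["bboost_advice"]],
      bboost_obs_hat = p[["bboost_observation"]],
      nll = f$nll, converged = f$converged,
      class_adv = f$bboost_class_advice,
      class_obs = f$bboost_class_observation,
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped),
            " participant(s) with missing blocks: ",
            paste(head(skipped, 5), collapse = ", "))
  }
  fits <- do.call(rbind, rows)
  if (is.null(fits)) {
    fits <- data.frame(participant_id = character(0))
  } else {
    fits$group4 <- four_group(fits$class_adv, fits$class_obs)
    rownames(fits) <- NULL
  }
  structure(list(fits = fits, results = results[!vapply(results, is.null,
                                                        logical(1))],
                 config = config, control = control,
                 data = data, skipped = skipped, call = cl),
            class = "social_qlearn")
}

#' Four-group partition and high-precision shares of a fitted cohort
#'
#' @param object A `"social_qlearn"` fit.
#' @return A list with `shares` (proportion classified high per social
#'   condition and jointly) and `groups` (counts of the four-group
#'   partition).
#' @export
high_shares <- function(object) {
  f <- object$fits
  if (!nrow(f)) return(list(shares = c(advice = NA, observation = NA,
                                       both = NA), groups = table(character(0))))
  list(shares = c(advice = mean(f$class_adv == "high"),
                  observation = mean(f$class_obs == "high"),
                  both = mean(f$class_adv == "high" & f$class_obs == "high")),
       groups = table(factor(f$group4,
                             levels = c("none", "observation", "advice",
                                        "both"))))
}
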