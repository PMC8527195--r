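#' Specification of a synthetic cohort
#'
#' Describes the population from which synthetic participants are drawn. The
#' defaults are calibration targets echoing the published cohort summaries,
#' not claims about the original population: learning rates follow a
#' symmetric Beta rescaled to \[0.05, 0.95\] (median 0.5); baseline precision
#' is lognormal clipped to \[0.1, 50\], with its median (0.8) calibrated on
#' the task's reward scale so that control-block long-term performance sits
#' near the observed 0.70 rather than at ceiling; value boosts are a
#' point mass at 1 (full adoption) with a Beta tail; post-cue precision is
#' bimodal — at the ceiling of 50 with the stated probabilities, otherwise
#' drawn from a genuinely exploratory low component; the paranoia covariate
#' is a right-skewed discretized gamma on the 0-40 questionnaire range.
#'
#' High/low ceiling labels are correlated across the two social conditions
#' through a shared latent Bernoulli, so that the advice, observation and
#' joint shares (defaults 0.39 / 0.34 / 0.18) are hit simultaneously; this
#' requires `p_high_joint >= p_high_advice * p_high_observation`.
#'
#' Paranoia enters twice, both on log-odds scales centred at the mean score:
#' `paranoia_qboost_slope` lowers the probability (and tail size) of fully
#' adopting advice, and `paranoia_phigh_slope` lowers the shared latent
#' probability of ceiling post-cue precision. Both default negative.
#'
#' @param n_participants Cohort size.
#' @param alpha_shape Shape of the symmetric Beta for the learning rate.
#' @param beta_meanlog,beta_sdlog Lognormal parameters of baseline precision.
#' @param qboost_point_mass Baseline probability of full advice/observation
#'   adoption (value boost exactly 1).
#' @param qboost_tail_shape1,qboost_tail_shape2 Beta parameters of the
#'   partial-adoption tail.
#' @param p_high_advice,p_high_observation,p_high_joint Probabilities of
#'   ceiling post-cue precision in each condition and in both.
#' @param bboost_low_meanlog,bboost_low_sdlog,bboost_low_max Lognormal
#'   parameters (and clip ceiling) of the exploratory low-precision
#'   component.
#' @param bboost_high_value The precision ceiling (50).
#' @param paranoia_shape,paranoia_scale,paranoia_max Discretized-gamma
#'   parameters of the paranoia score.
#' @param paranoia_qboost_slope Per-point change in the log-odds of full
#'   advice adoption (<= 0).
#' @param paranoia_phigh_slope Per-point change in the log-odds of the
#'   shared high-precision latent (<= 0).
#' @param slow_trial_rate Probability a trial's response time exceeds 20 s.
#' @param rt_meanlog,rt_sdlog Lognormal parameters of ordinary response
#'   times (ms).
#' @param seed Master seed for the cohort.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 500,
                        alpha_shape = 2,
                        beta_meanlog = log(0.8), beta_sdlog = 0.65,
                        qboost_point_mass = 0.6,
                        qboost_tail_shape1 = 1.5, qboost_tail_shape2 = 1.2,
                        p_high_advice = 0.39, p_high_observation = 0.34,
                        p_high_joint = 0.18,
                        bboost_low_meanlog = log(0.6),
                        bboost_low_sdlog = 0.5, bboost_low_max = 20,
                        bboost_high_value = 50,
                        paranoia_shape = 1.5, paranoia_scale = 6,
                        paranoia_max = 40,
                        paranoia_qboost_slope = -0.08,
                        paranoia_phigh_slope = -0.05,
                        slow_trial_rate = 0.003, rt_meanlog = log(1500),
                        rt_sdlog = 0.5, seed = 1L) {
  stopifnot(n_participants >= 1,
            p_high_advice >= 0, p_high_advice <= 1,
            p_high_observation >= 0, p_high_observation <= 1,
            p_high_joint <= min(p_high_advice, p_high_observation),
            slow_trial_rate >= 0, slow_trial_rate <= 1,
            paranoia_qboost_slope <= 0, paranoia_phigh_slope <= 0)
  if (p_high_joint > 0 &&
      p_high_joint < p_high_advice * p_high_observation - 1e-12) {
    stop("cohort_spec: p_high_joint below the independence bound ",
         "p_high_advice * p_high_observation cannot be represented by a ",
         "shared positive latent")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

# (q, a, o) of the shared-latent construction Z~Bern(q), A=Z&Bern(a),
# O=Z&Bern(o) hitting the three target shares exactly
latent_probs <- function(spec) {
  if (spec$p_high_joint <= 0) {
    # independence fallback: no shared latent
    return(c(q = 1, a = spec$p_high_advice, o = spec$p_high_observation))
  }
  q <- spec$p_high_advice * spec$p_high_observation / spec$p_high_joint
  q <- min(q, 1)
  c(q = q, a = spec$p_high_advice / q, o = spec$p_high_observation / q)
}

shift_logit <- function(p, delta) plogis(qlogis(clamp(p, 1e-9, 1 - 1e-9)) +
                                           delta)

#' Draw one synthetic agent
#'
#' Samples the paranoia score first, then the six model parameters with the
#' two paranoia linkages applied; all values respect the [param_bounds()]
#' box. Uses the current RNG state (seed upstream).
#'
#' @param spec A [cohort_spec()].
#' @return A list: `params` ([agent_params()]), `paranoia`, and the ground
#'   truth labels `high_advice`, `high_observation`.
#' @export
sample_agent <- function(spec) {
  paranoia <- min(round(rgamma(1, spec$paranoia_shape,
                               scale = spec$paranoia_scale)),
                  spec$paranoia_max)
  pc <- paranoia - spec$paranoia_shape * spec$paranoia_scale

  lp <- latent_probs(spec)
  z <- runif(1) < shift_logit(lp[["q"]], spec$paranoia_phigh_slope * pc)
  high_adv <- z && runif(1) < lp[["a"]]
  high_obs <- z && runif(1) < lp[["o"]]

  alpha <- 0.05 + 0.9 * rbeta(1, spec$alpha_shape, spec$alpha_shape)
  beta <- clamp(rlnorm(1, spec$beta_meanlog, spec$beta_sdlog), 0.1, 50)

  tail_q <- function() rbeta(1, spec$qboost_tail_shape1,
                             spec$qboost_tail_shape2)
  qb_obs <- if (runif(1) < spec$qboost_point_mass) 1 else tail_q()
  w1 <- shift_logit(spec$qboost_point_mass, spec$paranoia_qboost_slope * pc)
  qb_adv <- if (runif(1) < w1) 1 else
    shift_logit(tail_q(), spec$paranoia_qboost_slope * pc)

  low_b <- function() clamp(rlnorm(1, spec$bboost_low_meanlog,
                                   spec$bboost_low_sdlog),
                            0.1, spec$bboost_low_max)
  bb_adv <- if (high_adv) spec$bboost_high_value else low_b()
  bb_obs <- if (high_obs) spec$bboost_high_value else low_b()

  list(params = agent_params(alpha, beta, qb_adv, qb_obs, bb_adv, bb_obs),
       paranoia = paranoia, high_advice = high_adv,
       high_observation = high_obs)
}

block_order_table <- function() {
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
             c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(apply(m, 1, function(i) CONDITIONS[i]))
}

#' Generate a full synthetic cohort
#'
#' Draws `n_participants` agents from the spec, runs each through a
#' three-block session with block orders counterbalanced round-robin over
#' all six permutations, attaches lognormal response times with a
#' `slow_trial_rate` fraction exceeding 20 s, and returns both the trial
#' table and the ground-truth parameter table. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @return A list of data frames: `trials` (one row per trial, flat CSV
#'   schema) and `truth` (one row per participant with every sampled
#'   parameter and label).
#' @export
generate_cohort <- function(spec, config = task_config()) {
  orders <- block_order_table()
  trials <- vector("list", spec$n_participants)
  truth <- vector("list", spec$n_participants)
  nt <- 3L * config$n_trials
  for (p in seq_len(spec$n_participants)) {
    id <- sprintf("P%05d", p)
    set.seed(mix_seed(spec$seed, c(1L, p)))
    ag <- sample_agent(spec)
    ord <- orders[(p - 1L) %% 6L + 1L, ]
    ses <- simulate_session(config, ag$params, ord,
                            seed = mix_seed(spec$seed, c(2L, p)))
    set.seed(mix_seed(spec$seed, c(3L, p)))
    rt <- rlnorm(nt, spec$rt_meanlog, spec$rt_sdlog)
    slow <- runif(nt) < spec$slow_trial_rate
    rt[slow] <- runif(sum(slow), 20500, 60000)
    ses$rt_ms <- rt
    ses$participant_id <- id
    ses$paranoia <- ag$paranoia
    trials[[p]] <- ses
    pr <- ag$params
    truth[[p]] <- data.frame(
      participant_id = id, paranoia = ag$paranoia,
      alpha = pr[["alpha"]], beta = pr[["beta"]],
      qboost_advice = pr[["qboost_advice"]],
      qboost_observation = pr[["qboost_observation"]],
      bboost_advice = pr[["bboost_advice"]],
      bboost_observation = pr[["bboost_observation"]],
      high_advice = ag$high_advice, high_observation = ag$high_observation,
      block_order = paste(ord, collapse = ">"),
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  cols <- c("participant_id", "condition", "block_order", "trial", "choice",
            "reward", "rt_ms", "good_lake", "cue_target", "cue_after_trial",
            "paranoia")
  list(trials = trials[, cols], truth = do.call(rbind, truth))
}

#' Closed-loop parameter-recovery experiment
#'
#' Generates a synthetic cohort with known parameters, fits every
#' participant, and compares estimates with the generating truth: per-
#' parameter bias and median absolute error, the high/low post-cue precision
#' confusion matrix per condition, and estimated versus true ceiling shares.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @param settings A [fit_control()].
#' @return An object of class `"recovery_report"`: list with `parameters`
#'   (bias/MAE table), `confusion_advice`, `confusion_observation`,
#'   `shares` (true and estimated high shares), `fit` (the
#'   `"social_qlearn"` object) and `truth`.
#' @export
recovery_experiment <- function(spec, config = task_config(),
                                settings = fit_control()) {
  gen <- generate_cohort(spec, config)
  fit <- social_qlearn(gen$trials, config, settings)
  truth <- gen$truth[match(fit$fits$participant_id,
                           gen$truth$participant_id), ]
  est <- coef(fit)
  pars <- colnames(est)
  ptab <- do.call(rbind, lapply(pars, function(pn) {
    err <- est[, pn] - truth[[pn]]
    data.frame(parameter = pn, bias = mean(err), mae = median(abs(err)),
               cor_spearman = suppressWarnings(
                 cor(est[, pn], truth[[pn]], method = "spearman")))
  }))
  conf <- function(true_high, cls) {
    table(truth = factor(ifelse(true_high, "high", "low"),
                         levels = c("high", "low")),
          estimated = factor(cls, levels = c("high", "low")))
  }
  hs <- high_shares(fit)
  structure(list(
    parameters = ptab,
    confusion_advice = conf(truth$high_advice, fit$fits$class_adv),
    confusion_observation = conf(truth$high_observation,
                                 fit$fits$class_obs),
    shares = rbind(
      true = c(advice = mean(truth$high_advice),
               observation = mean(truth$high_observation),
               both = mean(truth$high_advice & truth$high_observation)),
      estimated = hs$shares),
    fit = fit, truth = truth), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Closed-loop recovery,", nrow(x$truth), "participants\n\n")
  print(transform(x$parameters, bias = round(bias, 3), mae = round(mae, 3),
                  cor_spearman = round(cor_spearman, 3)))
  cat("\nCeiling (high) shares:\n")
  print(round(x$shares, 3))
  cat("\nAdvice confusion:\n")
  print(x$confusion_advice)
  cat("\nObservation confusion:\n")
  print(x$confusion_observation)
  invisible(x)
}
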