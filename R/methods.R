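# per-trial choice probabilities along one observed block (teacher-forced),
# used by predict/residuals
block_trajectory <- function(block, params, config) {
  block <- block[order(block$trial), , drop = FALSE]
  condition <- block$condition[1L]
  social <- condition != "control"
  qb <- boost_for(params, condition)
  q <- c(config$q_init, config$q_init)
  b <- params[["beta"]]
  boosted <- FALSE
  rmax <- -Inf
  n <- nrow(block)
  p_good <- p_choice <- numeric(n)
  for (i in seq_len(n)) {
    if (social && !boosted && block$trial[i] > config$cue_after_trial) {
      qmax <- if (config$q_max_mode == "observed_max") {
        max(rmax, config$q_init)
      } else config$q_max_fixed
      st <- apply_social_boost(list(q = q, beta = b),
                               as.integer(block$cue_target[1L]),
                               qb[1L], qb[2L], qmax)
      q <- st$q
      b <- st$beta
      boosted <- TRUE
    }
    g <- block$good_lake[1L] + 1L
    c1 <- block$choice[i] + 1L
    p_good[i] <- plogis(b * (q[g] - q[3L - g]))
    p_choice[i] <- plogis(b * (q[c1] - q[3L - c1]))
    if (block$reward[i] > rmax) rmax <- block$reward[i]
    q[c1] <- q_update(q[c1], block$reward[i], params[["alpha"]])
  }
  cbind(block[, c("trial", "choice")],
        p_good = p_good, p_choice = p_choice)
}

#' @export
print.social_qlearn <- function(x, ...) {
  cat("Boosted Q-learning cohort fit:", nrow(x$fits), "participants",
      if (length(x$skipped)) paste0("(", length(x$skipped), " skipped)"),
      "\n")
  hs <- high_shares(x)
  cat(sprintf("high-precision shares: advice %.1f%%, observation %.1f%%, both %.1f%%\n",
              100 * hs$shares[["advice"]], 100 * hs$shares[["observation"]],
              100 * hs$shares[["both"]]))
  invisible(x)
}

#' Summary of a fitted cohort
#'
#' Quartile table of the six parameter estimates across participants (the
#' customary way these bounded, often bimodal estimates are reported), the
#' four-group partition by post-cue precision class, and the high-precision
#' shares.
#'
#' @param object A `"social_qlearn"` fit.
#' @param ... Unused.
#' @export
summary.social_qlearn <- function(object, ...) {
  est <- coef(object)
  qtab <- apply(est, 2, function(v) {
    c(min = min(v), q1 = unname(quantile(v, 0.25)), median = median(v),
      mean = mean(v), q3 = unname(quantile(v, 0.75)), max = max(v))
  })
  out <- list(n = nrow(object$fits), param_quartiles = qtab,
              high = high_shares(object),
              mean_nll = mean(object$fits$nll),
              n_unconverged = sum(!object$fits$converged),
              skipped = length(object$skipped))
  class(out) <- "summary.social_qlearn"
  out
}

#' @export
print.summary.social_qlearn <- function(x, ...) {
  cat("Boosted Q-learning cohort fit —", x$n, "participants\n\n")
  cat("Parameter estimates across participants:\n")
  print(round(x$param_quartiles, 3))
  cat("\nFour-group partition (post-cue precision class):\n")
  print(x$high$groups)
  cat(sprintf("\nhigh shares: advice %.3f, observation %.3f, both %.3f\n",
              x$high$shares[["advice"]], x$high$shares[["observation"]],
              x$high$shares[["both"]]))
  cat(sprintf("mean NLL %.2f nats; %d unconverged; %d skipped\n",
              x$mean_nll, x$n_unconverged, x$skipped))
  invisible(x)
}

#' @export
coef.social_qlearn <- function(object, ...) {
  f <- object$fits
  m <- as.matrix(f[, c("alpha_hat", "beta_hat", "qboost_adv_hat",
                       "qboost_obs_hat", "bboost_adv_hat",
                       "bboost_obs_hat")])
  colnames(m) <- c("alpha", "beta", "qboost_advice", "qboost_observation",
                   "bboost_advice", "bboost_observation")
  rownames(m) <- as.character(f$participant_id)
  m
}

#' @export
logLik.social_qlearn <- function(object, ...) {
  ll <- -sum(object$fits$nll)
  attr(ll, "df") <- 6L * nrow(object$fits)
  attr(ll, "nobs") <- sum(vapply(object$results,
                                 function(r) r$n_trials_used, integer(1)))
  class(ll) <- "logLik"
  ll
}

#' Fitted per-trial choice probabilities
#'
#' Recomputes, for every retained trial, the model's probability of the
#' choice the participant actually made (`p_choice`) and of the good lake
#' (`p_good`) under that participant's estimates, teacher-forced along the
#' observed sequence.
#'
#' @param object A `"social_qlearn"` fit.
#' @param newdata Optional trials data frame to score instead of the fitted
#'   data (participants must appear in the fit).
#' @param ... Unused.
#' @return A data frame: `participant_id`, `condition`, `trial`, `choice`,
#'   `p_good`, `p_choice`.
#' @export
predict.social_qlearn <- function(object, newdata = NULL, ...) {
  data <- newdata %||% object$data
  est <- coef(object)
  out <- list()
  for (id in rownames(est)) {
    pt <- data[data$participant_id == id, , drop = FALSE]
    if (!nrow(pt)) next
    p <- do.call(agent_params, as.list(est[id, ]))
    for (b in split_blocks(pt)) {
      tr <- block_trajectory(b, p, object$config)
      out[[length(out) + 1L]] <-
        cbind(participant_id = id, condition = b$condition[1L], tr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
#' @describeIn predict.social_qlearn Response residuals `choice_good -
#'   p_good`, where `choice_good` indicates choosing the good lake.
residuals.social_qlearn <- function(object, ...) {
  pr <- predict(object)
  good <- object$data$good_lake[match(
    paste(pr$participant_id, pr$condition, pr$trial),
    paste(object$data$participant_id, object$data$condition,
          object$data$trial))]
  as.numeric(pr$choice == good) - pr$p_good
}

#' Simulate new sessions from fitted parameters
#'
#' Each simulation replays every fitted participant through a fresh session
#' (new lakes and rewards) under their estimated parameters — a posterior
#' predictive check of the fitted cohort.
#'
#' @param object A `"social_qlearn"` fit.
#' @param nsim Number of replicate cohorts.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A trials data frame with a `sim` column.
#' @export
simulate.social_qlearn <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  est <- coef(object)
  out <- list()
  for (s in seq_len(nsim)) {
    for (k in seq_len(nrow(est))) {
      p <- do.call(agent_params, as.list(est[k, ]))
      ses <- simulate_session(object$config, p,
                              seed = mix_seed(seed, c(s, k)))
      ses$participant_id <- rownames(est)[k]
      ses$sim <- s
      out[[length(out) + 1L]] <- ses
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Learning curves of a fitted cohort
#'
#' Plots the observed proportion of good-lake choices per trial, one line per
#' condition, with the social-cue point marked.
#'
#' @param x A `"social_qlearn"` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.social_qlearn <- function(x, ...) {
  d <- x$data
  curves <- tapply(as.numeric(d$choice == d$good_lake),
                   list(d$trial, d$condition), mean)
  matplot(as.integer(rownames(curves)), curves, type = "b", pch = 1:3,
          lty = 1, col = c("black", "tomato", "steelblue"),
          xlab = "trial", ylab = "P(choose good lake)", ylim = c(0, 1), ...)
  abline(v = x$config$cue_after_trial + 0.5, lty = 3)
  legend("bottomright", colnames(curves), pch = 1:3,
         col = c("black", "tomato", "steelblue"), bty = "n")
  invisible(curves)
}
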