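#' Task configuration for the two-armed fishing bandit
#'
#' Describes the generative environment of the task: two lakes with Gaussian
#' yields, a fixed number of trials per block, and a single social cue that
#' appears after the feedback of trial \code{cue_after_trial} in the two
#' social conditions. Defaults reproduce the published design: good-lake mean
#' 5.5 fish, bad-lake mean 4 fish, common SD 1.7, 15 trials per block, cue
#' after trial 4.
#'
#' @param mean_good Expected yield of the good lake (fish per trial).
#' @param mean_bad Expected yield of the bad lake; must be below `mean_good`.
#' @param reward_sd Yield standard deviation (fish), shared by both lakes.
#' @param n_trials Trials per block.
#' @param cue_after_trial 1-based trial index after whose feedback the social
#'   cue is shown; the boost therefore acts before the choice of
#'   `cue_after_trial + 1`.
#' @param q_init Initial Q-value assigned to both lakes. Defaults to the
#'   midpoint of the two lake means, which avoids a first-trial novelty
#'   asymmetry while staying on the reward scale.
#' @param q_max_mode Rule for the value-boost ceiling: `"observed_max"` uses
#'   the largest reward the agent has received so far in the current block,
#'   floored at `q_init` — the highest value the learner could currently
#'   represent, since Q-values are convex combinations of `q_init` and
#'   received rewards; a full boost therefore always lifts the cued lake
#'   weakly above both running values. `"fixed"` uses `q_max_fixed`.
#' @param q_max_fixed Ceiling used when `q_max_mode = "fixed"`.
#' @param round_rewards Round simulated yields to whole fish for display;
#'   the default keeps them continuous, as only the normal distributions are
#'   part of the design.
#' @return An object of class `"task_config"`.
#' @export
task_config <- function(mean_good = 5.5, mean_bad = 4, reward_sd = 1.7,
                        n_trials = 15, cue_after_trial = 4,
                        q_init = (mean_good + mean_bad) / 2,
                        q_max_mode = c("observed_max", "fixed"),
                        q_max_fixed = mean_good + reward_sd,
                        round_rewards = FALSE) {
  q_max_mode <- match.arg(q_max_mode)
  stopifnot(is.numeric(mean_good), is.numeric(mean_bad),
            mean_good > mean_bad, reward_sd > 0,
            n_trials >= 2, cue_after_trial >= 1,
            cue_after_trial < n_trials)
  structure(list(mean_good = mean_good, mean_bad = mean_bad,
                 reward_sd = reward_sd, n_trials = as.integer(n_trials),
                 cue_after_trial = as.integer(cue_after_trial),
                 q_init = q_init, q_max_mode = q_max_mode,
                 q_max_fixed = q_max_fixed,
                 round_rewards = isTRUE(round_rewards)),
            class = "task_config")
}

#' Agent parameters for the boosted Q-learning model
#'
#' The six free parameters of the model: learning rate `alpha`, softmax
#' precision `beta`, and the one-time social boosts — `qboost_*` lifts the
#' cued lake's Q-value toward the ceiling (1 = all the way), `bboost_*`
#' replaces the precision for all remaining trials of the block. Box bounds
#' follow the fitting bounds used throughout the package (see
#' [param_bounds()]).
#'
#' @param alpha Learning rate in \[0.05, 0.95\].
#' @param beta Softmax precision (inverse temperature) in \[0.1, 50\].
#' @param qboost_advice,qboost_observation Value-boost weights in \[0, 1\].
#' @param bboost_advice,bboost_observation Post-cue precisions in \[0.1, 50\].
#' @return An object of class `"agent_params"` (a named numeric vector).
#' @export
agent_params <- function(alpha = 0.5, beta = 8.6,
                         qboost_advice = 1, qboost_observation = 1,
                         bboost_advice = beta, bboost_observation = beta) {
  p <- setNames(as.numeric(c(alpha, beta, qboost_advice,
                             qboost_observation, bboost_advice,
                             bboost_observation)),
                c("alpha", "beta", "qboost_advice", "qboost_observation",
                  "bboost_advice", "bboost_observation"))
  b <- param_bounds()
  bad <- p < b$lower - 1e-12 | p > b$upper + 1e-12
  if (any(bad)) {
    stop("agent parameter(s) outside bounds: ",
         paste(names(p)[bad], collapse = ", "))
  }
  structure(p, class = "agent_params")
}

#' Box bounds of the six model parameters
#'
#' The closed intervals within which parameters live and estimates are
#' constrained: alpha \[0.05, 0.95\], beta \[0.1, 50\], value boosts \[0, 1\],
#' precision boosts \[0.1, 50\].
#'
#' @return A list with named numeric vectors `lower` and `upper`.
#' @export
param_bounds <- function() {
  nm <- c("alpha", "beta", "qboost_advice", "qboost_observation",
          "bboost_advice", "bboost_observation")
  list(lower = setNames(c(0.05, 0.1, 0, 0, 0.1, 0.1), nm),
       upper = setNames(c(0.95, 50, 1, 1, 50, 50), nm))
}

boost_for <- function(params, condition) {
  switch(condition,
         advice = c(params[["qboost_advice"]], params[["bboost_advice"]]),
         observation = c(params[["qboost_observation"]],
                         params[["bboost_observation"]]),
         control = c(NA_real_, NA_real_))
}

#' Softmax choice probability for a two-option value comparison
#'
#' Probability of choosing lake A given the two Q-values and the precision
#' parameter. Computed through the log-odds `beta * (q_a - q_b)` so it is
#' numerically stable for any finite inputs; at `beta = 0` choice is uniform.
#'
#' @param q_a,q_b Q-values of lakes A and B.
#' @param beta Softmax precision, `>= 0`.
#' @return `P(choose A)`, strictly inside (0, 1) for finite arguments.
#' @examples
#' softmax_choice_prob(5.5, 4, 1) # ~0.8176
#' @export
softmax_choice_prob <- function(q_a, q_b, beta) {
  if (!all(is.finite(q_a), is.finite(q_b), is.finite(beta))) {
    stop("softmax_choice_prob: inputs must be finite")
  }
  if (any(beta < 0)) stop("softmax_choice_prob: beta must be >= 0")
  plogis(beta * (q_a - q_b))
}

#' Delta-rule Q-value update
#'
#' Moves the chosen option's value a fraction `alpha` of the way toward the
#' realised reward: `q + alpha * (reward - q)`. Only the chosen lake is ever
#' updated.
#'
#' @param q_old Current Q-value.
#' @param reward Realised reward (fish).
#' @param alpha Learning rate in \[0, 1\].
#' @return The updated Q-value.
#' @export
q_update <- function(q_old, reward, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("q_update: alpha must be in [0, 1]")
  q_old + alpha * (reward - q_old)
}

#' Apply the one-time social boost to an agent state
#'
#' Implements both social-information effects: the cued lake's Q-value is
#' moved toward the ceiling as a convex combination
#' `(1 - qboost) * Q + qboost * q_max` (so `qboost = 1` sets it exactly to
#' the ceiling), and the softmax precision is replaced by `bboost` for the
#' rest of the block. Both changes happen exactly once, after the feedback of
#' the cue trial and before the next choice; control blocks are never
#' boosted.
#'
#' @param state List with elements `q` (numeric length-2, lakes 0 and 1) and
#'   `beta`.
#' @param cue_target Lake indicated by the cue (0 or 1).
#' @param qboost Value-boost weight in \[0, 1\].
#' @param bboost Replacement precision.
#' @param q_max Boost ceiling.
#' @return The boosted state (same structure).
#' @export
apply_social_boost <- function(state, cue_target, qboost, bboost, q_max) {
  stopifnot(cue_target %in% c(0, 1), qboost >= 0, qboost <= 1,
            is.finite(q_max), bboost >= 0)
  i <- cue_target + 1L
  state$q[i] <- (1 - qboost) * state$q[i] + qboost * q_max
  state$beta <- bboost
  state
}
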