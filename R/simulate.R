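#' Simulate one block of the fishing task
#'
#' Generates an agent's choices and rewards for a single block. With a seed
#' the block is bit-reproducible: the per-lake reward streams (one potential
#' yield per lake per trial) and the choice uniforms are drawn up front from
#' that seed, so two agents sharing a seed face identical lakes regardless of
#' which lake they sample. In the social conditions the one-time boost is
#' applied after the feedback of trial `config$cue_after_trial`; in control
#' the boost machinery is never touched.
#'
#' @param config A [task_config()].
#' @param params An [agent_params()] vector (or named numeric with the same
#'   fields).
#' @param condition `"control"`, `"observation"` or `"advice"`.
#' @param good_lake Identifier (0/1) of the higher-mean lake; drawn at random
#'   when `NULL`.
#' @param seed Optional integer seed for this block.
#' @return A data frame with one row per trial: `trial`, `choice`, `reward`,
#'   `q_a`, `q_b` (values entering the trial), plus constant columns
#'   `condition`, `good_lake`, `cue_target` (NA in control) and
#'   `cue_after_trial`.
#' @export
simulate_block <- function(config, params, condition, good_lake = NULL,
                           seed = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  if (is.null(good_lake)) good_lake <- sample(0:1, 1L)
  stopifnot(good_lake %in% c(0, 1))

  # potential yields for both lakes on every trial, then choice uniforms
  means <- c(config$mean_bad, config$mean_bad)
  means[good_lake + 1L] <- config$mean_good
  yields <- cbind(rnorm(n, means[1L], config$reward_sd),
                  rnorm(n, means[2L], config$reward_sd))
  if (config$round_rewards) yields <- round(yields)
  u <- runif(n)

  social <- condition != "control"
  cue_target <- if (social) good_lake else NA_integer_
  qb <- boost_for(params, condition)

  q <- c(config$q_init, config$q_init)
  b <- params[["beta"]]
  boosted <- FALSE
  rmax <- -Inf
  choice <- integer(n)
  reward <- numeric(n)
  q_a <- q_b <- numeric(n)
  for (t in seq_len(n)) {
    if (social && !boosted && t > config$cue_after_trial) {
      qmax <- if (config$q_max_mode == "observed_max") {
        max(rmax, config$q_init)
      } else config$q_max_fixed
      st <- apply_social_boost(list(q = q, beta = b), cue_target,
                               qb[1L], qb[2L], qmax)
      q <- st$q
      b <- st$beta
      boosted <- TRUE
    }
    q_a[t] <- q[1L]
    q_b[t] <- q[2L]
    p1 <- plogis(b * (q[2L] - q[1L]))
    choice[t] <- as.integer(u[t] < p1)
    reward[t] <- yields[t, choice[t] + 1L]
    if (reward[t] > rmax) rmax <- reward[t]
    q[choice[t] + 1L] <- q_update(q[choice[t] + 1L], reward[t],
                                  params[["alpha"]])
  }
  data.frame(trial = seq_len(n), choice = choice, reward = reward,
             q_a = q_a, q_b = q_b, condition = condition,
             good_lake = good_lake, cue_target = cue_target,
             cue_after_trial = config$cue_after_trial,
             stringsAsFactors = FALSE)
}

#' Simulate a full three-block session
#'
#' One session is three blocks — control, observation and advice in the given
#' order — each with a fresh pair of lakes. Each block draws its own sub-seed
#' deterministically from the session seed and the block's position, so the
#' lakes and reward streams encountered at position k do not depend on which
#' condition is played there (counterbalancing changes only the agent's
#' policy, not the environment).
#'
#' @param config A [task_config()].
#' @param params An [agent_params()] vector.
#' @param block_order Character permutation of
#'   `c("control", "observation", "advice")`.
#' @param seed Session seed.
#' @return A data frame of 3 x `n_trials` rows, the blocks stacked in play
#'   order with a `block_order` column (1-3).
#' @export
simulate_session <- function(config, params,
                             block_order = CONDITIONS, seed = NULL) {
  if (length(block_order) != 3L || !setequal(block_order, CONDITIONS)) {
    stop("block_order must be a permutation of control/observation/advice")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  out <- vector("list", 3L)
  for (k in 1:3) {
    blk <- simulate_block(config, params, block_order[k],
                          seed = mix_seed(seed, k))
    blk$block_order <- k
    out[[k]] <- blk
  }
  do.call(rbind, out)
}
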