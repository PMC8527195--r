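# Independent brute-force re-implementation of the block likelihood:
# a naive trial-by-trial loop using the explicit exp-normalize softmax,
# deliberately sharing no code with the package's likelihood path.
naive_block_nll <- function(block, params, config) {
  block <- block[order(block$trial), , drop = FALSE]
  cond <- block$condition[1]
  social <- cond != "control"
  q <- c(config$q_init, config$q_init)
  beta <- params[["beta"]]
  boosted <- FALSE
  seen <- numeric(0)
  nll <- 0
  for (i in seq_len(nrow(block))) {
    if (social && !boosted && block$trial[i] > config$cue_after_trial) {
      qmax <- if (config$q_max_mode == "observed_max") {
        max(seen, config$q_init)
      } else config$q_max_fixed
      qb <- params[[paste0("qboost_", cond)]]
      bb <- params[[paste0("bboost_", cond)]]
      tgt <- block$cue_target[1] + 1
      q[tgt] <- (1 - qb) * q[tgt] + qb * qmax
      beta <- bb
      boosted <- TRUE
    }
    w <- exp(beta * (q - max(q)))
    p <- w / sum(w)
    nll <- nll - log(p[block$choice[i] + 1])
    seen <- c(seen, block$reward[i])
    k <- block$choice[i] + 1
    q[k] <- q[k] + params[["alpha"]] * (block$reward[i] - q[k])
  }
  nll
}

# hand-built block from explicit vectors
make_block <- function(choice, reward, condition = "control",
                       good_lake = 1, trial = seq_along(choice),
                       cue_target = if (condition == "control") NA
                                    else good_lake) {
  data.frame(trial = trial, choice = choice, reward = reward,
             condition = condition, good_lake = good_lake,
             cue_target = cue_target, cue_after_trial = 4,
             stringsAsFactors = FALSE)
}

random_params <- function() {
  b <- param_bounds()
  v <- runif(6, b$lower, b$upper)
  agent_params(v[1], v[2], v[3], v[4], v[5], v[6])
}
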