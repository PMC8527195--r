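#' Negative log-likelihood of one block of observed choices
#'
#' Teacher-forced likelihood: Q-values are propagated along the
#' participant's actual choice and reward sequence, and each observed choice
#' contributes `-log P(choice | Q, beta)` under the softmax rule. In social
#' blocks the one-time value and precision boosts are inserted at the cue
#' point, using the boost parameters matching the block's condition; control
#' blocks depend only on `alpha` and `beta`. Trials removed by the response
#' time filter may be absent — the original trial indices decide where the
#' boost falls.
#'
#' @param block A block data frame (as produced by [simulate_block()] or one
#'   participant-condition slice of a trials table) with columns `trial`,
#'   `choice`, `reward`, `condition`, and `cue_target` for social blocks.
#' @param params An [agent_params()] vector.
#' @param config A [task_config()].
#' @return The summed negative log-likelihood in nats (`>= 0`).
#' @export
block_nll <- function(block, params, config = task_config()) {
  if (nrow(block) == 0L) stop("block_nll: empty block")
  condition <- match.arg(block$condition[1L], CONDITIONS)
  social <- condition != "control"
  cue_target <- if (social) as.integer(block$cue_target[1L]) else 0L
  if (social && (is.na(cue_target) || !cue_target %in% c(0L, 1L))) {
    stop("block_nll: social block without a valid cue_target")
  }
  qb <- boost_for(params, condition)
  block_nll_cpp(as.integer(block$trial), as.integer(block$choice),
                as.numeric(block$reward),
                social, cue_target, config$cue_after_trial,
                params[["alpha"]], params[["beta"]],
                if (social) qb[1L] else 0, if (social) qb[2L] else 0,
                config$q_init, config$q_max_mode == "observed_max",
                config$q_max_fixed)
}

#' Session negative log-likelihood (all blocks of one participant)
#'
#' @param blocks A list of block data frames (typically one per condition).
#' @inheritParams block_nll
#' @return Summed negative log-likelihood across blocks (nats).
#' @export
session_nll <- function(blocks, params, config = task_config()) {
  sum(vapply(blocks, block_nll, numeric(1), params = params,
             config = config))
}
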