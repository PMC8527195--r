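#' Specification of a simulation sweep
#'
#' A grid over one of the social-boost knobs — the value boost (`qboost`),
#' the post-cue precision (`bboost`), or the population `mixture_ratio` of
#' ceiling-precision agents — simulated at `n_agents` blocks per grid value.
#'
#' @param parameter `"qboost"`, `"bboost"` or `"mixture_ratio"`.
#' @param grid Numeric grid of values (boosts within their bounds; ratios in
#'   \[0, 1\]).
#' @param n_agents Simulated agents per grid value.
#' @param base_params [agent_params()] shared by all agents; the swept
#'   parameter overrides the matching field for the chosen condition. The
#'   default uses a learning rate of 0.2, at which the model displays both
#'   signature effects cleanly — the value boost decays within the block
#'   while ceiling precision sustains near-perfect exploitation (faster
#'   learning makes greedy agents race their jittery value estimates and
#'   erodes ceiling performance).
#' @param condition Social condition to simulate (`"advice"` by default).
#' @param seed Integer seed.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(parameter = c("qboost", "bboost", "mixture_ratio"),
                       grid, n_agents = 2000,
                       base_params = agent_params(alpha = 0.2),
                       condition = "advice", seed = 1L) {
  parameter <- match.arg(parameter)
  stopifnot(length(grid) >= 1, n_agents >= 1)
  if (parameter == "mixture_ratio" && any(grid < 0 | grid > 1)) {
    stop("mixture ratios must lie in [0, 1]")
  }
  condition <- match.arg(condition, CONDITIONS)
  structure(list(parameter = parameter, grid = grid,
                 n_agents = as.integer(n_agents),
                 base_params = base_params, condition = condition,
                 seed = as.integer(seed)), class = "sweep_spec")
}

set_boost <- function(params, condition, qboost = NULL, bboost = NULL) {
  p <- unclass(params)
  suff <- if (condition == "advice") "advice" else "observation"
  if (!is.null(qboost)) p[paste0("qboost_", suff)] <- qboost
  if (!is.null(bboost)) p[paste0("bboost_", suff)] <- bboost
  do.call(agent_params, as.list(p))
}

curve_of <- function(blocks) {
  g <- vapply(blocks, good_indicator, integer(nrow(blocks[[1]])))
  rowMeans(g)
}

#' Run a boost-parameter or mixture sweep
#'
#' For each grid value, simulates `n_agents` independent blocks of the swept
#' condition and aggregates the proportion choosing the good lake on every
#' trial — the learning curves behind the immediate (value boost) and
#' long-term (precision boost) effects of social information. Only the swept
#' condition's block is simulated per agent, since the curve depends on
#' nothing else. Deterministic given the spec seed; agents at the same index
#' share lakes and reward streams across grid values, so curves differ only
#' through the swept parameter.
#'
#' @param spec A [sweep_spec()].
#' @param config A [task_config()].
#' @param params_high,params_low For `mixture_ratio` sweeps, the two
#'   subpopulations' [agent_params()] (defaults: base parameters with
#'   post-cue precision at ceiling 50 vs at the baseline `beta`, both with
#'   full value adoption).
#' @return A data frame of learning curves: `grid_value`, `trial`, `p_good`,
#'   `n_agents`.
#' @export
run_sweep <- function(spec, config = task_config(),
                      params_high = NULL, params_low = NULL) {
  out <- list()
  for (v in spec$grid) {
    if (spec$parameter == "mixture_ratio") {
      ph <- params_high %||% set_boost(spec$base_params, spec$condition,
                                       qboost = 1, bboost = 50)
      pl <- params_low %||% set_boost(spec$base_params, spec$condition,
                                      qboost = 1,
                                      bboost = spec$base_params[["beta"]])
      cur <- run_mixture(v, spec$n_agents, ph, pl, config, spec$seed,
                         condition = spec$condition)
      cur$grid_value <- v
      out[[length(out) + 1L]] <- cur[, c("grid_value", "trial", "p_good",
                                         "n_agents")]
    } else {
      params <- if (spec$parameter == "qboost") {
        set_boost(spec$base_params, spec$condition, qboost = v)
      } else {
        set_boost(spec$base_params, spec$condition, bboost = v)
      }
      blocks <- lapply(seq_len(spec$n_agents), function(i) {
        simulate_block(config, params, spec$condition,
                       seed = mix_seed(spec$seed, i))
      })
      out[[length(out) + 1L]] <- data.frame(
        grid_value = v, trial = seq_len(config$n_trials),
        p_good = curve_of(blocks), n_agents = spec$n_agents)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a mixed population of exploiters and explorers
#'
#' Each agent is independently an exploiter (ceiling post-cue precision,
#' `params_high`) with probability `ratio_high`, otherwise an explorer
#' (`params_low`); the aggregated good-lake learning curve is returned with
#' the realized exploiter count. Agent i's lakes and rewards are seeded by
#' index, so two mixtures with the same seed differ only in agent types.
#'
#' @param ratio_high Probability of the high-precision type, in \[0, 1\].
#' @param n_agents Number of simulated agents.
#' @param params_high,params_low [agent_params()] of the two types.
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @param condition Social condition simulated.
#' @return A data frame: `trial`, `p_good`, `n_agents`, `ratio_high`,
#'   `n_high`.
#' @export
run_mixture <- function(ratio_high, n_agents, params_high, params_low,
                        config = task_config(), seed = 1L,
                        condition = "advice") {
  stopifnot(ratio_high >= 0, ratio_high <= 1)
  set.seed(mix_seed(seed, 0L))
  is_high <- runif(n_agents) < ratio_high
  blocks <- lapply(seq_len(n_agents), function(i) {
    simulate_block(config, if (is_high[i]) params_high else params_low,
                   condition, seed = mix_seed(seed, i))
  })
  data.frame(trial = seq_len(config$n_trials), p_good = curve_of(blocks),
             n_agents = n_agents, ratio_high = ratio_high,
             n_high = sum(is_high))
}
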