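cfg <- task_config()

test_that("sampled ceiling shares hit the configured probabilities jointly", {
  spec <- cohort_spec(seed = 1)
  set.seed(1)
  ag <- replicate(2000, sample_agent(spec), simplify = FALSE)
  ha <- vapply(ag, `[[`, logical(1), "high_advice")
  ho <- vapply(ag, `[[`, logical(1), "high_observation")
  se <- function(p) sqrt(p * (1 - p) / 2000)
  expect_lt(abs(mean(ha) - 0.39), 3 * se(0.39))
  expect_lt(abs(mean(ho) - 0.34), 3 * se(0.34))
  expect_lt(abs(mean(ha & ho) - 0.18), 3 * se(0.18))
  # all sampled parameters inside the box bounds
  b <- param_bounds()
  pm <- t(vapply(ag, function(a) unclass(a$params), numeric(6)))
  expect_true(all(pm >= matrix(b$lower, 2000, 6, byrow = TRUE) - 1e-9))
  expect_true(all(pm <= matrix(b$upper, 2000, 6, byrow = TRUE) + 1e-9))
})

test_that("zero paranoia slopes decouple parameters from paranoia", {
  spec <- cohort_spec(paranoia_qboost_slope = 0, paranoia_phigh_slope = 0,
                      seed = 2)
  set.seed(2)
  ag <- replicate(3000, sample_agent(spec), simplify = FALSE)
  par <- vapply(ag, `[[`, numeric(1), "paranoia")
  qb <- vapply(ag, function(a) a$params[["qboost_advice"]], numeric(1))
  ha <- vapply(ag, `[[`, logical(1), "high_advice")
  lo <- par <= quantile(par, 1 / 3)
  hi <- par >= quantile(par, 2 / 3)
  # tertile contrasts compatible with zero difference (3 SEs)
  d_qb <- mean(qb[hi]) - mean(qb[lo])
  se_qb <- sqrt(var(qb[hi]) / sum(hi) + var(qb[lo]) / sum(lo))
  expect_lt(abs(d_qb), 3 * se_qb)
  d_ha <- mean(ha[hi]) - mean(ha[lo])
  se_ha <- sqrt(0.25 / sum(hi) + 0.25 / sum(lo))
  expect_lt(abs(d_ha), 3 * se_ha)
})

test_that("negative paranoia slopes lower immediate advice following", {
  spec <- cohort_spec(n_participants = 1500, seed = 6)
  gen <- generate_cohort(spec, cfg)
  adv <- gen$trials[gen$trials$condition == "advice" &
                      gen$trials$trial == 5, ]
  follow <- as.numeric(adv$choice == adv$good_lake)
  lo <- adv$paranoia <= quantile(gen$truth$paranoia, 1 / 3)
  hi <- adv$paranoia >= quantile(gen$truth$paranoia, 2 / 3)
  expect_gt(mean(follow[lo]), mean(follow[hi]))
})

test_that("cohort generation is reproducible, counterbalanced and consistent", {
  spec <- cohort_spec(n_participants = 6, seed = 9)
  g1 <- generate_cohort(spec, cfg)
  g2 <- generate_cohort(spec, cfg)
  expect_identical(g1, g2)
  # n = 6 -> each block order used exactly once
  expect_equal(sort(unique(g1$truth$block_order)),
               sort(g1$truth$block_order))
  expect_equal(length(unique(g1$truth$block_order)), 6L)
  # trial and truth tables agree on participants and conditions
  expect_setequal(unique(g1$trials$participant_id),
                  g1$truth$participant_id)
  expect_equal(nrow(g1$trials), 6L * 45L)
  for (id in g1$truth$participant_id) {
    pt <- g1$trials[g1$trials$participant_id == id, ]
    expect_setequal(unique(pt$condition),
                    c("control", "observation", "advice"))
    ord <- g1$truth$block_order[g1$truth$participant_id == id]
    played <- pt$condition[order(pt$block_order, pt$trial)]
    expect_equal(paste(unique(played), collapse = ">"), ord)
  }
  # social blocks always cue the good lake; control blocks carry no cue
  soc <- g1$trials$condition != "control"
  expect_true(all(g1$trials$cue_target[soc] == g1$trials$good_lake[soc]))
  expect_true(all(is.na(g1$trials$cue_target[!soc])))
})

test_that("slow-trial contamination matches the requested rate", {
  spec <- cohort_spec(n_participants = 40, slow_trial_rate = 0.05,
                      seed = 33)
  gen <- generate_cohort(spec, cfg)
  n <- nrow(gen$trials)
  slow <- sum(gen$trials$rt_ms > 20000)
  expect_lt(abs(slow / n - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("small closed-loop recovery report is well-formed", {
  spec <- cohort_spec(n_participants = 12, seed = 41)
  rep <- recovery_experiment(spec, cfg, fit_control(n_starts = 3))
  expect_s3_class(rep, "recovery_report")
  expect_equal(nrow(rep$parameters), 6L)
  expect_equal(sum(rep$confusion_advice), 12L)
  expect_equal(dim(rep$shares), c(2L, 3L))
  expect_true(all(rep$shares >= 0 & rep$shares <= 1))
})

test_that("an all-explorer cohort has a bounded false-high rate", {
  # bound frozen from a calibration run of the generate->fit loop on
  # all-low cohorts: rate ~0.14, plus three binomial standard errors
  spec <- cohort_spec(n_participants = 120, p_high_advice = 0,
                      p_high_observation = 0, p_high_joint = 0, seed = 404)
  gen <- generate_cohort(spec, cfg)
  fit <- social_qlearn(gen$trials, cfg, fit_control(start_seed = 404))
  hs <- high_shares(fit)$shares
  expect_lt(hs[["advice"]], 0.22)
  expect_lt(hs[["observation"]], 0.22)
})
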