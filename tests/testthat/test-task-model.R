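test_that("softmax choice probability matches direct evaluation and its symmetries", {
  # direct evaluation of 1 / (1 + exp(-beta * (qa - qb)))
  expect_equal(softmax_choice_prob(5.5, 4.0, 1), 1 / (1 + exp(-1.5)),
               tolerance = 1e-12)
  expect_equal(softmax_choice_prob(5.5, 4.0, 1), 0.8176, tolerance = 1e-4)
  # equal values or zero precision -> uniform
  expect_equal(softmax_choice_prob(7.3, 7.3, 8), 0.5)
  expect_equal(softmax_choice_prob(5, 5, 0), 0.5)
  set.seed(1)
  for (i in 1:25) {
    qa <- runif(1, -10, 10); qb <- runif(1, -10, 10)
    beta <- runif(1, 0, 50); shift <- runif(1, -20, 20)
    p <- softmax_choice_prob(qa, qb, beta)
    # complements sum to one; invariant to adding a constant to both Qs
    expect_equal(p + softmax_choice_prob(qb, qa, beta), 1, tolerance = 1e-12)
    expect_equal(softmax_choice_prob(qa + shift, qb + shift, beta), p,
                 tolerance = 1e-9)
    expect_equal(softmax_choice_prob(qa, qb, 0), 0.5)
    # greedy limit
    if (abs(qa - qb) > 0.5) {
      expect_gt(softmax_choice_prob(qa, qb, 1e4) , if (qa > qb) 0.999 else -1)
      if (qa < qb) expect_lt(softmax_choice_prob(qa, qb, 1e4), 0.001)
    }
  }
  expect_error(softmax_choice_prob(NaN, 1, 2), "finite")
  expect_error(softmax_choice_prob(1, 2, -1), "beta")
})

test_that("delta-rule update moves toward the reward and stays bracketed", {
  expect_equal(q_update(4.75, 4.75, 0.3), 4.75) # zero prediction error
  expect_equal(q_update(3, 7, 1), 7)            # full update
  expect_equal(q_update(3, 7, 0.25), 4.0)       # hand evaluation
  expect_error(q_update(3, 7, 1.2), "alpha")
  set.seed(2)
  for (i in 1:50) {
    q <- runif(1, -5, 10); r <- runif(1, -5, 10); a <- runif(1)
    qn <- q_update(q, r, a)
    expect_gte(qn, min(q, r) - 1e-12)
    expect_lte(qn, max(q, r) + 1e-12)
  }
})

test_that("social boost is a convex combination toward the ceiling and replaces precision", {
  st <- list(q = c(4.1, 4.0), beta = 6)
  # identity when qboost = 0 and bboost = beta
  expect_equal(apply_social_boost(st, 0, 0, 6, 7.2), st)
  # full boost reaches the ceiling exactly
  expect_equal(apply_social_boost(st, 0, 1, 50, 7.2)$q, c(7.2, 4.0))
  # half boost: midpoint; untargeted lake untouched
  half <- apply_social_boost(list(q = c(4, 5), beta = 2), 0, 0.5, 30, 8)
  expect_equal(half$q, c(6, 5))
  expect_equal(half$beta, 30)
})

test_that("simulated rewards reproduce the generative lake moments", {
  cfg <- task_config()
  p <- agent_params(beta = 0.1) # near-random sampling of both lakes
  set.seed(42)
  blocks <- lapply(1:1500, function(i)
    simulate_block(cfg, p, "control", good_lake = 1, seed = i))
  d <- do.call(rbind, blocks)
  good <- d$reward[d$choice == 1]
  bad <- d$reward[d$choice == 0]
  se_mean <- cfg$reward_sd / sqrt(length(good))
  expect_lt(abs(mean(good) - cfg$mean_good), 3 * se_mean)
  expect_lt(abs(mean(bad) - cfg$mean_bad),
            3 * cfg$reward_sd / sqrt(length(bad)))
  # sd within 3 SEs (SE of the sd ~ sd / sqrt(2n))
  expect_lt(abs(sd(good) - cfg$reward_sd),
            3 * cfg$reward_sd / sqrt(2 * length(good)))
})

test_that("control blocks never touch the boost machinery", {
  cfg <- task_config()
  # identical blocks whatever the boost parameters are set to
  p1 <- agent_params(0.4, 5, 1, 1, 50, 50)
  p2 <- agent_params(0.4, 5, 0, 0, 0.1, 0.1)
  b1 <- simulate_block(cfg, p1, "control", good_lake = 0, seed = 9)
  b2 <- simulate_block(cfg, p2, "control", good_lake = 0, seed = 9)
  expect_identical(b1, b2)
})

test_that("a social block with null boosts matches control on the same rewards", {
  cfg <- task_config()
  p <- agent_params(0.5, 4, qboost_advice = 0, bboost_advice = 4)
  ctrl <- simulate_block(cfg, p, "control", good_lake = 1, seed = 31)
  soc <- simulate_block(cfg, p, "advice", good_lake = 1, seed = 31)
  expect_equal(soc$choice, ctrl$choice)
  expect_equal(soc$reward, ctrl$reward)
  expect_equal(soc[c("q_a", "q_b")], ctrl[c("q_a", "q_b")])
})

test_that("high precision plus full value boost converges on the good lake", {
  cfg <- task_config()
  # slow learner: the boosted value ordering persists through the block, so
  # ceiling precision pins the choice to the cued lake
  p <- agent_params(0.1, 8.6, qboost_advice = 1, bboost_advice = 50)
  set.seed(5)
  d <- do.call(rbind, lapply(1:400, function(i)
    simulate_block(cfg, p, "advice", seed = i)))
  late <- d[d$trial >= 6, ]
  expect_gt(mean(late$choice == late$good_lake), 0.99)
})

test_that("sessions have 45 trials, are seed-reproducible, and share reward streams across orders", {
  cfg <- task_config()
  p <- agent_params()
  s1 <- simulate_session(cfg, p, c("advice", "observation", "control"),
                         seed = 77)
  expect_equal(nrow(s1), 45L)
  expect_setequal(unique(s1$condition),
                  c("advice", "control", "observation"))
  expect_true(all(table(s1$condition) == 15L))
  s2 <- simulate_session(cfg, p, c("advice", "observation", "control"),
                         seed = 77)
  expect_identical(s1, s2)
  # per-block sub-seeding: the lakes met at position k do not depend on the
  # condition played there
  s3 <- simulate_session(cfg, p, c("control", "observation", "advice"),
                         seed = 77)
  expect_equal(s1$good_lake[s1$block_order == 2],
               s3$good_lake[s3$block_order == 2])
  expect_error(simulate_session(cfg, p, c("control", "control", "advice")),
               "permutation")
})
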