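cfg <- task_config()

test_that("response-time filter removes exactly the slow rows, preserving order", {
  tr <- make_block(choice = c(0, 1, 0), reward = c(5, 4, 6))
  tr$rt_ms <- c(1200, 25000, 3000)
  out <- filter_long_trials(tr)
  expect_equal(out$n_removed, 1L)
  expect_equal(out$kept$trial, c(1, 3))
  # identity when nothing is slow
  fast <- tr; fast$rt_ms <- c(100, 200, 19999)
  expect_identical(filter_long_trials(fast)$kept, fast)
  # missing RTs are kept
  nas <- tr; nas$rt_ms <- c(NA, 21000, NA)
  expect_equal(filter_long_trials(nas)$n_removed, 1L)
  expect_error(filter_long_trials(transform(tr, rt_ms = c(-1, 2, 3))),
               "negative")
})

test_that("immediate following reads the first post-cue trial", {
  g <- make_block(choice = c(0, 0, 0, 0, 1, 0), reward = rep(5, 6),
                  condition = "advice", good_lake = 1)
  expect_equal(immediate_follow(g, 4), 1L)
  b <- g; b$choice[5] <- 0
  expect_equal(immediate_follow(b, 4), 0L)
  # trial 5 filtered out -> missing, not zero
  expect_true(is.na(immediate_follow(g[g$trial != 5, ], 4)))
})

test_that("long-term performance averages good choices over trials 6-15", {
  ch <- c(rep(0, 5), rep(1, 10))
  blk <- make_block(choice = ch, reward = rep(5, 15), good_lake = 1)
  expect_equal(longterm_performance(blk, 4), 1.0)
  ch2 <- c(rep(0, 5), rep(1, 7), rep(0, 3))
  blk2 <- make_block(choice = ch2, reward = rep(5, 15), good_lake = 1)
  expect_equal(longterm_performance(blk2, 4), 0.7)
})

test_that("convergence is the first run of three consecutive good choices", {
  runs <- list(list(ch = c(1, 1, 1, 0, 1), want = 1),
               list(ch = c(0, 1, 1, 1, 0), want = 2),
               list(ch = c(1, 0, 1, 0, 1, 0, 1, 0), want = NA))
  for (r in runs) {
    blk <- make_block(choice = r$ch, reward = rep(5, length(r$ch)),
                      good_lake = 1)
    cv <- convergence_trial(blk, 3, n_trials = 15)
    if (is.na(r$want)) {
      expect_false(cv$converged)
      expect_equal(cv$trial, 16L) # censored
    } else {
      expect_true(cv$converged)
      expect_equal(cv$trial, r$want)
    }
  }
})

test_that("convergence by trial 13 implies positive long-term performance", {
  set.seed(4)
  for (i in 1:40) {
    blk <- make_block(choice = rbinom(15, 1, 0.6), reward = rnorm(15, 5),
                      good_lake = 1)
    cv <- convergence_trial(blk, 3, 15)
    if (cv$converged && cv$trial <= 13) {
      expect_gt(longterm_performance(blk, 4), 0)
    }
  }
})

test_that("U-value is normalized binary entropy of the choice mix", {
  expect_equal(u_value(rep(1, 15)), 0)
  expect_equal(u_value(rep(0, 9)), 0)
  expect_equal(u_value(rep(c(0, 1), 8)[1:16]), 1)
  p8 <- c(rep(1, 8), rep(0, 2))
  expect_equal(u_value(p8), -(0.8 * log2(0.8) + 0.2 * log2(0.2)),
               tolerance = 1e-12)
  expect_equal(u_value(p8), 0.7219, tolerance = 1e-4)
  # symmetry p <-> 1-p; maximum at 0.5
  expect_equal(u_value(c(rep(1, 3), rep(0, 7))),
               u_value(c(rep(1, 7), rep(0, 3))))
  expect_lt(u_value(c(rep(1, 6), rep(0, 4))), 1)
})

test_that("bonus pays 20p per 50 fish, floored and capped", {
  expect_equal(bonus_pence(50), 20)
  expect_equal(bonus_pence(49), 0)
  expect_equal(bonus_pence(10000), 180)
  expect_equal(bonus_pence(125), 40)
  expect_equal(bonus_pence(125, pro_rata = TRUE), 50)
  expect_error(bonus_pence(-1), "negative")
  # monotone non-decreasing
  fish <- seq(0, 600, by = 7)
  expect_true(all(diff(bonus_pence(fish)) >= 0))
})

test_that("cohort summaries have degenerate CIs for constants and are seeded", {
  spec <- cohort_spec(n_participants = 12, seed = 3)
  gen <- generate_cohort(spec, cfg)
  meas <- cohort_measures(gen$trials, cfg)
  expect_equal(nrow(meas), 36L)
  s1 <- summarize_cohort(meas, n_boot = 200, seed = 8)
  s2 <- summarize_cohort(meas, n_boot = 200, seed = 8)
  expect_identical(s1, s2)
  # constant column -> zero-width CI
  m0 <- meas
  m0$longterm_perf <- 0.6
  s0 <- summarize_cohort(m0, n_boot = 100, seed = 1)
  lt <- s0$means[s0$means$measure == "longterm_perf", ]
  expect_true(all(abs(lt$ci_hi - lt$ci_lo) < 1e-12))
})

test_that("the social long-term advantage separates from control in bootstrap CIs", {
  spec <- cohort_spec(n_participants = 1500, seed = 19)
  gen <- generate_cohort(spec, task_config())
  meas <- cohort_measures(gen$trials, task_config())
  s <- summarize_cohort(meas, n_boot = 500, seed = 19)
  m <- s$means[s$means$measure == "longterm_perf", ]
  adv <- m[m$condition == "advice", ]
  ctl <- m[m$condition == "control", ]
  expect_gt(adv$mean, ctl$mean)
  expect_gt(adv$ci_lo, ctl$ci_hi) # non-overlapping intervals
  d <- s$differences[s$differences$measure == "longterm_perf" &
                       s$differences$contrast == "control - advice", ]
  expect_lt(d$ci_hi, 0)
})
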