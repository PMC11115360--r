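test_that("estimates use the last sample by default and the mean as the variant", {
  expect_equal(estimate_from_samples(c(22, 26, 24), "last"), 24)
  expect_equal(estimate_from_samples(c(22, 26, 24), "mean"), 24)
  expect_equal(estimate_from_samples(c(22, 26, 27), "last"), 27)
  expect_equal(estimate_from_samples(5, "last"), estimate_from_samples(5, "mean"))
  expect_error(estimate_from_samples(numeric(0)), "no samples")
})

test_that("interval production interpolates symmetric fractional order statistics", {
  x <- c(10, 12, 14, 16, 18)
  expect_equal(ci_produce(x, 0.60), c(12, 16))  # 2nd and 4th of five
  expect_equal(ci_produce(x, 1.00), c(10, 18))  # full sample range
  expect_equal(ci_produce(x, 0.93), c(10.35, 17.65)) # hand-evaluated ranks
  expect_error(ci_produce(10, 0.6), "two samples")
  # bounds stay inside the sample range and widen with the coverage level
  set.seed(430)
  for (r in 1:50) {
    s <- rnorm(sample(3:12, 1), 24, 3)
    gammas <- c(0.3, 0.5, 0.7, 0.9, 1)
    cis <- vapply(gammas, function(g) ci_produce(s, g), c(0, 0))
    expect_true(all(cis[1, ] >= min(s) - 1e-12))
    expect_true(all(cis[2, ] <= max(s) + 1e-12))
    expect_true(all(diff(cis[2, ] - cis[1, ]) >= -1e-12))
  }
})

test_that("interval evaluation is the closed-interval sample proportion, optionally tempered", {
  x <- c(10, 12, 14, 16, 18)
  expect_equal(ci_evaluate(x, c(11, 17)), 0.6)
  expect_equal(ci_evaluate(x, c(0, 100)), 1)
  expect_equal(ci_evaluate(x, c(11, 17), prior = beta11()), (1 + 3) / (2 + 5))
  expect_error(ci_evaluate(numeric(0), c(0, 1)), "one sample")
})

test_that("interval evaluation of a known central region is unbiased for i.i.d. samples", {
  set.seed(431)
  spec <- dots_spec()
  iv <- 24 + qnorm(c(0.1, 0.9)) * 3
  tc <- trial_config(spec, dots_partition(), query = "ci_evaluate",
                     rule = stopping_rule("fixed_n", n_fixed = 5),
                     sampler = sampler_config("direct"), eval_interval = iv)
  st <- init_state(tc$sampler, "random", spec)
  ev <- replicate(4000, {
    r <- run_trial(tc, st, beta11())
    r$record$prob_judgment
  })
  se <- sd(ev) / sqrt(length(ev))
  expect_lt(abs(mean(ev) - 0.8), 3 * se)
})

test_that("response times are shifted Erlang sums of exponential waits", {
  expect_equal(rt_draw(0, 10, t0 = 0.3), 0.3)
  set.seed(432)
  draws <- replicate(2e4, rt_draw(5, 10, t0 = 0.2))
  se <- sqrt(5 / 100) / sqrt(2e4)
  expect_lt(abs(mean(draws) - 0.7), 3 * se)
  ks <- ks.test(draws - 0.2, pgamma, shape = 5, rate = 10)
  expect_gt(ks$p.value, 0.001)
  # one sample reduces to a plain exponential wait
  set.seed(433)
  one <- replicate(2e4, rt_draw(1, 10))
  expect_gt(ks.test(one, pexp, 10)$p.value, 0.001)
})

test_that("a fixed-N estimation trial reports the most recent sample and its Erlang clock", {
  set.seed(434)
  spec <- dots_spec()
  tc <- trial_config(spec, dots_partition(), query = "estimate",
                     rule = stopping_rule("fixed_n", n_fixed = 5),
                     sampler = sampler_config("mc3"), rate_lambda = 1e6)
  st <- init_state(tc$sampler, "random", spec)
  res <- run_trial(tc, st, beta11())
  expect_identical(res$record$n_samples, 5L)
  expect_equal(res$record$estimate, res$record$samples[5])
  # with a very fast sampling clock the response time collapses to t0
  expect_lt(res$record$rt, 1e-4)
})

test_that("choice trials beat chance and report complementary confidence", {
  set.seed(435)
  spec <- dots_spec(mean = 27)
  tc <- trial_config(spec, dots_partition(25), query = "choice",
                     rule = stopping_rule("max_minus_next", delta = 2),
                     sampler = sampler_config("mc3"), correct = 2L,
                     reinit = TRUE)
  bat <- rep(list(tc), 2000)
  df <- run_trials(bat, beta11())
  expect_gt(mean(df$correct), 0.75)
  expect_true(all(df$confidence > 0.5 & df$confidence <= 1))
  expect_true(all(df$rt >= 0))
  expect_identical(df$n_samples, as.integer(df$n_samples))
})

test_that("run_trials adapts the prior from the preceding trial's feedback", {
  set.seed(436)
  spec <- dots_spec(mean = 26.5)
  # a threshold-1 rule exposes the adapted prior: after correct feedback the
  # next trial can stop on pseudocounts alone (zero samples)
  tc <- trial_config(spec, dots_partition(25), query = "choice",
                     rule = stopping_rule("max_minus_next", delta = 1),
                     sampler = sampler_config("direct"), correct = 2L)
  df <- run_trials(rep(list(tc), 50), beta11(), adaptive = TRUE)
  expect_gt(sum(df$n_samples[-1] == 0), 30)
  expect_true(all(df$rt[df$n_samples == 0] == tc$t0))
  # without adaptation a decision always needs at least one sample
  df0 <- run_trials(rep(list(tc), 50), beta11(), adaptive = FALSE)
  expect_true(all(df0$n_samples >= 1))
})

test_that("under fixed N the response-time distribution is the t0-shifted Erlang", {
  set.seed(437)
  spec <- dots_spec()
  tc <- trial_config(spec, dots_partition(), query = "probability_judgment",
                     rule = stopping_rule("fixed_n", n_fixed = 5),
                     sampler = sampler_config("mc3"), rate_lambda = 10,
                     t0 = 0.2)
  df <- run_trials(rep(list(tc), 5000), beta11())
  expect_gt(ks.test(df$rt - 0.2, pgamma, shape = 5, rate = 10)$p.value, 0.001)
  # unimodal positive skew: mean above median
  expect_gt(mean(df$rt), median(df$rt))
})
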