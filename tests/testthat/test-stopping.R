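test_that("max-minus-next stops exactly when the pseudocount-inclusive lead reaches the threshold", {
  rule <- stopping_rule("max_minus_next", delta = 2)
  # totals (1+2, 1+0): lead 2 -> stop and choose the leader
  res <- should_stop(rule, beta11(), c(2, 0))
  expect_true(res$stop)
  expect_identical(res$chosen, 1L)
  # lead 1 -> keep sampling
  res <- should_stop(rule, beta11(), c(1, 0))
  expect_false(res$stop)
  expect_null(res$chosen)
  # a biased prior can satisfy the threshold before any sample is drawn
  res <- should_stop(stopping_rule("max_minus_next", delta = 1),
                     response_prior(c(2, 1)), c(0, 0))
  expect_true(res$stop)
  expect_identical(res$chosen, 1L)
})

test_that("fixed-N stopping fires at the sample budget with argmax choice", {
  rule <- stopping_rule("fixed_n", n_fixed = 5)
  expect_false(should_stop(rule, beta11(), c(2, 2))$stop)
  res <- should_stop(rule, beta11(), c(4, 1))
  expect_true(res$stop)
  expect_identical(res$chosen, 1L)
  # ties broken uniformly at random among the tied alternatives
  set.seed(420)
  tied <- replicate(400, should_stop(rule, response_prior(c(1, 1, 1)),
                                     c(2, 2, 1))$chosen)
  expect_setequal(unique(tied), c(1L, 2L))
  expect_gt(mean(tied == 1L), 0.4)
  expect_lt(mean(tied == 1L), 0.6)
})

test_that("at stopping the achieved lead is exactly the threshold when evidence arrives unit-wise", {
  set.seed(421)
  rule <- stopping_rule("max_minus_next", delta = 3)
  pr <- beta11()
  counts <- c(0, 0)
  repeat {
    res <- should_stop(rule, pr, counts)
    if (res$stop) break
    k <- sample(1:2, 1, prob = c(0.7, 0.3))
    counts[k] <- counts[k] + 1
  }
  totals <- pr$alphas + counts
  expect_identical(max(totals) - min(totals), 3)
})

test_that("the n_max cap forces a majority decision", {
  set.seed(422)
  spec <- dots_spec(mean = 25)           # mean on the boundary
  tc <- trial_config(spec, dots_partition(25), query = "choice",
                     rule = stopping_rule("max_minus_next", delta = 50,
                                          n_max = 40),
                     sampler = sampler_config("direct"))
  res <- run_trial(tc, init_state(tc$sampler, "random", spec), beta11())
  expect_identical(res$record$n_samples, 40L)
  expect_true(res$record$choice %in% 1:2)
})

test_that("mean stopped sample size matches a Markov-chain absorption oracle for i.i.d. evidence", {
  # oracle: expected absorption time of the +/-1 evidence-difference walk
  expected_n <- function(p, delta) {
    states <- (-delta + 1):(delta - 1)   # transient differences
    k <- length(states)
    A <- diag(k); b <- rep(1, k)
    for (i in seq_len(k)) {
      up <- states[i] + 1; dn <- states[i] - 1
      if (abs(up) < delta) A[i, match(up, states)] <- A[i, match(up, states)] - p
      if (abs(dn) < delta) A[i, match(dn, states)] <- A[i, match(dn, states)] - (1 - p)
    }
    solve(A, b)[match(0, states)]
  }
  set.seed(423)
  delta <- 3L
  for (p in c(0.6, 0.75)) {
    mu <- 25 + qnorm(p) * 3              # P(sample > 25) = p
    spec <- dots_spec(mean = mu)
    tc <- trial_config(spec, dots_partition(25), query = "choice",
                       rule = stopping_rule("max_minus_next", delta = delta),
                       sampler = sampler_config("direct"))
    pr <- response_prior(c(0, 0))        # unseeded accumulator
    ns <- replicate(3000, run_trial(tc, init_state(tc$sampler, "random", spec),
                                    pr)$record$n_samples)
    target <- expected_n(p, delta)
    expect_lt(abs(mean(ns) - target), 3 * sd(ns) / sqrt(length(ns)))
  }
  # more homogeneous evidence stops sooner
  expect_lt(expected_n(0.75, delta), expected_n(0.6, delta))
})

test_that("the dynamic-programming reference policy is a documented stub", {
  expect_error(optimal_stop_reference(), "not implemented")
})
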