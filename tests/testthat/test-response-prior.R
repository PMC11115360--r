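test_that("posterior-mean probability estimates reproduce the worked cases", {
  expect_equal(probability_estimate(beta11(), c(2, 0), 1), 0.75)
  expect_equal(probability_estimate(beta11(), c(51, 49), 1), 52 / 102)
  # all-zero prior reduces to relative frequency
  expect_equal(probability_estimate(response_prior(c(0, 0)), c(3, 2), 1), 0.6)
  # uniform Dirichlet over 7 alternatives with no samples: the prior mean
  expect_equal(probability_estimate(response_prior(rep(1, 7)),
                                    rep(0, 7), 3), 1 / 7)
  expect_error(probability_estimate(response_prior(c(0, 0)), c(0, 0), 1),
               "no information")
})

test_that("the prior bounds the reachable range of estimates and is monotone in counts", {
  pr <- response_prior(c(1, 1))
  n <- 5
  ests <- vapply(0:n, function(s) probability_estimate(pr, c(s, n - s), 1), 0)
  expect_true(all(diff(ests) > 0))
  expect_equal(min(ests), 1 / (n + 2))
  expect_equal(max(ests), (1 + n) / (n + 2))
  # adding evidence for the other alternative strictly lowers the estimate
  expect_lt(probability_estimate(pr, c(2, 3), 1),
            probability_estimate(pr, c(2, 2), 1))
})

test_that("feedback adaptation resets to a one-pseudocount advantage", {
  base <- beta11()
  expect_equal(adapt_from_feedback(base, 1)$alphas, c(2, 1))
  expect_equal(adapt_from_feedback(base, 2)$alphas, c(1, 2))
  expect_equal(adapt_from_feedback(base, NULL)$alphas, c(1, 1))
  # previously adapted priors reset rather than accumulate
  expect_equal(adapt_from_feedback(response_prior(c(2, 1)), 2)$alphas, c(1, 2))
  m4 <- adapt_from_feedback(response_prior(rep(1, 4)), 3)
  expect_equal(m4$alphas, c(1, 1, 2, 1))
})

test_that("confidence at stopping matches its closed form for random stopped states", {
  expect_equal(confidence_at_stop(beta11(), c(2, 0), 1), 0.75)
  expect_equal(confidence_at_stop(beta11(), c(51, 49), 1), 52 / 102)
  set.seed(410)
  for (r in 1:1000) {
    i <- sample(1:3, 1); j <- sample(1:3, 1)
    sa <- sample(0:30, 1); sb <- sample(0:30, 1)
    if (i + sa <= j + sb) next
    delta <- (i + sa) - (j + sb)
    n <- sa + sb
    pr <- response_prior(c(i, j))
    closed <- (i + j + n + delta) / (2 * (i + j + n))
    expect_equal(confidence_at_stop(pr, c(sa, sb), 1), closed,
                 tolerance = 1e-12)
    # the two alternatives' confidences are complementary
    expect_equal(confidence_at_stop(pr, c(sa, sb), 1) +
                   confidence_at_stop(pr, c(sa, sb), 2), 1,
                 tolerance = 1e-12)
  }
})

test_that("multialternative confidence agrees between its two algebraic forms", {
  expect_equal(confidence_multialt(c(5, 3, 2), delta = 2), 0.5)
  # uninformative limit: evidence (delta + k, k, k) tends to 1/3 as k grows
  expect_equal(confidence_multialt(c(2 + 1e6, 1e6, 1e6), delta = 2), 1 / 3,
               tolerance = 1e-5)
  expect_error(confidence_multialt(c(3, 3, 1), delta = 0), "positive")
  set.seed(411)
  for (r in 1:1000) {
    ev <- sort(sample(1:50, 3), decreasing = TRUE)
    if (ev[1] == ev[2]) next
    delta <- ev[1] - ev[2]
    conf <- confidence_multialt(ev, delta)
    diff <- (ev[1] - ev[2]) / sum(ev)
    expect_equal(conf, diff * ev[1] / delta, tolerance = 1e-12)
  }
})

test_that("the explicit-subadditivity bias formula covers its edge cases", {
  expect_equal(subadditivity_bias(1, 5, 1), 0)
  expect_equal(subadditivity_bias(2, 5, 1, exhaustive = TRUE), 0)
  expect_equal(subadditivity_bias(3, 5, 1), 2 / 7)
  # strictly increasing in the number of components when the prior is active
  b <- vapply(2:6, function(m) subadditivity_bias(m, 5, 1), 0)
  expect_true(all(diff(b) > 0))
  expect_equal(subadditivity_bias(4, 5, 0), 0)
})
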