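test_that("anchored initialization puts every chain on the comparison value", {
  cfg <- sampler_config("mc3")
  for (h in c(75.5, 25.5)) {
    st <- init_state(cfg, start = h, spec = dots_spec())
    expect_equal(st$chain_positions, rep(h, cfg$n_chains))
    expect_identical(st$trial_index, 0L)
  }
})

test_that("random initialization draws the cold chain from the posterior", {
  set.seed(401)
  cfg <- sampler_config("mc3")
  cold <- replicate(2000, init_state(cfg, "random", dots_spec())$chain_positions[1])
  ks <- ks.test(cold, pnorm, 24, 3)
  expect_gt(ks$p.value, 0.001)
})

test_that("long-run rwm and mc3 frequencies match an exhaustively known discrete target", {
  set.seed(402)
  spec <- grid5_spec()
  for (alg in c("rwm", "mc3")) {
    cfg <- sampler_config(alg)
    st <- init_state(cfg, "random", spec)
    s <- draw_samples(st, spec, cfg, 1e5)$samples
    # raw cell frequencies sit within a few mixing-adjusted standard errors
    freq <- tabulate(match(s, spec$grid_values), 5) / 1e5
    expect_lt(max(abs(freq - grid5_probs)), 0.02)
    # chi-square requires effective independence: thin past the mixing time
    thin <- s[seq(1, length(s), by = 25)]
    tab <- tabulate(match(thin, spec$grid_values), 5)
    expect_gt(chisq.test(tab, p = grid5_probs)$p.value, 0.001)
  }
})

test_that("swap steps conserve the multiset of chain positions", {
  set.seed(403)
  cfg <- sampler_config("mc3")
  spec <- dots_spec()
  st <- init_state(cfg, "random", spec)
  for (i in 1:50) {
    before <- sort(st$chain_positions)
    st2 <- swap_step(st, spec, cfg)
    expect_equal(sort(st2$chain_positions), before)
    st <- mh_step(st2, spec, cfg, chain = 1 + (i %% cfg$n_chains))
  }
})

test_that("autocorrelation separates the local samplers from direct sampling", {
  set.seed(404)
  spec <- dots_spec()
  lag1 <- function(cfg) {
    st <- init_state(cfg, "random", spec)
    s <- draw_samples(st, spec, cfg, 1e4)$samples
    stats::acf(s, lag.max = 1, plot = FALSE)$acf[2]
  }
  expect_gt(lag1(sampler_config("mc3", proposal_sd = 0.1)), 0.5)
  expect_lt(abs(lag1(sampler_config("direct"))), 0.05)
})

test_that("the mc3 marginal mean converges to the posterior mean", {
  set.seed(405)
  spec <- dots_spec()
  cfg <- sampler_config("mc3")
  st <- init_state(cfg, "random", spec)
  s <- draw_samples(st, spec, cfg, 1e5)$samples
  expect_lt(abs(mean(s) - 24), 0.2) # ~4 standard errors at IACT ~ 25
})

test_that("carryover links consecutive trials and counts them", {
  set.seed(406)
  spec <- dots_spec()
  cfg <- sampler_config("mc3")
  st <- init_state(cfg, "random", spec)
  last <- first <- numeric(1000)
  for (i in 1:1000) {
    d <- draw_samples(st, spec, cfg, 5)
    last[i] <- d$samples[5]
    if (i > 1) first[i] <- d$samples[1]
    st0 <- d$state
    st <- carryover(st0, spec)
    expect_identical(st$trial_index, st0$trial_index + 1L)
  }
  expect_gt(cor(last[-1000], first[-1]), 0.3)
})

test_that("an explicit anchor overrides carried-over positions", {
  set.seed(407)
  spec <- dots_spec()
  cfg <- sampler_config("mc3")
  st <- carryover(init_state(cfg, "random", spec), spec)
  part <- dots_partition()
  tc <- trial_config(spec, part, query = "estimate",
                     rule = stopping_rule("fixed_n", n_fixed = 1),
                     sampler = cfg, anchor = 75.5, rate_lambda = 10)
  res <- run_trial(tc, st, beta11())
  # one step from 75.5 with a 0.75-sd proposal cannot reach the posterior bulk
  expect_gt(res$record$samples[1], 60)
})

test_that("identical seeds give bit-identical sample streams", {
  spec <- dots_spec()
  cfg <- sampler_config("mc3")
  runs <- lapply(1:2, function(i) {
    set.seed(408)
    st <- init_state(cfg, "random", spec)
    draw_samples(st, spec, cfg, 500)
  })
  expect_identical(runs[[1]]$samples, runs[[2]]$samples)
  expect_identical(runs[[1]]$state$chain_positions,
                   runs[[2]]$state$chain_positions)
})

test_that("next_sample is the single-draw form of draw_samples", {
  spec <- dots_spec()
  cfg <- sampler_config("rwm")
  set.seed(409); st <- init_state(cfg, "random", spec)
  a <- next_sample(st, spec, cfg)
  set.seed(409); st <- init_state(cfg, "random", spec)
  b <- draw_samples(st, spec, cfg, 1)
  expect_identical(a$sample, b$samples)
})
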