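test_that("choice batteries map difficulty to posterior-mean offsets with random sides", {
  set.seed(460)
  v <- abs_variant("full")
  pp <- effect_params(n_trials = 200L)
  bat <- make_task_battery("choice", v, pp, d = 2, delta = 2L)
  mu <- vapply(bat, function(cfg) cfg$spec$mean, 0)
  side <- vapply(bat, function(cfg) cfg$correct, 0L)
  expect_setequal(unique(mu), c(25 - 6, 25 + 6))
  expect_equal(mu > 25, side == 2L)
  expect_gt(mean(side == 2L), 0.3)
  # offset of 2 sd puts ~97.7% of the posterior mass on the correct side
  frac <- 1 - pnorm(25, mean = 25 + 2 * 3, sd = 3)
  expect_equal(frac, pnorm(2), tolerance = 1e-12)
})

test_that("anchoring batteries span the stated stimulus range around the comparison value", {
  set.seed(461)
  v <- abs_variant("full")
  bat <- make_task_battery("anchoring", v, effect_params(n_trials = 300L),
                           anchor = 75.5)
  mu <- vapply(bat, function(cfg) cfg$spec$mean, 0)
  expect_gte(min(mu), 21)
  expect_lte(max(mu), 30)
  expect_true(all(vapply(bat, function(cfg) cfg$anchor, 0) == 75.5))
  expect_error(make_task_battery("nonsense", v), "unknown battery")
})

test_that("variant definitions carry exactly their documented overrides", {
  full <- abs_variant("full")
  expect_equal(full$alpha, 1)
  expect_true(full$adaptive)
  expect_identical(full$sampler$algorithm, "mc3")
  expect_true(is.na(full$fixed_n))
  np <- abs_variant("no_prior")
  expect_equal(np$alpha, 0)
  expect_false(np$adaptive)
  ds <- abs_variant("direct_sampling")
  expect_identical(ds$sampler$algorithm, "direct")
  fx <- abs_variant("fixed_sample_size")
  expect_identical(fx$fixed_n, 5L)
  expect_identical(absampler:::variant_choice_rule(fx, 5L)$kind, "fixed_n")
  expect_identical(absampler:::variant_choice_rule(full, 5L)$delta, 5L)
})

test_that("effect reports are reproducible bit-exactly under a fixed seed", {
  pp <- effect_params(n_trials = 400L)
  a <- run_effect("speed_accuracy", "full", seed = 7, params = pp)
  b <- run_effect("speed_accuracy", "full", seed = 7, params = pp)
  expect_identical(a$statistics, b$statistics)
  expect_identical(a$se, b$se)
  c <- run_effect("speed_accuracy", "full", seed = 8, params = pp)
  expect_false(identical(a$statistics, c$statistics))
})

test_that("prior-driven effects hold across a small parameter neighbourhood", {
  # sensitivity sweep: the conjunction fallacy and subadditivity direction
  # survive halving the trial budget and changing the judgment sample size
  for (nj in c(4L, 5L)) {
    pp <- effect_params(n_trials = 3000L, n_judgment = nj)
    r <- run_effect("conjunction", "direct_sampling", seed = 12, params = pp)
    expect_gt(r$statistics["fallacy_rate"], 0.5)
    s <- run_effect("subadditivity", "direct_sampling", seed = 13, params = pp)
    expect_gt(s$statistics["bias_m5"], 0)
    expect_lt(abs(s$statistics["bias_m3"] -
                    subadditivity_bias(3, nj, 1)), 0.05)
  }
})

test_that("the expected ablation grid has the documented structure", {
  m <- table2_expected()
  expect_identical(dim(m), c(17L, 4L))
  expect_true(all(m[, "full"]))                  # full model passes everything
  expect_false(m["one_over_f", "direct_sampling"])
  expect_false(m["anchoring", "direct_sampling"])
  expect_false(m["qq_fan", "fixed_sample_size"])
  expect_false(m["fast_errors", "no_prior"])
  expect_false(m["slow_errors", "direct_sampling"])
})
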