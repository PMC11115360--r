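#' Default task and condition parameters for the effect battery
#'
#' Difficulty is the offset of the posterior mean from the decision boundary
#' in units of the posterior sd; larger offsets make the sampled evidence
#' more homogeneous.  Accuracy emphasis raises the max-minus-next threshold;
#' speed emphasis lowers it.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
effect_params <- function(...) {
  p <- list(
    sd = 3,              # posterior sd, hypothesis units (e.g., dots)
    boundary = 25,       # decision boundary for binary numerosity choices
    d_hard = 0.5,        # difficult condition, in sd units
    d_moderate = 1,
    d_easy = 2,
    delta_acc = 5L,      # accuracy-emphasis threshold
    delta_speed = 2L,    # speed-emphasis threshold
    delta_anchor = 16L,  # threshold for the decision-then-estimation task
    lambda = 10,         # samples per second
    t0 = 0.2,            # nondecision time, seconds
    n_judgment = 5L,     # fixed sample size for judgment-type queries
    conj_budget = 0.5,   # conjunction sample budget factor (N_conj = ceil(f N))
    n_trials = 10000L,   # trials per condition
    mean_range = c(21, 30),   # stimulus means for the decision-estimation task
    anchor_near = 25.5,
    anchor_far = 75.5,
    ci_gamma = 0.6,      # requested coverage in interval production
    eval_mass = 0.8,     # true mass of the evaluated interval
    n_series = 1024L,    # trials per simulated participant, spectral battery
    n_participants = 10L,
    n_max = 1000L,       # cap on samples per trial
    n_blocks = 20L       # blocks for Monte-Carlo standard errors
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  p
}

the_effects <- c("slow_errors", "fast_errors", "speed_accuracy", "qq_fan",
                 "resolution_of_confidence", "confidence_discriminability",
                 "confidence_rt_within", "confidence_rt_between", "metacog",
                 "interval_calibration", "anchoring", "repulsion",
                 "conservatism_meanvar", "subadditivity", "conjunction",
                 "partition_dependence", "one_over_f")

#' Generate a battery of trial configurations for one task type
#'
#' @param kind `"choice"` (binary numerosity comparison, random correct side
#'   per trial, difficulty `d`), `"anchoring"` (decision-then-estimation with
#'   an anchored comparison value), `"estimation"` (repeated fixed-N
#'   estimation of one fixed quantity), `"interval_production"`,
#'   `"interval_evaluation"`, or `"probability_judgment"`.
#' @param variant An [abs_variant()].
#' @param params From [effect_params()].
#' @param n Number of trials.
#' @param d Difficulty (sd units) for choice batteries.
#' @param delta Max-minus-next threshold for choice batteries.
#' @param anchor Comparison value h* for the anchoring battery.
#' @param p Target event probability for judgment batteries.
#' @param query Query override for choice-type batteries.
#' @return A list of [trial_config()] objects.
#' @export
make_task_battery <- function(kind, variant = abs_variant(),
                              params = effect_params(),
                              n = params$n_trials, d = params$d_hard,
                              delta = params$delta_acc,
                              anchor = params$anchor_far, p = 0.5,
                              query = NULL) {
  pp <- params
  part <- partition_spec(pp$boundary, labels = c("lower", "greater"))
  judge_rule <- stopping_rule("fixed_n", n_fixed = pp$n_judgment,
                              n_max = pp$n_max)
  mk <- function(spec, query, rule, ...) {
    trial_config(spec, part, query = query, rule = rule,
                 sampler = variant$sampler, rate_lambda = pp$lambda,
                 t0 = pp$t0, ...)
  }
  switch(kind,
    choice = {
      side <- sample(c(1L, 2L), n, replace = TRUE)
      mu <- pp$boundary + ifelse(side == 2L, 1, -1) * d * pp$sd
      rule <- variant_choice_rule(variant, delta, pp$n_max)
      tpl <- mk(posterior_spec("gaussian", mu[1], pp$sd),
                query = if (is.null(query)) "choice" else query,
                rule = rule, correct = side[1], reinit = TRUE)
      lapply(seq_len(n), function(i) {
        cfg <- tpl
        cfg$spec$mean <- mu[i]
        cfg$correct <- side[i]
        cfg
      })
    },
    anchoring = {
      mu <- runif(n, pp$mean_range[1], pp$mean_range[2])
      apart <- partition_spec(anchor, labels = c("lower", "greater"))
      rule <- variant_choice_rule(variant, delta, pp$n_max)
      tpl <- trial_config(posterior_spec("gaussian", mu[1], pp$sd), apart,
                          query = "choice_plus_estimate", rule = rule,
                          sampler = variant$sampler, anchor = anchor,
                          correct = 1L, rate_lambda = pp$lambda, t0 = pp$t0)
      lapply(seq_len(n), function(i) {
        cfg <- tpl
        cfg$spec$mean <- mu[i]
        cfg$correct <- if (mu[i] >= anchor) 2L else 1L
        cfg
      })
    },
    estimation = {
      spec <- posterior_spec("gaussian", pp$boundary - 1, pp$sd)
      cfg <- mk(spec, "estimate", judge_rule)
      rep(list(cfg), n)
    },
    interval_production = {
      spec <- posterior_spec("gaussian", pp$boundary - 1, pp$sd)
      cfg <- mk(spec, "ci_produce", judge_rule, ci_level = pp$ci_gamma)
      rep(list(cfg), n)
    },
    interval_evaluation = {
      spec <- posterior_spec("gaussian", pp$boundary - 1, pp$sd)
      half <- (1 - pp$eval_mass) / 2
      iv <- spec$mean + qnorm(c(half, 1 - half)) * pp$sd
      cfg <- mk(spec, "ci_evaluate", judge_rule, eval_interval = iv)
      rep(list(cfg), n)
    },
    probability_judgment = {
      mu <- pp$boundary + qnorm(p) * pp$sd
      cfg <- mk(posterior_spec("gaussian", mu, pp$sd),
                "probability_judgment", judge_rule, target = 2L)
      rep(list(cfg), n)
    },
    stop("unknown battery kind: ", kind)
  )
}

# ---- Monte-Carlo standard errors from contiguous blocks -----------------
# trials are serially dependent (carryover), so SEs come from block means
block_stat <- function(df, stat_fn, nblocks = 20L) {
  n <- nrow(df)
  g <- ceiling(seq_len(n) / (n / nblocks))
  bs <- vapply(split(seq_len(n), g),
               function(i) stat_fn(df[i, , drop = FALSE]), 0)
  bs <- bs[is.finite(bs)]
  list(value = stat_fn(df), se = stats::sd(bs) / sqrt(length(bs)),
       blocks = bs)
}

zpass <- function(value, se, z = 3) is.finite(value) && se > 0 && value > z * se

run_battery <- function(battery, variant) {
  run_trials(battery, variant_prior(variant), adaptive = variant$adaptive)
}

new_report <- function(effect_id, variant, statistics, se, passed, seed,
                       n_trials) {
  structure(list(effect_id = effect_id, variant = variant$name,
                 statistics = statistics, se = se, passed = passed,
                 seed = seed, n_trials = n_trials),
            class = "abs_effect_report")
}

#' @export
print.abs_effect_report <- function(x, ...) {
  cat(sprintf("Effect %s, variant %s: %s (seed %d, %d trials)\n",
              x$effect_id, x$variant, if (x$passed) "PASS" else "FAIL",
              x$seed, x$n_trials))
  s <- format(signif(x$statistics, 4))
  e <- format(signif(x$se[names(x$statistics)], 3))
  for (nm in names(x$statistics))
    cat(sprintf("  %-22s %s (se %s)\n", nm, s[nm], e[nm]))
  invisible(x)
}

# ---- individual effects -------------------------------------------------

eff_slow_errors <- function(variant, pp) {
  df <- run_battery(make_task_battery("choice", variant, pp,
                                      d = pp$d_hard, delta = pp$delta_acc),
                    variant)
  st <- block_stat(df, function(d) mean(d$rt[!d$correct]) -
                     mean(d$rt[d$correct]), pp$n_blocks)
  list(statistics = c(rt_error_minus_correct = st$value,
                      accuracy = mean(df$correct),
                      mean_rt = mean(df$rt)),
       se = c(rt_error_minus_correct = st$se),
       passed = zpass(st$value, st$se), n = nrow(df))
}

eff_fast_errors <- function(variant, pp) {
  # the prior-driven RT asymmetry is a fraction of one sampling interval,
  # so this battery is larger to hold the Monte-Carlo SE under a fifth of it
  df <- run_battery(make_task_battery("choice", variant, pp,
                                      n = 10L * pp$n_trials,
                                      d = pp$d_easy, delta = pp$delta_speed),
                    variant)
  st <- block_stat(df, function(d) mean(d$rt[d$correct]) -
                     mean(d$rt[!d$correct]), pp$n_blocks)
  list(statistics = c(rt_correct_minus_error = st$value,
                      accuracy = mean(df$correct),
                      error_rate = mean(!df$correct)),
       se = c(rt_correct_minus_error = st$se),
       passed = zpass(st$value, st$se), n = nrow(df))
}

# two emphasis conditions: the threshold Delta for optional-stopping
# variants; the sample budget N for the fixed-sample-size variant (its only
# speed/accuracy control)
emphasis_batteries <- function(variant, pp, d) {
  if (!is.na(variant$fixed_n)) {
    lax <- variant; lax$fixed_n <- 2L
    strict <- variant; strict$fixed_n <- 10L
    list(lax = make_task_battery("choice", lax, pp, d = d),
         strict = make_task_battery("choice", strict, pp, d = d),
         lax_variant = lax, strict_variant = strict)
  } else {
    list(lax = make_task_battery("choice", variant, pp, d = d,
                                 delta = pp$delta_speed),
         strict = make_task_battery("choice", variant, pp, d = d,
                                    delta = pp$delta_acc),
         lax_variant = variant, strict_variant = variant)
  }
}

eff_speed_accuracy <- function(variant, pp) {
  bb <- emphasis_batteries(variant, pp, pp$d_moderate)
  lax <- run_battery(bb$lax, bb$lax_variant)
  strict <- run_battery(bb$strict, bb$strict_variant)
  sa <- block_stat(lax, function(d) mean(d$correct), pp$n_blocks)
  sb <- block_stat(strict, function(d) mean(d$correct), pp$n_blocks)
  ra <- block_stat(lax, function(d) mean(d$rt), pp$n_blocks)
  rb <- block_stat(strict, function(d) mean(d$rt), pp$n_blocks)
  acc_gain <- sb$value - sa$value
  rt_cost <- rb$value - ra$value
  se_acc <- sqrt(sa$se^2 + sb$se^2)
  se_rt <- sqrt(ra$se^2 + rb$se^2)
  list(statistics = c(accuracy_gain = acc_gain, rt_cost = rt_cost,
                      accuracy_speed = sa$value, accuracy_acc = sb$value),
       se = c(accuracy_gain = se_acc, rt_cost = se_rt),
       passed = zpass(acc_gain, se_acc) && zpass(rt_cost, se_rt),
       n = nrow(lax) + nrow(strict))
}

eff_qq_fan <- function(variant, pp) {
  run_one <- function(d)
    run_battery(make_task_battery("choice", variant, pp, d = d,
                                  delta = pp$delta_acc), variant)
  easy <- run_one(pp$d_easy)
  hard <- run_one(pp$d_hard)
  qs <- function(d, pr) unname(quantile(d$rt, pr))
  fan_fn <- function(de, dh)
    (qs(dh, 0.9) - qs(de, 0.9)) - (qs(dh, 0.1) - qs(de, 0.1))
  ae <- block_stat(easy, function(d) qs(d, 0.9) - qs(d, 0.1), pp$n_blocks)
  ah <- block_stat(hard, function(d) qs(d, 0.9) - qs(d, 0.1), pp$n_blocks)
  fan <- fan_fn(easy, hard)
  se <- sqrt(ae$se^2 + ah$se^2)
  list(statistics = c(upper_tail_fan = fan,
                      iqr80_easy = ae$value, iqr80_hard = ah$value),
       se = c(upper_tail_fan = se),
       passed = zpass(fan, se), n = nrow(easy) + nrow(hard))
}

eff_resolution_of_confidence <- function(variant, pp) {
  df <- run_battery(make_task_battery("choice", variant, pp,
                                      d = pp$d_hard, delta = pp$delta_acc),
                    variant)
  st <- block_stat(df, function(d) mean(d$confidence[d$correct]) -
                     mean(d$confidence[!d$correct]), pp$n_blocks)
  list(statistics = c(conf_correct_minus_error = st$value,
                      accuracy = mean(df$correct)),
       se = c(conf_correct_minus_error = st$se),
       passed = zpass(st$value, st$se), n = nrow(df))
}

eff_confidence_discriminability <- function(variant, pp) {
  ds <- c(pp$d_hard, pp$d_moderate, pp$d_easy)
  res <- lapply(ds, function(d)
    run_battery(make_task_battery("choice", variant, pp, d = d,
                                  delta = pp$delta_speed), variant))
  m <- vapply(res, function(d) mean(d$confidence), 0)
  st <- lapply(res, function(d)
    block_stat(d, function(x) mean(x$confidence), pp$n_blocks))
  gain <- m[3] - m[1]
  se <- sqrt(st[[1]]$se^2 + st[[3]]$se^2)
  list(statistics = c(conf_gain_easy_vs_hard = gain, conf_hard = m[1],
                      conf_moderate = m[2], conf_easy = m[3]),
       se = c(conf_gain_easy_vs_hard = se),
       passed = zpass(gain, se) && m[1] < m[2] && m[2] < m[3],
       n = sum(vapply(res, nrow, 0L)))
}

eff_confidence_rt_within <- function(variant, pp) {
  df <- run_battery(make_task_battery("choice", variant, pp,
                                      d = pp$d_moderate,
                                      delta = pp$delta_acc), variant)
  st <- block_stat(df, function(d) {
    if (stats::sd(d$confidence) == 0 || stats::sd(d$rt) == 0) return(NA_real_)
    -cor(d$confidence, d$rt)
  }, pp$n_blocks)
  list(statistics = c(neg_conf_rt_correlation = st$value),
       se = c(neg_conf_rt_correlation = st$se),
       passed = zpass(st$value, st$se), n = nrow(df))
}

eff_confidence_rt_between <- function(variant, pp) {
  bb <- emphasis_batteries(variant, pp, pp$d_moderate)
  lax <- run_battery(bb$lax, bb$lax_variant)
  strict <- run_battery(bb$strict, bb$strict_variant)
  ca <- block_stat(lax, function(d) mean(d$confidence), pp$n_blocks)
  cb <- block_stat(strict, function(d) mean(d$confidence), pp$n_blocks)
  ra <- block_stat(lax, function(d) mean(d$rt), pp$n_blocks)
  rb <- block_stat(strict, function(d) mean(d$rt), pp$n_blocks)
  conf_gain <- cb$value - ca$value
  rt_gain <- rb$value - ra$value
  se_c <- sqrt(ca$se^2 + cb$se^2)
  se_r <- sqrt(ra$se^2 + rb$se^2)
  list(statistics = c(conf_gain_across = conf_gain, rt_gain_across = rt_gain),
       se = c(conf_gain_across = se_c, rt_gain_across = se_r),
       passed = zpass(conf_gain, se_c) && zpass(rt_gain, se_r),
       n = nrow(lax) + nrow(strict))
}

eff_metacog <- function(variant, pp) {
  df <- run_battery(make_task_battery("choice", variant, pp,
                                      d = pp$d_moderate,
                                      delta = pp$delta_speed), variant)
  tr <- data.frame(stimulus = df$correct_alt, response = df$choice,
                   confidence = df$confidence)
  grid <- sort(unique(tr$confidence))
  ok <- vapply(grid, function(c) sum(tr$confidence >= c) >= 0.05 * nrow(tr),
               TRUE)
  grid <- grid[ok]
  c_lo <- grid[1]
  c_hi <- grid[length(grid)]
  ratio_at <- function(d, crit) {
    meta_dprime(d, crit, signal = 2L) / dprime_from_trials(d, signal = 2L)
  }
  st_hi <- block_stat(tr, function(d) 1 - ratio_at(d, c_hi), pp$n_blocks)
  st_dec <- block_stat(tr, function(d) ratio_at(d, c_lo) - ratio_at(d, c_hi),
                       pp$n_blocks)
  curve <- metacog_curve(tr, criteria = grid, signal = 2L)
  list(statistics = c(one_minus_ratio_top = st_hi$value,
                      ratio_drop = st_dec$value,
                      ratio_top = 1 - st_hi$value,
                      d_prime = curve$d[1]),
       se = c(one_minus_ratio_top = st_hi$se, ratio_drop = st_dec$se),
       passed = zpass(st_hi$value, st_hi$se) && zpass(st_dec$value, st_dec$se),
       n = nrow(df))
}

eff_interval_calibration <- function(variant, pp) {
  prod <- run_battery(make_task_battery("interval_production", variant, pp),
                      variant)
  spec_mean <- pp$boundary - 1
  cover <- pnorm(prod$ci_hi, spec_mean, pp$sd) -
    pnorm(prod$ci_lo, spec_mean, pp$sd)
  prod$coverage <- cover
  st_over <- block_stat(prod, function(d) pp$ci_gamma - mean(d$coverage),
                        pp$n_blocks)
  ev <- run_battery(make_task_battery("interval_evaluation", variant, pp),
                    variant)
  st_bias <- block_stat(ev, function(d) mean(d$prob_judgment) - pp$eval_mass,
                        pp$n_blocks)
  list(statistics = c(production_overconfidence = st_over$value,
                      production_coverage = mean(cover),
                      evaluation_bias = st_bias$value),
       se = c(production_overconfidence = st_over$se,
              evaluation_bias = st_bias$se),
       passed = zpass(st_over$value, st_over$se) &&
         abs(st_bias$value) < 0.03,
       n = nrow(prod) + nrow(ev))
}

eff_anchoring <- function(variant, pp) {
  bat <- make_task_battery("anchoring", variant, pp,
                           anchor = pp$anchor_far, delta = pp$delta_anchor)
  mu <- vapply(bat, function(cfg) cfg$spec$mean, 0)
  df <- run_battery(bat, variant)
  df$pull <- df$estimate - mu
  st <- block_stat(df, function(d) mean(d$pull), pp$n_blocks)
  list(statistics = c(pull_toward_far_anchor = st$value,
                      mean_estimate = mean(df$estimate)),
       se = c(pull_toward_far_anchor = st$se),
       passed = zpass(st$value, st$se), n = nrow(df))
}

eff_repulsion <- function(variant, pp) {
  # repulsion shows as an estimate-mass deficit in the anchor's vicinity
  # relative to the true stimulus distribution (a dip at the boundary)
  bat <- make_task_battery("anchoring", variant, pp,
                           anchor = pp$anchor_near, delta = pp$delta_anchor)
  mu <- vapply(bat, function(cfg) cfg$spec$mean, 0)
  df <- run_battery(bat, variant)
  w <- pp$sd / 2
  df$mu_near <- abs(mu - pp$anchor_near) < w
  df$est_near <- abs(df$estimate - pp$anchor_near) < w
  st <- block_stat(df, function(d) mean(d$mu_near) - mean(d$est_near),
                   pp$n_blocks)
  list(statistics = c(near_anchor_mass_deficit = st$value,
                      p_truth_near = mean(df$mu_near),
                      p_estimate_near = mean(df$est_near)),
       se = c(near_anchor_mass_deficit = st$se),
       passed = zpass(st$value, st$se), n = nrow(df))
}

eff_conservatism_meanvar <- function(variant, pp) {
  ps <- seq(0.1, 0.9, by = 0.2)
  n_per <- max(200L, pp$n_trials %/% length(ps))
  res <- lapply(ps, function(p)
    run_battery(make_task_battery("probability_judgment", variant, pp,
                                  n = n_per, p = p), variant))
  m <- vapply(res, function(d) mean(d$prob_judgment), 0)
  v <- vapply(res, function(d) var(d$prob_judgment), 0)
  st_lo <- block_stat(res[[1]], function(d) mean(d$prob_judgment) - ps[1],
                      pp$n_blocks)
  st_hi <- block_stat(res[[length(ps)]],
                      function(d) ps[length(ps)] - mean(d$prob_judgment),
                      pp$n_blocks)
  inv_u <- v[3] > v[1] && v[3] > v[5]
  list(statistics = c(pull_up_at_low_p = st_lo$value,
                      pull_down_at_high_p = st_hi$value,
                      var_mid = v[3], var_low = v[1], var_high = v[5]),
       se = c(pull_up_at_low_p = st_lo$se, pull_down_at_high_p = st_hi$se),
       passed = zpass(st_lo$value, st_lo$se) &&
         zpass(st_hi$value, st_hi$se) && inv_u,
       n = n_per * length(ps))
}

# judge the probability that a hypothesis sample falls in (a, b] using a
# fixed sample size and the variant's symmetric Beta prior
judge_intervals <- function(variant, pp, intervals, nrep) {
  spec <- posterior_spec("gaussian", pp$boundary - 1, pp$sd)
  n_ev <- length(intervals)
  order_idx <- rep(seq_len(n_ev), nrep)
  state <- init_state(variant$sampler, "random", spec)
  a0 <- variant$alpha
  nj <- pp$n_judgment
  out <- matrix(NA_real_, nrow = nrep, ncol = n_ev)
  row_i <- rep(1L, n_ev)
  for (ev in order_idx) {
    d <- draw_samples(state, spec, variant$sampler, nj)
    state <- carryover(d$state, spec)
    iv <- intervals[[ev]]
    s <- sum(d$samples > iv[1] & d$samples <= iv[2])
    out[row_i[ev], ev] <- (a0 + s) / (nj + 2 * a0)
    row_i[ev] <- row_i[ev] + 1L
  }
  out
}

eff_subadditivity <- function(variant, pp) {
  nrep <- max(200L, pp$n_trials %/% 20L)
  mps <- 2:5
  spec_mean <- pp$boundary - 1
  tail_mass <- 0.3
  stats <- c(); ses <- c(); ok <- TRUE
  for (mp in mps) {
    qs <- qnorm(1 - tail_mass * (mp:0) / mp, spec_mean, pp$sd)
    comps <- lapply(seq_len(mp), function(k) c(qs[k], qs[k + 1]))
    disj <- list(c(qs[1], Inf))
    j <- judge_intervals(variant, pp, c(comps, disj), nrep)
    bias_rows <- rowSums(j[, seq_len(mp), drop = FALSE]) - j[, mp + 1]
    bias <- mean(bias_rows)
    se <- stats::sd(bias_rows) / sqrt(nrep)
    pred <- subadditivity_bias(mp, pp$n_judgment, variant$alpha)
    nm <- paste0("bias_m", mp)
    stats[nm] <- bias; ses[nm] <- se
    stats[paste0("predicted_m", mp)] <- pred
    ok <- ok && abs(bias - pred) <= 3 * se
    if (mp == max(mps)) ok <- ok && zpass(bias, se)
  }
  # mutually exhaustive binary complements: bias should vanish
  ex <- judge_intervals(variant, pp,
                        list(c(-Inf, spec_mean), c(spec_mean, Inf)), nrep)
  ex_rows <- rowSums(ex) - 1
  stats["bias_exhaustive_m2"] <- mean(ex_rows)
  ses["bias_exhaustive_m2"] <- stats::sd(ex_rows) / sqrt(nrep)
  ok <- ok && abs(stats["bias_exhaustive_m2"]) <=
    3 * ses["bias_exhaustive_m2"] + 1e-12
  list(statistics = stats, se = ses, passed = ok,
       n = nrep * (sum(mps + 1) + 2))
}

eff_conjunction <- function(variant, pp) {
  n_pairs <- max(500L, pp$n_trials %/% 2L)
  spec_mean <- pp$boundary - 1
  p_a <- 0.1
  p_conj <- 0.08
  iv_a <- c(qnorm(1 - p_a, spec_mean, pp$sd), Inf)
  iv_c <- c(qnorm(1 - p_conj, spec_mean, pp$sd), Inf)
  spec <- posterior_spec("gaussian", spec_mean, pp$sd)
  state <- init_state(variant$sampler, "random", spec)
  a0 <- variant$alpha
  nj <- pp$n_judgment
  nc <- max(1L, as.integer(ceiling(pp$conj_budget * nj)))
  fall <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    da <- draw_samples(state, spec, variant$sampler, nj)
    state <- da$state
    dc <- draw_samples(state, spec, variant$sampler, nc)
    state <- carryover(dc$state, spec)
    ja <- (a0 + sum(da$samples > iv_a[1])) / (nj + 2 * a0)
    jc <- (a0 + sum(dc$samples > iv_c[1])) / (nc + 2 * a0)
    fall[i] <- jc > ja
  }
  rate <- mean(fall)
  se <- stats::sd(fall) / sqrt(n_pairs)
  list(statistics = c(fallacy_rate = rate, excess_over_chance = rate - 0.5),
       se = c(fallacy_rate = se, excess_over_chance = se),
       passed = zpass(rate - 0.5, se), n = n_pairs)
}

eff_partition_dependence <- function(variant, pp) {
  ms <- 2:7
  ps <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  nrep <- max(50L, pp$n_trials %/% (length(ms) * length(ps) * 4L))
  nj <- pp$n_judgment
  stats <- c(); ses <- c(); ok <- TRUE
  for (m in ms) {
    jm <- c(); pm <- c()
    for (p in ps) {
      probs <- c(p, rep((1 - p) / (m - 1), m - 1))
      spec <- posterior_spec("discrete_grid", grid_values = seq_len(m),
                             grid_logmass = log(probs))
      state <- init_state(variant$sampler, "random", spec)
      a0 <- variant$alpha
      for (r in seq_len(nrep)) {
        d <- draw_samples(state, spec, variant$sampler, nj)
        state <- carryover(d$state, spec)
        s <- sum(d$samples == 1)
        jm <- c(jm, (a0 + s) / (nj + m * a0))
        pm <- c(pm, p)
      }
    }
    fit <- lm(jm ~ pm)
    sl <- unname(coef(fit)[2]); ic <- unname(coef(fit)[1])
    se_sl <- summary(fit)$coefficients[2, 2]
    se_ic <- summary(fit)$coefficients[1, 2]
    stats[paste0("slope_m", m)] <- sl
    stats[paste0("intercept_m", m)] <- ic
    ses[paste0("slope_m", m)] <- se_sl
    ses[paste0("intercept_m", m)] <- se_ic
    ok <- ok && zpass(1 - sl, se_sl) && zpass(ic, se_ic)
  }
  list(statistics = stats, se = ses, passed = ok,
       n = length(ms) * length(ps) * nrep)
}

eff_one_over_f <- function(variant, pp) {
  # repeated decision-plus-estimation of one fixed stimulus
  spec <- posterior_spec("gaussian", pp$boundary + pp$d_hard * pp$sd, pp$sd)
  part <- partition_spec(pp$boundary, labels = c("lower", "greater"))
  rule <- variant_choice_rule(variant, pp$delta_speed, pp$n_max)
  cfg <- trial_config(spec, part, query = "choice_plus_estimate",
                      rule = rule, sampler = variant$sampler, correct = 2L,
                      rate_lambda = pp$lambda, t0 = pp$t0)
  est_slopes <- numeric(pp$n_participants)
  rt_slopes <- numeric(pp$n_participants)
  for (k in seq_len(pp$n_participants)) {
    df <- run_battery(rep(list(cfg), pp$n_series), variant)
    est_slopes[k] <- power_spectrum(df$estimate)$slope
    rt_slopes[k] <- power_spectrum(df$rt)$slope
  }
  m_est <- mean(est_slopes); m_rt <- mean(rt_slopes)
  se_est <- stats::sd(est_slopes) / sqrt(pp$n_participants)
  se_rt <- stats::sd(rt_slopes) / sqrt(pp$n_participants)
  dd <- rt_slopes - est_slopes
  se_d <- stats::sd(dd) / sqrt(pp$n_participants)
  in_band <- m_est >= -1.5 && m_est <= -0.5
  list(statistics = c(estimate_slope = m_est, rt_slope = m_rt,
                      rt_minus_estimate_slope = mean(dd)),
       se = c(estimate_slope = se_est, rt_slope = se_rt,
              rt_minus_estimate_slope = se_d),
       passed = in_band && zpass(mean(dd), se_d),
       n = pp$n_participants * pp$n_series)
}

#' Run one qualitative effect for one model variant
#'
#' Simulates the effect's trial battery with the given variant and evaluates
#' the effect's directional criterion as a one-sided test at three
#' Monte-Carlo standard errors (standard errors from contiguous trial
#' blocks, so serial dependence is respected).
#'
#' @param effect_id One of `"slow_errors"`, `"fast_errors"`,
#'   `"speed_accuracy"`, `"qq_fan"`, `"resolution_of_confidence"`,
#'   `"confidence_discriminability"`, `"confidence_rt_within"`,
#'   `"confidence_rt_between"`, `"metacog"`, `"interval_calibration"`,
#'   `"anchoring"`, `"repulsion"`, `"conservatism_meanvar"`,
#'   `"subadditivity"`, `"conjunction"`, `"partition_dependence"`,
#'   `"one_over_f"`.
#' @param variant An [abs_variant()] or variant name.
#' @param seed Integer seed; every random quantity in the effect derives
#'   from it.
#' @param params From [effect_params()].
#' @return An `"abs_effect_report"` with named `statistics`, their `se`, and
#'   the `passed` flag.
#' @export
run_effect <- function(effect_id, variant = abs_variant("full"), seed = 1L,
                       params = effect_params()) {
  if (is.character(variant)) variant <- abs_variant(variant)
  stopifnot(effect_id %in% the_effects)
  set.seed(seed)
  fn <- get(paste0("eff_", effect_id), mode = "function")
  res <- fn(variant, params)
  new_report(effect_id, variant, res$statistics, res$se, res$passed,
             as.integer(seed), as.integer(res$n))
}

#' Expected ablation pattern of the effect battery
#'
#' Which effects each model variant is predicted to reproduce, given the
#' ingredient each effect requires: local autocorrelated sampling (slow
#' errors, anchoring, 1/f structure), optional stopping (slow and fast
#' errors, repulsion, Q-Q fanning, resolution of confidence, within-condition
#' confidence-RT coupling), and the response prior (conservatism,
#' subadditivity, conjunction fallacy, partition dependence; its adaptive
#' component drives fast errors).
#'
#' Without pseudocounts the stopped confidence `(N + Delta) / (2N)`
#' saturates at 1 on the unanimous short trials that dominate run-like
#' autocorrelated evidence, so the no-prior variant cannot show the positive
#' cross-condition confidence-RT relation; that relation is carried by the
#' prior's tempering of small samples.
#'
#' The fixed-sample-size variant is marked as producing resolution of
#' confidence: its confidence is a monotone transform of the sample tally,
#' and a tally informative enough about accuracy to yield a positive
#' meta-d-prime (which all variants produce) necessarily yields higher mean
#' confidence on correct than on incorrect trials.  Equating confidence on
#' correct and error trials at fixed N would require every trial's evidence
#' to be unanimous, which would simultaneously abolish the metacognition
#' effect.
#'
#' @return A logical matrix, effects by variants.
#' @export
table2_expected <- function() {
  v <- c("no_prior", "direct_sampling", "fixed_sample_size", "full")
  m <- rbind(
    slow_errors                 = c(TRUE,  FALSE, FALSE, TRUE),
    fast_errors                 = c(FALSE, TRUE,  FALSE, TRUE),
    speed_accuracy              = c(TRUE,  TRUE,  TRUE,  TRUE),
    qq_fan                      = c(TRUE,  TRUE,  FALSE, TRUE),
    resolution_of_confidence    = c(TRUE,  FALSE, TRUE,  TRUE),
    confidence_discriminability = c(TRUE,  TRUE,  TRUE,  TRUE),
    confidence_rt_within        = c(TRUE,  TRUE,  FALSE, TRUE),
    confidence_rt_between       = c(FALSE, TRUE,  TRUE,  TRUE),
    metacog                     = c(TRUE,  TRUE,  TRUE,  TRUE),
    interval_calibration        = c(TRUE,  TRUE,  TRUE,  TRUE),
    anchoring                   = c(TRUE,  FALSE, TRUE,  TRUE),
    repulsion                   = c(TRUE,  TRUE,  FALSE, TRUE),
    conservatism_meanvar        = c(FALSE, TRUE,  TRUE,  TRUE),
    subadditivity               = c(FALSE, TRUE,  TRUE,  TRUE),
    conjunction                 = c(FALSE, TRUE,  TRUE,  TRUE),
    partition_dependence        = c(FALSE, TRUE,  TRUE,  TRUE),
    one_over_f                  = c(TRUE,  FALSE, TRUE,  TRUE)
  )
  colnames(m) <- v
  m
}

#' Run the full effect-by-variant grid
#'
#' Runs every effect for every variant and collects the pass/fail flags.
#' Each cell gets its own seed derived from `seed`, so the grid is
#' reproducible and cells are independent of execution order.
#'
#' @param seed Base integer seed.
#' @param variants Variant names to include.
#' @param effects Effect ids to include.
#' @param params From [effect_params()].
#' @param verbose Print per-cell progress to stderr.
#' @return A logical matrix (effects by variants) of class `"abs_table2"`,
#'   with the per-cell reports in attribute `"reports"`.
#' @export
table2_matrix <- function(seed = 1L,
                          variants = c("no_prior", "direct_sampling",
                                       "fixed_sample_size", "full"),
                          effects = the_effects,
                          params = effect_params(), verbose = FALSE) {
  grid <- matrix(NA, nrow = length(effects), ncol = length(variants),
                 dimnames = list(effects, variants))
  reports <- list()
  for (i in seq_along(effects)) {
    for (j in seq_along(variants)) {
      cell_seed <- as.integer(seed) + 1000L * i + j
      t0 <- proc.time()[3]
      rep_ij <- run_effect(effects[i], variants[j], seed = cell_seed,
                           params = params)
      if (verbose)
        message(sprintf("%-28s %-18s %s  (%.1fs)", effects[i], variants[j],
                        if (rep_ij$passed) "pass" else "fail",
                        proc.time()[3] - t0))
      grid[i, j] <- rep_ij$passed
      reports[[paste(effects[i], variants[j], sep = ".")]] <- rep_ij
    }
  }
  structure(grid, class = c("abs_table2", "matrix"),
            reports = reports, seed = as.integer(seed))
}

#' @export
print.abs_table2 <- function(x, ...) {
  m <- unclass(x)
  attr(m, "reports") <- NULL
  attr(m, "seed") <- NULL
  disp <- ifelse(m, "pass", "fail")
  print(disp, quote = FALSE)
  invisible(x)
}
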