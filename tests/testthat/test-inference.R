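# Measurement-error correlation model, directional and default Bayes factors.

test_that("measurement SDs follow SD * sqrt(1 - reliability)", {
  expect_equal(measurement_se(1.0, 0.87), sqrt(0.13), tolerance = 1e-12)
  expect_equal(measurement_se(1.0, 0.87), 0.3605551, tolerance = 1e-6)
  expect_equal(measurement_se(1.0, 1.0), 0)
  expect_equal(measurement_se(2.0, 0.78), 2 * sqrt(0.22), tolerance = 1e-12)
  expect_equal(measurement_se(2.0, 0.78), 0.9380832, tolerance = 1e-6)
  expect_error(measurement_se(1, 1.2), "reliability")
  expect_error(measurement_se(-1, 0.5), "sd_observed")
})

test_that("directional BF is the exact posterior count ratio", {
  half <- c(rep(-1, 1000) - runif(1000), rep(1, 1000) + runif(1000))
  expect_equal(bf_directional(half)$bf, 1.0)
  skew <- c(rep(-0.5, 2999), 0.4)
  expect_equal(bf_directional(skew)$bf, 2999)
  expect_false(bf_directional(skew)$is_lower_bound)
  # positive direction is symmetric
  expect_equal(bf_directional(-skew, "positive")$bf, 2999)
  # all-negative draws: lower-bound convention
  allneg <- -abs(rnorm(20000))
  out <- bf_directional(allneg)
  expect_equal(out$bf, 20000)
  expect_true(out$is_lower_bound)
  # zeros belong to neither side
  expect_equal(bf_directional(c(rep(-1, 1500), rep(0, 100), rep(1, 500)))$bf, 3)
  expect_error(bf_directional(numeric(0)), "empty")
  expect_warning(bf_directional(rnorm(100)), "fewer than 1000")
})

test_that("directional BF grows with the posterior mass below zero", {
  set.seed(4)
  base <- rnorm(10000)
  bfs <- vapply(c(0, -0.3, -0.8, -1.5, -2.5), function(shift)
    bf_directional(base + shift)$bf, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("Pearson BF10 matches independent Simpson quadrature within 1%", {
  cases <- expand.grid(n = c(10, 20, 50, 136), r = c(-0.6, -0.26, 0, 0.3, 0.8))
  for (i in seq_len(nrow(cases))) {
    got <- bf10_pearson_stat(cases$r[i], cases$n[i])$bf10
    want <- oracle_bf_pearson(cases$r[i], cases$n[i])
    expect_lt(abs(got / want - 1), 0.01)
  }
  # width parameter reaches the oracle too
  expect_lt(abs(bf10_pearson_stat(0.4, 40, kappa = 0.5)$bf10 /
                  oracle_bf_pearson(0.4, 40, kappa = 0.5) - 1), 0.01)
})

test_that("Pearson BF10 handles null-centred and degenerate data", {
  set.seed(30)
  for (n in c(10, 50, 200)) {
    expect_lt(bf10_pearson_stat(0, n)$bf10, 1)
  }
  x <- rnorm(25)
  res <- bf10_pearson(x, 2 * x + 1)   # r = 1 exactly
  expect_true(res$capped)
  expect_gte(res$bf10, 1e6)
  expect_error(bf10_pearson(x, rep(1, 25)), "zero variance")
  expect_error(bf10_pearson(x[1:2], x[1:2]), "at least 3")
  # data interface agrees with the statistic interface
  y <- 0.5 * x + rnorm(25)
  expect_equal(bf10_pearson(x, y)$bf10,
               bf10_pearson_stat(cor(x, y), 25)$bf10)
})

test_that("JZS t-test BF10 matches independent quadrature within 1%", {
  cases <- expand.grid(n = c(10, 20, 50, 136), t = c(0, 1, 2, 3.5))
  for (i in seq_len(nrow(cases))) {
    n1 <- cases$n[i]
    n2 <- max(2, round(cases$n[i] * 0.6))
    got <- bf10_ttest_stat(cases$t[i], n1, n2)$bf10
    want <- oracle_bf_ttest(cases$t[i], n1, n2)
    expect_lt(abs(got / want - 1), 0.01)
  }
  # identical groups: t = 0 favours the null
  expect_lt(bf10_ttest_stat(0, 30, 30)$bf10, 1)
  expect_lt(bf10_ttest(rep(c(1, 2), 10), rep(c(1, 2), 10))$bf10, 1)
  expect_error(bf10_ttest(rep(1, 10), rep(1, 10)), "zero pooled variance")
})

test_that("large effects give decisive two-sample evidence", {
  # standardized effect size 2 at n = 50 per group: BF10 >> 100 almost always
  set.seed(90)
  hits <- replicate(30, {
    a <- rnorm(50, 0, 1)
    b <- rnorm(50, 2, 1)
    bf10_ttest(a, b)$bf10 > 100
  })
  expect_gte(mean(hits), 0.99)
})

test_that("latent model with zero SEs recovers the plain correlation", {
  set.seed(44)
  n <- 200
  x <- rnorm(n, 0.2, 0.3)
  y <- pmin(20, pmax(0, 10 + rnorm(n, 0, 3)))   # independent of x
  fit <- fit_latent_correlation(x, y, se_x = 0, se_y = 0, chains = 2,
                                iter = 2500, warmup = 500, seed = 6)
  expect_lt(abs(fit$summary["rho", "mean"] - cor(x, y)), 0.05)
  expect_lt(abs(fit$summary["rho", "mean"]), 0.1)
})

test_that("the rho posterior is scale-equivariant", {
  fx <- fx_noisy_pairs()
  f1 <- fit_with_retry(fx$x, fx$y, fx$se_x, fx$se_y, seed = 8,
                       chains = 2, iter = 4000, warmup = 600)
  c_scale <- 2  # keeps the scaled data well inside the uniform prior box
  f2 <- fit_with_retry(fx$x * c_scale, fx$y, fx$se_x * c_scale, fx$se_y,
                       seed = 9, chains = 2, iter = 4000, warmup = 600)
  expect_lt(abs(f1$summary["rho", "mean"] - f2$summary["rho", "mean"]), 0.02)
  expect_lt(abs(f1$summary["rho", "q2.5"] - f2$summary["rho", "q2.5"]), 0.03)
})

test_that("the sampler agrees with JAGS on the same latent model", {
  fx <- fx_noisy_pairs()
  fit <- fit_latent_correlation(fx$x, fx$y, se_x = fx$se_x, se_y = fx$se_y,
                                chains = 4, iter = 10000, warmup = 1000,
                                seed = 13)
  model_str <- "model {
    for (i in 1:N) {
      lat[i, 1:2] ~ dmnorm(mu[1:2], TI[1:2, 1:2])
      x[i] ~ dnorm(lat[i, 1], px)
      y[i] ~ dnorm(lat[i, 2], py)
    }
    mu[1] ~ dunif(-2, 2)
    mu[2] ~ dunif(0, 20)
    sx ~ dunif(0, 2)
    sy ~ dunif(0, 10)
    rho ~ dunif(-1, 1)
    T[1,1] <- sx^2
    T[2,2] <- sy^2
    T[1,2] <- rho * sx * sy
    T[2,1] <- T[1,2]
    TI[1:2, 1:2] <- inverse(T[1:2, 1:2])
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(N = length(fx$x), x = fx$x, y = fx$y,
                px = 1 / fx$se_x^2, py = 1 / fx$se_y^2),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7),
    n.chains = 2, quiet = TRUE)
  update(jm, 3000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, "rho", 30000, progress.bar = "none")
  rho_jags <- unlist(sm)
  expect_lt(abs(fit$summary["rho", "mean"] - mean(rho_jags)), 0.03)
  expect_lt(abs(fit$summary["rho", "q2.5"] - quantile(rho_jags, 0.025)), 0.04)
})

test_that("non-convergence fails loudly with diagnostics attached", {
  fx <- fx_noisy_pairs()
  expect_error(
    fit_latent_correlation(fx$x, fx$y, se_x = fx$se_x, se_y = fx$se_y,
                           chains = 4, iter = 30, warmup = 30, seed = 2,
                           rhat_max = 1.0001),
    "split R-hat")
  set.seed(17)
  xw <- rnorm(40, 0, 0.2)
  yw <- 22 - 10 * xw + rnorm(40)   # well-behaved but outside the (0, 20) box
  expect_warning(
    fit_latent_correlation(xw, yw, chains = 2, iter = 2500, warmup = 600,
                           seed = 3, rhat_max = 1.05),
    "widening bounds")
})

test_that("the item screen always yields 22 rows and flags degenerate items", {
  co <- pupilcorr:::with_seed(55, pupilcorr:::simulate_cohort(
    sim_config(n_participants = 136, true_rho = -0.4)))
  fe <- data.frame(participant_id = co$ids,
                   diff_reward_minus_control = 0.2 + 0.15 * co$trait)
  cli <- derive_clinical(co$clinical)
  screen <- run_item_screen(fe, cli)
  expect_equal(nrow(screen), 22)
  expect_identical(screen$item[22], "anhedonia_score")
  expect_true(all(screen$computable))
  expect_true(all(screen$n == 136))

  # constant item: flagged not computable instead of erroring
  cli2 <- cli
  cli2$bdi_item_07 <- 0L
  screen2 <- run_item_screen(fe, cli2)
  expect_false(screen2$computable[screen2$item == "bdi_item_07"])
  expect_true(is.na(screen2$bf10[screen2$item == "bdi_item_07"]))
  expect_true(all(screen2$computable[screen2$item != "bdi_item_07"]))
})

test_that("trait-loaded BDI items dominate the item screen at n = 136", {
  # cohort-level replicates: measured differential dilation = planted slope
  # difference plus measurement noise at the split-half reliability
  set.seed(70)
  n_rep <- 12
  loaded_hits <- matrix(NA, n_rep, 4)   # items 4, 15, 21 + anhedonia
  false_rates <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    cfg <- sim_config(n_participants = 136, true_rho = -0.4)
    co <- pupilcorr:::simulate_cohort(cfg)
    d_true <- 0.2 + 0.15 * co$trait
    x <- d_true + rnorm(136, 0, sd(d_true) * sqrt(1 / 0.93 - 1))
    fe <- data.frame(participant_id = co$ids, diff_reward_minus_control = x)
    screen <- run_item_screen(fe, derive_clinical(co$clinical))
    hot <- screen$moderate_evidence
    loaded_hits[k, ] <- hot[match(c("bdi_item_04", "bdi_item_15",
                                    "bdi_item_21", "anhedonia_score"),
                                  screen$item)]
    false_rates[k] <- mean(hot[!screen$item %in%
                                 c("bdi_item_04", "bdi_item_15", "bdi_item_21",
                                   "anhedonia_score")])
  }
  # every trait-loaded row reaches moderate evidence in >= 80% of replicates
  expect_true(all(colMeans(loaded_hits) >= 0.8))
  # items that load only on the shared symptom burden rarely cross BF10 > 3
  expect_lt(mean(false_rates), 0.35)
  expect_gt(mean(colMeans(loaded_hits[, 1:3])), mean(false_rates))
})

test_that("null item screens bold at the BF false-positive rate", {
  # all items independent of dilation: the expected number of BF10 > 3 rows
  # matches the simulated false-positive rate of the rule itself
  set.seed(71)
  n_rep <- 40
  n <- 136
  hits <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    co <- pupilcorr:::simulate_cohort(sim_config(n_participants = n,
                                                 true_rho = 0))
    x <- rnorm(n)   # dilation unrelated to anything clinical
    fe <- data.frame(participant_id = co$ids, diff_reward_minus_control = x)
    screen <- run_item_screen(fe, derive_clinical(co$clinical))
    hits[k] <- sum(screen$moderate_evidence)
  }
  fp_rate <- mean(replicate(400, {
    bf10_pearson_stat(cor(rnorm(n), rnorm(n)), n)$bf10 > 3
  }))
  expect_lt(abs(mean(hits) / 22 - fp_rate), 0.05)
  expect_lt(mean(hits) / 22, 0.10)
})
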