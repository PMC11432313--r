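test_that("fixed-effects pooling matches the closed forms", {
  one <- data.frame(rr = 0.3, v = 0.01)
  p1 <- fixed_effects_pool(one)
  expect_equal(p1$rr_plus, 0.3)
  expect_equal(p1$se, 0.1)
  expect_equal(c(p1$ci_low, p1$ci_high), c(0.104, 0.496))

  two <- data.frame(rr = c(0, 1), v = c(1, 1))
  p2 <- fixed_effects_pool(two)
  expect_equal(p2$rr_plus, 0.5)
  expect_equal(p2$se, sqrt(0.5))
  expect_equal(p2$ci_low, 0.5 - 1.96 * sqrt(0.5))
  expect_equal(p2$ci_high, 0.5 + 1.96 * sqrt(0.5))

  same <- data.frame(rr = rep(0.7, 4), v = runif(4, 0.1, 1))
  p3 <- fixed_effects_pool(same)
  expect_equal(p3$rr_plus, 0.7)
  expect_equal(p3$q, 0)
  expect_error(fixed_effects_pool(same[0, ]), "at least 1")
})

test_that("fixed-effects pooled value lies in the effect range and is a fixed point", {
  set.seed(31)
  for (i in 1:20) {
    eff <- sim_effects(sample(2:12, 1), mu = runif(1, -1, 1), tau2 = 0.1)
    p <- fixed_effects_pool(eff)
    expect_gte(p$rr_plus, min(eff$rr))
    expect_lte(p$rr_plus, max(eff$rr))
    expect_true(p$ci_low <= p$rr_plus && p$rr_plus <= p$ci_high)
    # adding an effect equal to the pooled value leaves it unchanged
    aug <- rbind(eff[, c("rr", "v")], data.frame(rr = p$rr_plus, v = 0.3))
    expect_equal(fixed_effects_pool(aug)$rr_plus, p$rr_plus)
  }
})

test_that("Cochran's Q matches hand computation and is chi-square centred", {
  same <- data.frame(rr = rep(0.2, 5), v = rep(0.1, 5))
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0)
  expect_equal(q0$p_value, 1)

  two <- data.frame(rr = c(0, 1), v = c(1, 1))
  expect_equal(cochran_q(two, center = 0.5)$q, 0.5) # 0.25 + 0.25

  # Monte-Carlo: under homogeneity E[Q] = k - 1
  set.seed(32)
  qs <- replicate(800, {
    v <- runif(10, 0.05, 0.2)
    cochran_q(data.frame(rr = rnorm(10, 0.3, sqrt(v)), v = v))$q
  })
  expect_equal(mean(qs), 9, tolerance = 0.05)
})

test_that("I-squared follows its truncated closed form", {
  expect_equal(i_squared(50, 25), 50)
  expect_equal(i_squared(10, 20), 0)
  expect_equal(i_squared(0, 5), 0)
  # large-Q regime: direct evaluation frozen from (q - df)/q * 100
  expect_equal(i_squared(51662.5037, 37), 99.9283813262, tolerance = 1e-9)
})

test_that("DerSimonian-Laird tau2 matches the moment closed form", {
  expect_equal(dl_tau2(data.frame(rr = rep(0.4, 6), v = rep(0.2, 6))), 0)
  # w = 100 each; Q = 100*1 + 100*1 = 200; denom = 200 - 20000/200 = 100
  expect_equal(dl_tau2(data.frame(rr = c(-1, 1), v = c(0.01, 0.01))),
               (200 - 1) / 100)
  expect_error(dl_tau2(data.frame(rr = 1, v = 0.1)), "at least 2")
})

test_that("REML tau2 matches the grid-search oracle on small fixtures", {
  fixtures <- list(
    data.frame(rr = c(0.2, 0.5, -0.1, 0.8, 0.3),
               v = c(0.05, 0.1, 0.08, 0.2, 0.12)),
    data.frame(rr = c(-1, -0.2, 0.4, 1.1), v = rep(0.15, 4)),
    data.frame(rr = c(0.05, 0.1, 0.07), v = c(0.3, 0.25, 0.4)) # homogeneous
  )
  for (eff in fixtures) {
    t_grid <- oracle_reml_grid(eff$rr, eff$v, upper = 10)
    expect_equal(reml_tau2(eff), t_grid, tolerance = 1e-3)
  }
  expect_equal(reml_tau2(data.frame(rr = rep(0.3, 5), v = rep(0.1, 5))), 0)
})

test_that("REML tau2 and random-effects pooling agree with metafor", {
  set.seed(33)
  for (i in 1:5) {
    eff <- sim_effects(30, mu = -0.4, tau2 = 0.06)
    fit <- metafor::rma(yi = eff$rr, vi = eff$v, method = "REML",
                        control = list(maxiter = 500))
    expect_equal(reml_tau2(eff), fit$tau2, tolerance = 1e-4)
    p <- random_effects_pool(eff)
    expect_equal(p$rr_plus, as.numeric(fit$b), tolerance = 1e-5)
    expect_equal(p$se, fit$se, tolerance = 1e-5)
  }
})

test_that("REML tau2 recovers the simulated between-effect variance", {
  set.seed(34)
  est <- replicate(120, reml_tau2(sim_effects(200, mu = 0.2, tau2 = 0.04)))
  expect_lt(abs(median(est) - 0.04), 0.015)
})

test_that("random-effects pooling has the documented limit behaviour", {
  # tau2 estimated at zero -> identical to fixed effects
  hom <- data.frame(rr = rep(0.25, 6), v = runif(6, 0.1, 0.5))
  pr <- random_effects_pool(hom)
  pf <- fixed_effects_pool(hom)
  expect_equal(pr$tau2, 0)
  expect_equal(pr$rr_plus, pf$rr_plus)
  expect_equal(pr$se, pf$se)

  # huge heterogeneity: weights equalise, pooled -> unweighted mean
  set.seed(35)
  big <- data.frame(rr = rnorm(20, 0, 10), v = runif(20, 0.001, 0.01))
  pb <- random_effects_pool(big)
  expect_equal(pb$rr_plus, mean(big$rr), tolerance = 1e-3)

  # heterogeneous set: random-effects CI at least as wide as fixed
  het <- sim_effects(15, mu = 0, tau2 = 0.5, seed = 36)
  expect_gte(random_effects_pool(het)$se, fixed_effects_pool(het)$se)
})

test_that("random-effects 95% CI covers the true mean at nominal rate", {
  set.seed(37)
  hits <- replicate(1000, {
    eff <- sim_effects(50, mu = -0.3, tau2 = 0.05)
    p <- random_effects_pool(eff)
    p$ci_low <= -0.3 && -0.3 <= p$ci_high
  })
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.97)
})

test_that("forest table carries per-effect rows plus both pooled rows", {
  eff <- compute_effects(pair_control_treatment(toy_observations()))
  ft <- forest_table(eff)
  expect_equal(nrow(ft), nrow(eff) + 2)
  expect_equal(sum(ft$weight_fixed_pct[seq_len(nrow(eff))]), 100)
  expect_equal(sum(ft$weight_random_pct[seq_len(nrow(eff))]), 100)
  expect_equal(ft$rr[nrow(eff) + 1], fixed_effects_pool(eff)$rr_plus)
})
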