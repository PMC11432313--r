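test_that("meta-regression recovers an exactly linear moderator signal", {
  eff <- data.frame(
    rr = 0.5 - 0.03 * c(20, 24, 28, 32, 36, 40),
    v = rep(0.1, 6),
    temperature_c = c(20, 24, 28, 32, 36, 40),
    rel_humidity_pct = 70, photoperiod_light_h = 12
  )
  mt <- meta_regression(eff, moderators = "temperature_c")
  expect_equal(mt$coefficients$estimate,
               c(0.5, -0.03), tolerance = 1e-8)
  expect_equal(mt$q_e, 0, tolerance = 1e-10)
  expect_equal(mt$q_t, mt$q_m, tolerance = 1e-10)
})

test_that("degenerate designs are rejected by name", {
  eff <- sim_effects(10, seed = 41)
  eff$temperature_c <- 25 # constant moderator
  expect_error(meta_regression(eff, moderators = "temperature_c"),
               "constant")
  eff$rel_humidity_pct <- NA_real_
  expect_error(moderator_design(eff, "bogus"), "unknown moderator")
  tiny <- data.frame(rr = c(0.1, 0.4), v = c(0.1, 0.1),
                     temperature_c = c(18, 30))
  expect_error(meta_regression(tiny, moderators = "temperature_c"),
               "more effects")
})

test_that("heterogeneity partitions exactly into model and residual parts", {
  set.seed(43)
  for (i in 1:15) {
    k <- sample(8:40, 1)
    eff <- sim_effects(k, mu = 0.2, tau2 = 0.1)
    eff$temperature_c <- runif(k, 18, 36)
    eff$rel_humidity_pct <- sample(c(60, 65, 70, 75, 80), k, replace = TRUE)
    mods <- sample(list("temperature_c", "rel_humidity_pct",
                        c("temperature_c", "rel_humidity_pct")), 1)[[1]]
    mt <- meta_regression(eff, moderators = mods)
    expect_lt(abs(mt$q_t - (mt$q_m + mt$q_e)), 1e-8)
    expect_gte(mt$q_m, 0)
    expect_gte(mt$q_e, 0)
    # total Q is the intercept-only Cochran Q on the same effects
    expect_equal(mt$q_t, cochran_q(eff)$q, tolerance = 1e-8)
  }
})

test_that("meta-regression coefficients agree with metafor", {
  set.seed(44)
  eff <- sim_effects(60, mu = 0, tau2 = 0.05)
  eff$temperature_c <- runif(60, 18, 36)
  eff$rr <- eff$rr + 0.02 * eff$temperature_c
  mt <- meta_regression(eff, moderators = "temperature_c")
  fit <- metafor::rma(yi = eff$rr, vi = eff$v, mods = ~ eff$temperature_c,
                      method = "REML", control = list(maxiter = 500))
  expect_equal(mt$coefficients$estimate, as.numeric(fit$b), tolerance = 1e-5)
  expect_equal(mt$coefficients$se, fit$se, tolerance = 1e-5)
  expect_equal(mt$tau2, fit$tau2, tolerance = 1e-5)
})

test_that("the I-squared gate opens strictly above the threshold", {
  mk <- function(i2) structure(list(i2 = i2), class = "pooled_result")
  expect_false(moderator_gate(mk(0)))
  expect_true(moderator_gate(mk(99.9)))
  expect_false(moderator_gate(mk(75))) # boundary: strict inequality
  expect_true(moderator_gate(mk(75.01)))
  expect_false(moderator_gate(mk(80), threshold = 90))
})

test_that("subgroup pooling partitions by trait and ignores ordering", {
  eff <- compute_effects(pair_control_treatment(toy_observations()))
  by_trait <- subgroup_pool(eff)
  expect_named(by_trait, c("egg", "fecundity"))
  expect_equal(by_trait$egg$k, sum(eff$variable == "egg"))

  single <- eff[eff$variable == "egg", ]
  expect_equal(subgroup_pool(single)$egg$rr_plus,
               random_effects_pool(single)$rr_plus)

  set.seed(45)
  shuffled <- eff[sample(nrow(eff)), ]
  by2 <- subgroup_pool(shuffled)
  expect_equal(by2$egg$rr_plus, by_trait$egg$rr_plus)
  expect_equal(by2$fecundity$rr_plus, by_trait$fecundity$rr_plus)
})

test_that("permuted moderators reject at the nominal rate", {
  # homogeneous effects, null moderator: Qm ~ chi-square(1)
  set.seed(46)
  rej <- replicate(2000, {
    v <- runif(12, 0.05, 0.2)
    eff <- data.frame(rr = rnorm(12, 0.3, sqrt(v)), v = v,
                      temperature_c = sample(c(18, 21, 24, 27, 30, 33),
                                             12, replace = TRUE))
    meta_regression(eff, tau2 = 0, moderators = "temperature_c")$p_value < 0.05
  })
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("temperature profile recovers a quadratic optimum", {
  # exact quadratic with vertex at 27 C, symmetric design
  temps <- c(18, 21, 24, 27, 30, 33, 36)
  eff <- data.frame(rr = -0.01 * (temps - 27)^2, v = rep(0.02, 7),
                    temperature_c = temps)
  pr <- temperature_profile(eff, direction = "max")
  expect_equal(pr$optimum_c, 27, tolerance = 1e-6)
  expect_false(pr$monotone)
  expect_equal(nrow(pr$by_temperature), 7)

  # perfectly linear: vertex leaves the range, best endpoint + flag
  lin <- data.frame(rr = -0.05 * temps, v = rep(0.02, 7),
                    temperature_c = temps)
  pl <- temperature_profile(lin, direction = "max")
  expect_true(pl$monotone)
  expect_equal(pl$optimum_c, 18)
  pl2 <- temperature_profile(lin, direction = "min")
  expect_true(pl2$monotone)
  expect_equal(pl2$optimum_c, 36)

  expect_error(temperature_profile(
    data.frame(rr = c(0, 0.5, 1), v = rep(0.1, 3),
               temperature_c = c(18, 18, 24))), "3 distinct")
})

test_that("per-temperature pooled rows match direct pooling", {
  ds <- synthesize_dataset(synthetic_config(n_studies = 4, traits = "egg"),
                           seed = 47)
  eff <- compute_effects(pair_control_treatment(resolve_sd(ds$observations)))
  pr <- temperature_profile(eff)
  for (i in seq_len(nrow(pr$by_temperature))) {
    tt <- pr$by_temperature$temperature_c[i]
    sub <- eff[eff$temperature_c == tt, ]
    direct <- if (nrow(sub) >= 2) random_effects_pool(sub)
              else fixed_effects_pool(sub)
    expect_equal(pr$by_temperature$rr[i], direct$rr_plus)
  }
})
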