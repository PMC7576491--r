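test_that("parameter draws honor kind, floor and closed-form moments", {
  expect_equal(sample_parameter(param_spec("constant", 140), 3),
               c(140, 140, 140))

  set.seed(5)
  x <- sample_parameter(param_spec("lognormal", 2.7, 0.4), 1e5)
  expect_equal(mean(x), exp(2.7 + 0.4^2 / 2), tolerance = 0.02)

  set.seed(6)
  y <- sample_parameter(param_spec("normal", 35.1, 15.0), 1e5)
  expect_gte(min(y), 0)
  # truncated-moment oracle by numerical quadrature
  trunc_mean <- integrate(function(v) v * dnorm(v, 35.1, 15), 0, Inf)$value /
    (1 - pnorm(0, 35.1, 15))
  expect_equal(mean(y), trunc_mean, tolerance = 0.02)

  expect_error(param_spec("normal", 1), "p2")
  expect_error(sample_parameter(list(kind = "normal"), 5), "param_spec")
})

test_that("simulations are seed-reproducible and order-stable", {
  spec <- ilcr_scenario("heating", 500, seed = 99)
  a <- run_ilcr_simulation(spec)
  b <- run_ilcr_simulation(spec)
  expect_identical(a$ilcr, b$ilcr)
  expect_identical(a$c, b$c)
  c_ <- run_ilcr_simulation(ilcr_scenario("heating", 500, seed = 100))
  expect_false(identical(a$ilcr, c_$ilcr))
})

test_that("degenerate constant scenario collapses to the deterministic risk", {
  spec <- ilcr_scenario("heating", 50, seed = 1,
                        bapeq = param_spec("constant", 1),
                        ir = param_spec("constant", 1),
                        bw = param_spec("constant", 1),
                        ef = 1, ed = 1, at = 1, cf = 1, sf = 1)
  sim <- run_ilcr_simulation(spec)
  expect_true(all(sim$ilcr == 1))
})

test_that("raising EF rescales every draw by the exposure-frequency ratio", {
  a <- run_ilcr_simulation(ilcr_scenario("heating", 1000, seed = 3))
  b <- run_ilcr_simulation(ilcr_scenario("heating", 1000, seed = 3,
                                         ef = 220))
  expect_equal(b$ilcr, a$ilcr * 220 / 140)
})

test_that("mean simulated risk converges to the independence closed form", {
  # E[ILCR] = SF*CF*EF*ED/AT * E[C] * E[IR] * E[1/BW], each factor by
  # closed form or numerical quadrature over the truncated densities
  e_c <- exp(2.7 + 0.4^2 / 2)
  z <- 1 - pnorm(0, 35.1, 15)
  e_ir <- integrate(function(v) v * dnorm(v, 35.1, 15), 0, Inf)$value / z
  zb <- 1 - pnorm(0, 29.9, 5.6)
  e_invbw <- integrate(function(v) dnorm(v, 29.9, 5.6) / v, 0, Inf)$value / zb
  closed <- 3.14 * 1e-6 * 140 * 10 / 25500 * e_c * e_ir * e_invbw

  sim <- run_ilcr_simulation(ilcr_scenario("heating", 1e5, seed = 8))
  expect_lt(abs(sim$mean - closed) / closed, 0.02)
})

test_that("exceedance probability equals the sort-and-count oracle", {
  sim <- run_ilcr_simulation(ilcr_scenario("heating", 2000, seed = 21))
  thr <- 1e-6
  oracle <- sum(sort(sim$ilcr) > thr) / length(sim$ilcr)
  expect_equal(exceedance_probability(sim, thr), oracle)

  flat <- run_ilcr_simulation(ilcr_scenario("heating", 10, seed = 1,
                                            bapeq = param_spec("constant", 1),
                                            ir = param_spec("constant", 1),
                                            bw = param_spec("constant", 1),
                                            ef = 1, ed = 1, at = 1, cf = 1,
                                            sf = 1))
  expect_equal(exceedance_probability(flat, 1), 0)  # strict inequality
  expect_equal(mean(c(0.5, 1.5) > 1), 0.5)
})

test_that("distribution fitting selects the generating family", {
  set.seed(17)
  x <- exp(rnorm(1e4, 2.7, 0.4))
  fit <- fit_exposure_distribution(x)
  expect_identical(fit$selected, "lognormal")
  # maximum-likelihood recovery oracle with CLT tolerance 3*sd/sqrt(n)
  expect_lt(abs(coef(fit)[["log_mean"]] - 2.7), 3 * 0.4 / sqrt(1e4))
  expect_lt(abs(coef(fit)[["log_sd"]] - 0.4), 3 * 0.4 / sqrt(2e4))

  set.seed(18)
  y <- sample_parameter(param_spec("normal", 35.1, 15), 1e4)
  fity <- fit_exposure_distribution(y)
  expect_identical(fity$selected, "normal")
  expect_equal(fity$normal$mean, mean(y))

  expect_true(fit_exposure_distribution(rep(2, 20))$degenerate)
  expect_error(fit_exposure_distribution(1:5), "n >= 8")

  # nonpositive values are excluded from the log fit with a flag
  mixed <- c(-1, 0, exp(rnorm(100, 1, 0.3)))
  fitm <- fit_exposure_distribution(mixed)
  expect_equal(fitm$n_nonpositive, 2)
})

test_that("simulation reports carry the standard statistics and histogram", {
  sim <- run_ilcr_simulation(ilcr_scenario("non-heating", 1000, seed = 4))
  rep_ <- simulation_report(sim)
  expect_setequal(rep_$stats$statistic,
                  c("mean", "median", "sd", "p5", "p95", "exceedance"))
  expect_equal(sum(rep_$histogram$count), 1000)

  s <- summary(sim)
  expect_equal(s$value[s$statistic == "mean"], mean(sim$ilcr))
  expect_equal(s$value[s$statistic == "median"], median(sim$ilcr))

  # heating risk dominates non-heating on identical seeds
  h <- run_ilcr_simulation(ilcr_scenario("heating", 1000, seed = 4))
  expect_gt(h$mean, sim$mean)
})
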