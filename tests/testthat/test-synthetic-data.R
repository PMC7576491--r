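test_that("generation is deterministic in the seed", {
  a <- generate_cohort(generator_spec(seed = 7))
  b <- generate_cohort(generator_spec(seed = 7))
  expect_identical(a$participants, b$participants)
  expect_identical(as.data.frame(a$samples), as.data.frame(b$samples))
  c_ <- generate_cohort(generator_spec(seed = 8))
  expect_false(identical(as.data.frame(a$samples),
                         as.data.frame(c_$samples)))
})

test_that("default cohort matches the study group sizes", {
  coh <- default_cohort()
  p <- coh$participants
  expect_equal(nrow(p), 38)
  expect_equal(sum(p$season == "heating"), 16)
  expect_equal(sum(p$season == "non-heating"), 22)
  expect_equal(sum(p$season == "heating" & p$sex == "boy"), 7)
  expect_equal(sum(p$season == "non-heating" & p$sex == "girl"), 10)
  expect_equal(sum(coh$samples$sampler_kind == "personal"), 38)
  # one fixed indoor/outdoor pair set per season
  expect_equal(sum(coh$samples$sampler_kind == "fixed_indoor"), 4)
  # every generated record passes the IO validators (write/read round trip)
  dir <- tempfile()
  write_fixture_bundle(coh, dir)
  bundle <- read_fixture_bundle(dir)
  expect_equal(nrow(bundle$samples), nrow(coh$samples))
})

test_that("anthropometrics recover the group means at scale", {
  # CLT oracle: mean weight of simulated heating boys within 3 se of 31.7
  n <- 1e4
  spec <- generator_spec(seed = 23, n_heating_boys = n)
  p <- generate_participants(spec)
  boys <- p[p$season == "heating" & p$sex == "boy", ]
  expect_equal(nrow(boys), n)
  expect_lt(abs(mean(boys$weight_kg) - 31.7), 3 * 5.1 / sqrt(n) + 0.05)
  # spirometry back-solves to the drawn inhalation-rate distribution, whose
  # truncated mean comes from a quadrature oracle
  ir <- inhalation_rate(boys$tidal_volume_L, boys$breathing_rate_per_min)
  z <- 1 - pnorm(5, 41.2, 19.4)
  e_ir <- integrate(function(v) v * dnorm(v, 41.2, 19.4), 5, Inf)$value / z
  expect_lt(abs(mean(ir) - e_ir), 3 * 19.4 / sqrt(n))
  expect_true(all(ir > 0))
})

test_that("personal samples hit the seasonal concentration targets", {
  spec <- generator_spec(seed = 29, n_heating_boys = 500,
                         n_heating_girls = 500, n_nonheating_boys = 500,
                         n_nonheating_girls = 500)
  coh <- generate_cohort(spec)
  p <- coh$samples[coh$samples$sampler_kind == "personal", ]
  h <- p[p$season == "heating", ]
  n <- p[p$season == "non-heating", ]
  conc_h <- as.matrix(h[, REG$abbreviation])
  conc_n <- as.matrix(n[, REG$abbreviation])

  # direct-averaging oracle against the seasonal means
  expect_lt(abs(mean(rowSums(conc_h)) - 89.1) / 89.1, 0.10)
  expect_lt(abs(mean(rowSums(conc_n)) - 1.75) / 1.75, 0.10)

  # heating: HMW dominance and the coal diagnostic band
  hmw <- REG$abbreviation[REG$weight_class == "HMW"]
  expect_equal(sum(conc_h[, hmw]) / sum(conc_h), 0.56, tolerance = 0.02)
  icdp <- conc_h[, "IcdP"] / (conc_h[, "IcdP"] + conc_h[, "BghiP"])
  expect_gte(mean(abs(icdp - 0.51) <= 0.06), 0.95)
  baa <- conc_h[, "BaA"] / (conc_h[, "BaA"] + conc_h[, "Chr"])
  expect_true(all(baa > 0.4))

  # heating BaP respects mean/sd targets and the printed range clamp
  expect_true(all(h$BaP >= 3.86 & h$BaP <= 21.86))
  expect_equal(mean(h$BaP), 10.3, tolerance = 0.05)

  # non-heating: LMW profile shares and the BaP cap
  expect_true(all(n$BaP <= 0.01))
  expect_equal(mean(conc_n[, "Ant"]) / mean(rowSums(conc_n)), 0.23,
               tolerance = 0.02)
  expect_equal(mean(conc_n[, "Phe"]) / mean(rowSums(conc_n)), 0.15,
               tolerance = 0.03)

  # pump durations are always valid
  expect_true(all(p$duration_h >= 22 & p$duration_h <= 26))
})

test_that("fixed-site pairs encode the seasonal indoor/outdoor structure", {
  coh <- default_cohort()
  fixed <- coh$samples[coh$samples$sampler_kind != "personal", ]
  for (season in c("heating", "non-heating")) {
    tab <- io_ratio_table(fixed[fixed$season == season, ], REG)
    if (season == "heating") {
      not_acy <- tab$congener != "Acy"
      expect_true(all(tab$call[not_acy] == "indoor_source"))
      expect_true(tab$ratio[tab$congener == "Acy"] <= 1)
    } else {
      expect_true(all(tab$call == "outdoor_source"))
    }
  }
})

test_that("BaPeq parameter recovery matches the quadrature ground truth", {
  spec <- generator_spec(seed = 37, n_heating_boys = 5000,
                         n_heating_girls = 5000)
  participants <- generate_participants(spec)
  samples <- generate_personal_samples(spec, participants)
  h <- samples[samples$season == "heating", ]
  bq <- bapeq_by_sample(h, REG)
  fit <- fit_exposure_distribution(bq)
  expect_identical(fit$selected, "lognormal")

  gt <- generate_cohort(spec)$ground_truth
  glm <- gt$value[gt$parameter == "bapeq_log_mean" & gt$season == "heating"]
  gls <- gt$value[gt$parameter == "bapeq_log_sd" & gt$season == "heating"]
  n <- length(bq)
  expect_lt(abs(coef(fit)[["log_mean"]] - glm), 3 * gls / sqrt(n))
  expect_lt(abs(coef(fit)[["log_sd"]] - gls), 3 * gls / sqrt(2 * n))
})

test_that("fixture bundles round-trip and regenerate identically", {
  coh <- default_cohort()
  dir <- tempfile()
  paths <- write_fixture_bundle(coh, dir)
  expect_true(all(file.exists(paths)))
  # collision without the overwrite flag is refused
  expect_error(write_fixture_bundle(coh, dir), "overwrite")

  bundle <- read_fixture_bundle(dir)
  expect_equal(nrow(bundle$samples), nrow(coh$samples))
  gt_seed <- bundle$ground_truth$value[
    bundle$ground_truth$parameter == "seed"]
  expect_equal(gt_seed, coh$spec$seed)

  # regenerating from the recorded config reproduces the bundle
  coh2 <- generate_cohort(bundle$spec)
  dir2 <- tempfile()
  write_fixture_bundle(coh2, dir2)
  expect_identical(readLines(file.path(dir, "samples.csv")),
                   readLines(file.path(dir2, "samples.csv")))
  expect_identical(readLines(file.path(dir, "participants.csv")),
                   readLines(file.path(dir2, "participants.csv")))
})

test_that("a generated bundle drives the whole pipeline without errors", {
  coh <- default_cohort()
  samples <- filter_valid_personal(coh$samples)
  sm_h <- season_summary(samples, "heating", REG)
  sm_n <- season_summary(samples, "non-heating", REG)
  expect_gt(season_ratio(sm_h, sm_n, "sigma_pah"), 1)
  sc <- source_scatter(samples)
  expect_equal(nrow(sc), nrow(samples))
  personal <- samples[samples$sampler_kind == "personal", ]
  bq <- setNames(bapeq_by_sample(personal, REG), personal$participant_id)
  risk <- per_participant_risk(coh$participants, bq)
  expect_true(all(is.finite(risk$ilcr)))
  sim <- run_ilcr_simulation(ilcr_scenario("heating", 1000, seed = 1))
  expect_s3_class(summary(sim), "data.frame")
})
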