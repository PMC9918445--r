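test_that("trend projection is geometric", {
  expect_equal(project_control_incidence(1, 0.045, 1), 1.045)
  expect_equal(project_control_incidence(100, 0.045, 10), 155.2969,
               tolerance = 1e-6)
  expect_equal(project_control_incidence(42, 0, 25), 42)
  expect_equal(project_control_incidence(10, 0.045, 0:2),
               10 * 1.045^(0:2))
  expect_error(project_control_incidence(10, -1.2, 5), "exceed -1")
  expect_error(project_control_incidence(-1, 0.045, 5), "non-negative")
})

test_that("overdiagnosis proportion is the excess ratio", {
  expect_equal(overdiagnosis_proportion(931, 856), (931 / 856 - 1) * 100)
  expect_equal(round(overdiagnosis_proportion(931, 856), 2), 8.76)
  expect_equal(round(overdiagnosis_proportion(528, 483), 2), 9.32)
  expect_equal(overdiagnosis_proportion(500, 500), 0)
  expect_error(overdiagnosis_proportion(10, 0), "positive")
  expect_error(overdiagnosis_proportion(10, -5), "positive")
})

test_that("twin prediction components sum to S(t) and collapse without screening", {
  m <- od_model("progressive_3state"); mt0 <- mortality_schedule(0)
  d <- small_design()
  r0 <- rate_parameters(lambda1 = 0.0015, lambda2 = 0.4, sens_crc = 1e-12)
  tw <- predict_screened_twin(m, r0, mt0, d, cohort_size = 1e5, followup = 7)
  expect_equal(tw$S_t, sum(tw$components), tolerance = 1e-6)
  expect_true(all(tw$components >= 0))
  # with an inert test the twin equals the no-screening expectation
  expect_equal(tw$S_t, tw$U_model, tolerance = 1e-9 * tw$U_model)
  expect_equal(overdiagnosis_proportion(tw$S_t, tw$U_model), 0,
               tolerance = 1e-7)
  expect_error(predict_screened_twin(m, r0, mt0, d, 1e5, followup = 3),
               "shorter than the last screen")
})

test_that("twin predictions reproduce the published trial totals", {
  mt <- mortality_schedule(0.01)
  m <- od_model("progressive_3state")
  uk <- predict_screened_twin(
    m, rate_parameters(lambda1 = 0.00147, lambda2 = 0.3475,
                       sens_crc = 0.534),
    mt, rct_design("nottingham"), cohort_size = 74998, followup = 8.5)
  expect_equal(uk$S_t, 931, tolerance = 0.05)
  fu <- predict_screened_twin(
    m, rate_parameters(lambda1 = 0.00172, lambda2 = 0.4433,
                       sens_crc = 0.5205),
    mt, rct_design("funen"), cohort_size = 30966, followup = 10)
  expect_equal(fu$S_t, 528, tolerance = 0.05)
})

test_that("analytic twin S(t) agrees with simulation across scenarios", {
  mt <- mortality_schedule(0.01)
  scen <- list(
    list(fn = 0.05, sens = 0.8, p = 0.7, seed = 1),
    list(fn = 0.00, sens = 0.5, p = 0.6, seed = 2),
    list(fn = 0.10, sens = 0.9, p = 0.8, seed = 3),
    list(fn = 0.05, sens = 0.65, p = 0.5, seed = 4),
    list(fn = 0.02, sens = 0.8, p = 0.9, seed = 5))
  for (sc in scen) {
    m <- od_model("overdiag_embedded", nonprog_fraction = sc$fn)
    r <- rate_parameters(lambda1 = 0.0015, lambda2 = 0.4,
                         sens_crc = sc$sens)
    d <- screening_design(c(0, 2, 4), 7, 2e5, sc$p, lead_time = 20)
    tw <- predict_screened_twin(m, r, mt, d, cohort_size = 2e5, followup = 7)
    sim <- simulate_cohort(simulation_config(2e5, r, mt, d, model = m,
                                             seed = sc$seed))
    expect_lt(abs(sim$truth$screened_counted - tw$S_t) / sqrt(tw$S_t), 3.5)
  }
})

test_that("competing-risk adjustment is the identity at zero hazard and
           monotone in the hazard", {
  m <- od_model("progressive_3state"); r <- base_rates()
  d <- small_design()
  tw0 <- predict_screened_twin(m, r, mortality_schedule(0), d, 1e5, 7)
  adj0 <- competing_risk_adjustment(tw0)
  expect_equal(adj0$S_t, tw0$S_t)
  expect_false(adj0$competing_risk_adjusted)

  pcts <- vapply(c(0.005, 0.01, 0.02, 0.04), function(delta) {
    mt <- mortality_schedule(delta)
    tw <- predict_screened_twin(m, r, mt, d, 1e5, 7)
    adj <- competing_risk_adjustment(tw, mt)
    expect_gt(adj$S_t, tw$S_t)   # adjustment raises the percentage
    overdiagnosis_proportion(adj$S_t, tw$U_model)
  }, numeric(1))
  expect_true(all(diff(pcts) > 0))

  # simulation oracle: with a positive hazard some screen-detected subjects
  # die before their latent clinical date (overdiagnosed by competing death)
  mo <- od_model("overdiag_embedded")  # no non-progressive disease
  cfg <- simulation_config(2e5, r, mortality_schedule(0.02), d, model = mo,
                           seed = 31)
  expect_gt(simulate_cohort(cfg)$truth$n_overdiagnosed, 0)
  cfg0 <- simulation_config(2e5, r, mortality_schedule(0), d, model = mo,
                            seed = 31)
  expect_identical(simulate_cohort(cfg0)$truth$n_overdiagnosed, 0L)
})

test_that("posterior uncertainty propagates to the overdiagnosis interval", {
  m <- od_model("progressive_3state"); mt <- mortality_schedule(0.01)
  d <- small_design()
  set.seed(8)
  n <- 200
  draws <- cbind(lambda1 = 0.0015 * exp(rnorm(n, 0, 0.03)),
                 lambda2 = 0.4 * exp(rnorm(n, 0, 0.05)),
                 sens_crc = plogis(qlogis(0.8) + rnorm(n, 0, 0.1)))
  oi <- overdiagnosis_interval(draws, U_t = 1100, design = d, mort = mt,
                               cohort_size = 1e5, followup = 7)
  expect_true(oi$interval[1] < oi$interval[2])

  # degenerate posterior: zero-width interval at the point estimate
  dg <- draws[rep(1, 120), ]
  oid <- overdiagnosis_interval(dg, 1100, d, mt, cohort_size = 1e5,
                                followup = 7)
  expect_equal(unname(diff(oid$interval)), 0)
  r1 <- do.call(rate_parameters, as.list(draws[1, ]))
  tw1 <- predict_screened_twin(m, r1, mt, d, 1e5, 7)
  expect_equal(unname(oid$interval[1]),
               overdiagnosis_proportion(tw1$S_t, 1100), tolerance = 1e-9)

  # a wider posterior gives a wider interval
  ctr <- apply(draws, 2, median)
  wide <- sweep(sweep(draws, 2, ctr, "-"), 2, c(2, 2, 2), "*")
  wide <- sweep(wide, 2, ctr, "+")
  wide[, "sens_crc"] <- pmin(pmax(wide[, "sens_crc"], 0.01), 0.99)
  oiw <- overdiagnosis_interval(wide, 1100, d, mt, cohort_size = 1e5,
                                followup = 7)
  expect_gt(diff(oiw$interval), diff(oi$interval))

  # report assembly: interval brackets the point estimate
  fitlike <- predict_screened_twin(m, do.call(rate_parameters,
                                              as.list(ctr)), mt, d, 1e5, 7)
  rep <- overdiagnosis(fitlike, 1100, draws = draws)
  expect_true(rep$interval[1] <= rep$percentage + 1e-6 &&
              rep$percentage <= rep$interval[2] + 1e-6)
  expect_named(rep$flags, c("includes_HGD", "includes_adenoma_removal",
                            "competing_risk_adjusted"))
})

test_that("control imputation inverts the no-screening expectation", {
  m <- od_model("progressive_3state"); mt <- mortality_schedule(0.01)
  d <- small_design()
  r <- base_rates()
  # forward: expected control count at a known lower control incidence
  r_ctl <- rate_parameters(lambda1 = 0.0012, lambda2 = 0.4, sens_crc = 0.8)
  U <- odtwin:::control_expectation(m, r_ctl, mt, d, 1e5, 7)
  lam <- implied_control_incidence(U, r, mt, d, 1e5, 7)
  expect_equal(lam, 0.0012, tolerance = 1e-6)
  # trend imputation path
  ci <- control_imputation(baseline = 100, growth_rate = 0.045, years = 1:10)
  expect_equal(ci$U_t, sum(100 * 1.045^(1:10)), tolerance = 1e-12)
})

test_that("adenoma modelling adds the polypectomy offset", {
  mt <- mortality_schedule(0.01)
  d <- rct_design("taiwan")
  # matched chains: equal equilibrium preclinical inflow, progression and
  # sensitivity; removing adenomas must not lose predicted-cancer mass
  l1b <- 0.0839
  r3 <- rate_parameters(lambda1 = 0.00141, lambda2 = 0.386, sens_crc = 0.8)
  ra <- rate_parameters(lambda1a = 0.00141 * (l1b + 0.01) / l1b,
                        lambda1b = l1b, lambda2 = 0.386, sens_crc = 0.8,
                        sens_adenoma = 0.45)
  S3 <- predict_screened_twin(od_model("progressive_3state"), r3, mt, d,
                              1e6, 11)$S_t
  Sa <- predict_screened_twin(od_model("adenoma_4state"), ra, mt, d,
                              1e6, 11)$S_t
  expect_gte(Sa, S3)

  # sweep: a single-point grid reproduces the point analysis exactly
  ra_tw <- taiwan_rates(adenoma = TRUE)
  sw1 <- adenoma_sensitivity_sweep(ra_tw, mt, d, grid = 0.6348,
                                   cohort_size = 1e6, followup = 11)
  tw <- predict_screened_twin(od_model("adenoma_4state"), ra_tw, mt, d,
                              1e6, 11)
  expect_equal(sw1$S_t, tw$S_t, tolerance = 1e-12)
  expect_equal(sw1$percentage,
               overdiagnosis_proportion(tw$S_t, sw1$U_t), tolerance = 1e-12)

  # dense grid varies smoothly and monotonically
  sw <- adenoma_sensitivity_sweep(ra_tw, mt, d,
                                  grid = seq(0.2, 0.63, by = 0.025),
                                  cohort_size = 1e6, followup = 11)
  expect_true(all(diff(sw$percentage) > 0))
  expect_lt(max(abs(diff(diff(sw$percentage)))), 0.05)

  expect_error(adenoma_sensitivity_sweep(ra_tw, mt, d, grid = c(0.5, 1.2)),
               "inside")
  expect_error(adenoma_sensitivity_sweep(r3, mt, d, grid = 0.5,
                                         model = od_model("progressive_3state")),
               "adenoma")
})

test_that("offset bookkeeping matches the individual-level oracle", {
  mt <- mortality_schedule(0.01)
  d <- rct_design("taiwan"); d$cohort_size <- 2e5
  ma <- od_model("adenoma_4state")
  ra <- taiwan_rates(adenoma = TRUE)
  sim <- simulate_cohort(simulation_config(2e5, ra, mt, d, model = ma,
                                           seed = 9))
  pr <- mode_probabilities(ma, ra, mt, d)
  np <- sim$truth$n_participant
  expect_lt(abs(sim$truth$n_adenoma_removed - np * pr$adenoma_removed) /
              sqrt(np * pr$adenoma_removed), 3.5)
  expect_lt(abs(sim$truth$n_adenoma_would_pcdp - np * pr$adenoma_offset) /
              sqrt(np * pr$adenoma_offset), 3.5)
})
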