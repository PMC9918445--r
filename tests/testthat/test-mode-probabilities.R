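test_that("fate partitions are exhaustive within each stratum", {
  mt <- mortality_schedule(0.012)
  cases <- list(
    list(m = od_model("progressive_3state"), r = base_rates(),
         d = small_design()),
    list(m = od_model("overdiag_embedded", nonprog_fraction = 0.08),
         r = base_rates(), d = small_design(confirmation = 0.85)),
    list(m = od_model("adenoma_4state"),
         r = rate_parameters(lambda1a = 0.00149, lambda1b = 0.0839,
                             lambda2 = 0.53, sens_crc = 0.8,
                             sens_adenoma = 0.6),
         d = small_design(confirmation = 0.9)))
  for (cs in cases) {
    pr <- mode_probabilities(cs$m, cs$r, mt, cs$d)
    expect_equal(sum(pr$participant), 1, tolerance = 1e-9)
    expect_equal(sum(pr$refuser), 1, tolerance = 1e-9)
    expect_true(all(pr$participant >= 0 & pr$participant <= 1))
    expect_true(all(pr$refuser >= 0 & pr$refuser <= 1))
  }
})

test_that("degenerate designs and sensitivities behave as limits", {
  m <- od_model("progressive_3state")
  mt0 <- mortality_schedule(0)
  # vanishing sensitivity: no screen detections, cancers flow to
  # interval/clinical modes
  r0 <- rate_parameters(lambda1 = 0.0015, lambda2 = 0.4, sens_crc = 1e-12)
  pr0 <- mode_probabilities(m, r0, mt0, small_design())
  expect_lt(pr0$participant[["prevalent_crc"]], 1e-12)
  expect_lt(pr0$participant[["repeat_crc"]], 1e-12)
  expect_gt(pr0$participant[["interval_crc"]], 0)
  # with no screening effect, participant and refuser cancer totals agree
  part_total <- sum(pr0$participant[c("interval_crc",
                                      "post_program_clinical")])
  expect_equal(part_total, pr0$refuser[["refuser_crc"]], tolerance = 1e-9)

  # a single screen with no follow-up beyond it yields no interval cancers
  d1 <- screening_design(screen_times = 2, followup = 2, cohort_size = 100,
                         participation = 0.5)
  pr1 <- mode_probabilities(m, base_rates(), mt0, d1)
  expect_equal(pr1$participant[["interval_crc"]], 0)
})

test_that("higher sensitivity shifts cancers from interval to screen detection", {
  m <- od_model("progressive_3state")
  mt <- mortality_schedule(0.01)
  d <- small_design()
  sens <- c(0.2, 0.5, 0.8)
  prev <- interval <- numeric(3)
  for (i in seq_along(sens)) {
    r <- rate_parameters(lambda1 = 0.0015, lambda2 = 0.4, sens_crc = sens[i])
    pr <- mode_probabilities(m, r, mt, d)
    prev[i] <- pr$participant[["prevalent_crc"]]
    interval[i] <- pr$participant[["interval_crc"]]
  }
  expect_true(all(diff(prev) > 0))
  expect_true(all(diff(interval) < 0))
})

test_that("the embedded variant reduces to the progressive chain when the
           non-progressive fraction is zero", {
  r <- base_rates(); mt <- mortality_schedule(0.01); d <- small_design()
  pr3 <- mode_probabilities(od_model("progressive_3state"), r, mt, d)
  pro <- mode_probabilities(od_model("overdiag_embedded"), r, mt, d)
  expect_equal(pr3$participant, pro$participant, tolerance = 1e-12)
  expect_equal(pr3$refuser, pro$refuser, tolerance = 1e-12)
})

test_that("analytic mode probabilities match simulated frequencies", {
  m <- od_model("overdiag_embedded", nonprog_fraction = 0.05)
  r <- base_rates(); mt <- mortality_schedule(0.01)
  d <- small_design(confirmation = 0.9)
  pr <- mode_probabilities(m, r, mt, d)
  sim <- simulate_cohort(simulation_config(1e5, r, mt, d, model = m,
                                           seed = 71))
  ns <- c(sim$truth$n_participant, 1e5 - sim$truth$n_participant)
  e <- expected_mode_counts(pr, ns[1], ns[2])
  o <- sim$counts$observed[match(names(e), sim$counts$mode)]
  z <- (o - e) / sqrt(e)
  expect_true(all(abs(z) < 3.5))
})

test_that("log-likelihood has multinomial behaviour", {
  m <- od_model("progressive_3state")
  r <- base_rates(); mt <- mortality_schedule(0.01); d <- small_design()
  pr <- mode_probabilities(m, r, mt, d)
  e <- expected_mode_counts(pr, 70000, 30000)

  # all-zero counts give zero log-likelihood
  zero <- detection_mode_counts(
    prevalent_normal = 0, prevalent_crc = 0, interval_crc = 0,
    repeat_normal = 0, repeat_crc = 0, refuser_normal = 0, refuser_crc = 0)
  expect_identical(log_likelihood(zero, pr), 0)

  # counts equal to their expectation maximise the likelihood over rates
  cnt <- do.call(detection_mode_counts, as.list(round(e)))
  ll_at <- function(rr) log_likelihood(cnt, mode_probabilities(m, rr, mt, d))
  ll0 <- ll_at(r)
  for (f in c(0.5, 0.7, 1.5)) {
    expect_gt(ll0, ll_at(rate_parameters(lambda1 = 0.0015 * f,
                                         lambda2 = 0.4, sens_crc = 0.8)))
    expect_gt(ll0, ll_at(rate_parameters(lambda1 = 0.0015,
                                         lambda2 = 0.4 * f, sens_crc = 0.8)))
    expect_gt(ll0, ll_at(rate_parameters(lambda1 = 0.0015, lambda2 = 0.4,
                                         sens_crc = min(0.8 * f, 0.99))))
  }

  # a positive count on a zero-probability mode warns and returns -Inf
  pr_conf <- mode_probabilities(m, r, mt, d)  # confirmation = 1: unconf = 0
  cnt_bad <- detection_mode_counts(
    prevalent_normal = 1000, prevalent_crc = 5,
    positive_unconfirmed_first = 3, refuser_normal = 500, refuser_crc = 2)
  expect_warning(llb <- log_likelihood(cnt_bad, pr_conf), "zero-probability")
  expect_identical(llb, -Inf)
})

test_that("simulated counts prefer the generating parameters", {
  m <- od_model("progressive_3state")
  r <- base_rates(); mt <- mortality_schedule(0.01); d <- small_design()
  sim <- simulate_cohort(simulation_config(2e5, r, mt, d, model = m,
                                           seed = 5))
  ll <- function(rr) log_likelihood(sim$counts,
                                    mode_probabilities(m, rr, mt, d))
  ll_truth <- ll(r)
  expect_gt(ll_truth, ll(rate_parameters(lambda1 = 0.0015 * 1.5,
                                         lambda2 = 0.4, sens_crc = 0.8)))
  expect_gt(ll_truth, ll(rate_parameters(lambda1 = 0.0015 * 0.5,
                                         lambda2 = 0.4, sens_crc = 0.8)))
  expect_gt(ll_truth, ll(rate_parameters(lambda1 = 0.0015,
                                         lambda2 = 0.6, sens_crc = 0.4)))
})
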