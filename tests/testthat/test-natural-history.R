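test_that("intensity matrix encodes the transition graph and mortality", {
  m <- od_model("progressive_3state")
  r <- rate_parameters(lambda1 = 0.00141, lambda2 = 0.3860, sens_crc = 0.8)
  Q <- intensity_matrix(m, r, mortality_schedule(0))
  expect_equal(Q["Normal", "PCDP"], 0.00141)
  expect_equal(Q["PCDP", "Clinical"], 0.3860)
  expect_equal(unname(Q["Clinical", ]), rep(0, 4))
  expect_equal(unname(rowSums(Q)), rep(0, 4))

  # a degenerate all-zero chain is the zero matrix
  Q0 <- intensity_matrix(m, list(lambda1 = 0, lambda2 = 0),
                         mortality_schedule(0))
  expect_true(all(Q0 == 0))

  # every alive state feeds Death at the other-cause hazard
  mo <- od_model("overdiag_embedded", nonprog_fraction = 0.1)
  Qd <- intensity_matrix(mo, r, mortality_schedule(0.01))
  alive <- c("Normal", "PCDP", "NonprogPCDP")
  expect_equal(unname(Qd[alive, "Death"]), rep(0.01, 3))
  # non-progressive PCDP has no outgoing transition except Death
  expect_equal(unname(Qd["NonprogPCDP", c("PCDP", "Clinical")]), c(0, 0))

  expect_error(intensity_matrix(m, list(lambda1 = -1, lambda2 = 1),
                                mortality_schedule(0)), "negative")
  expect_error(
    intensity_matrix(od_model("adenoma_4state"), r, mortality_schedule(0)),
    "lambda1a")
})

test_that("closed-form transition probabilities match the matrix exponential", {
  grid <- expand.grid(l1 = c(0.0005, 0.0015, 0.05), l2 = c(0.1, 0.4, 1.2),
                      delta = c(0, 0.01, 0.05), t = c(0.5, 2, 10))
  for (variant in c("progressive_3state", "overdiag_embedded")) {
    m <- od_model(variant, nonprog_fraction =
                    if (variant == "overdiag_embedded") 0.07 else 0)
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      r <- rate_parameters(lambda1 = g$l1, lambda2 = g$l2, sens_crc = 0.5)
      P <- transition_probability(m, r, mortality_schedule(g$delta), g$t)
      expect_lt(max(abs(P - expm_oracle(m, r, g$delta, g$t))), 1e-10)
      expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
      expect_true(all(P >= 0 & P <= 1))
    }
  }
  # adenoma chain: matrix-exponential route, still row-stochastic
  ma <- od_model("adenoma_overdiag", nonprog_fraction = 0.05)
  ra <- rate_parameters(lambda1a = 0.00149, lambda1b = 0.0839,
                        lambda2 = 0.53, sens_crc = 0.8, sens_adenoma = 0.6)
  Pa <- transition_probability(ma, ra, mortality_schedule(0.01), 6)
  expect_equal(unname(rowSums(Pa)), rep(1, 6), tolerance = 1e-10)
})

test_that("transition probability basics: identity, Chapman-Kolmogorov, limits", {
  m <- od_model("progressive_3state")
  r <- rate_parameters(lambda1 = 0.00141, lambda2 = 0.3860, sens_crc = 0.8)
  mt0 <- mortality_schedule(0)

  expect_equal(unname(transition_probability(m, r, mt0, 0)), diag(4),
               ignore_attr = TRUE)

  P2 <- transition_probability(m, r, mt0, 2)
  expect_equal(P2["Normal", "PCDP"], 0.0019618, tolerance = 1e-4)

  # Chapman-Kolmogorov in the time-homogeneous case
  mt <- mortality_schedule(0.02)
  Ps <- transition_probability(m, r, mt, 1.3)
  Pt <- transition_probability(m, r, mt, 3.2)
  Pst <- transition_probability(m, r, mt, 4.5)
  expect_lt(max(abs(Ps %*% Pt - Pst)), 1e-9)

  # equal progression rates fall through to the analytic limit, continuously
  req <- rate_parameters(lambda1 = 0.5, lambda2 = 0.5, sens_crc = 0.5)
  Peq <- transition_probability(m, req, mt0, 2)
  expect_equal(Peq["Normal", "PCDP"], 0.5 * 2 * exp(-1), tolerance = 1e-12)
  rnear <- rate_parameters(lambda1 = 0.5, lambda2 = 0.5 * (1 + 1e-9),
                           sens_crc = 0.5)
  Pnear <- transition_probability(m, rnear, mt0, 2)
  expect_equal(Peq["Normal", "PCDP"], Pnear["Normal", "PCDP"],
               tolerance = 1e-8)

  # sensitivity lives in the screening layer only
  r2 <- rate_parameters(lambda1 = 0.00141, lambda2 = 0.3860, sens_crc = 0.1)
  expect_identical(unname(transition_probability(m, r2, mt0, 5)),
                   unname(transition_probability(m, r, mt0, 5)))

  # with no other-cause hazard no alive state ever reaches Death
  P8 <- transition_probability(m, r, mt0, 8)
  expect_true(all(P8[rownames(P8) != "Death", "Death"] == 0))

  expect_error(transition_probability(m, r, mt0, -1), "non-negative")
})

test_that("piecewise mortality schedules are handled exactly and strictly", {
  m <- od_model("progressive_3state")
  r <- rate_parameters(lambda1 = 0.002, lambda2 = 0.4, sens_crc = 0.5)
  mt <- mortality_schedule(c(0.005, 0.02), breaks = c(0, 3, 10))
  P <- transition_probability(m, r, mt, 7)
  oracle <- expm_oracle(m, r, 0.005, 3) %*% expm_oracle(m, r, 0.02, 4)
  expect_lt(max(abs(P - oracle)), 1e-10)
  expect_error(hazard_at(mt, 12), "outside")
  expect_error(mortality_schedule(c(0.01, 0.02), breaks = c(0, 1)),
               "increasing")
  expect_error(mortality_schedule(-0.1), "non-negative")
})

test_that("mean sojourn time is the reciprocal progression rate", {
  expect_equal(round(mean_sojourn_time(0.3860), 2), 2.59)
  expect_equal(round(mean_sojourn_time(0.3475), 2), 2.88)
  expect_equal(round(mean_sojourn_time(0.4433), 2), 2.26)
  expect_equal(mean_sojourn_time(1.0), 1.0)
  # an interval of rates maps to a reversed interval of sojourn times
  expect_equal(round(mean_sojourn_time(c(0.3726, 0.3997)), 2), c(2.50, 2.68))
  expect_equal(mean_sojourn_time(base_rates()), 1 / 0.40)
  expect_error(mean_sojourn_time(0), "positive")
  expect_error(mean_sojourn_time(-2), "positive")
})
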