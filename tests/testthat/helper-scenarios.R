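# Shared small scenarios for the test suite.

base_rates <- function() rate_parameters(lambda1 = 0.0015, lambda2 = 0.40,
                                         sens_crc = 0.80)

taiwan_truth <- c(lambda1 = 0.00141, lambda2 = 0.386, sens_crc = 0.80)

# A compact biennial programme used in many unit tests.
small_design <- function(...) screening_design(
  screen_times = c(0, 2, 4), followup = 7, cohort_size = 1e5,
  participation = 0.7, lead_time = 20, ...)

# The well-identified annual design used for the parameter-recovery studies.
recovery_design <- function(n = 2e6) screening_design(
  screen_times = 0:4, followup = 7, cohort_size = n,
  participation = 0.7, lead_time = 20)

uk_printed <- list(
  lambda1 = c(est = 0.00147, lo = 0.00136, hi = 0.00159),
  lambda2 = c(est = 0.3475, lo = 0.2437, hi = 0.4513),
  sens_crc = c(est = 0.534, lo = 0.3426, hi = 0.6955))
funen_printed <- list(
  lambda1 = c(est = 0.00172, lo = 0.00155, hi = 0.00189),
  lambda2 = c(est = 0.4433, lo = 0.3226, hi = 0.5639),
  sens_crc = c(est = 0.5205, lo = 0.3553, hi = 0.6856))

expm_oracle <- function(model, rates, delta, t) {
  Q <- intensity_matrix(model, rates, mortality_schedule(delta))
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  dimnames(P) <- dimnames(Q)
  P
}
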