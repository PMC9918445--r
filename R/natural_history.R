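#' Intensity matrix of a natural-history model
#'
#' Builds the generator matrix Q of the continuous-time Markov chain for one
#' model variant: off-diagonal entries are the transition intensities, every
#' alive (non-absorbing) state flows to Death at the other-cause hazard, and
#' each row sums to zero. In the overdiagnosis-embedded variants the
#' preclinical incidence is split as
#' `lambda1 * (1 - nonprog_fraction)` into the progressive PCDP and
#' `lambda1 * nonprog_fraction` into the non-progressive PCDP, whose only
#' outgoing transition is Death.
#'
#' @param model an [od_model()].
#' @param rates a [rate_parameters()] object (or, for degenerate experimental
#'   chains, a named list of non-negative intensities).
#' @param mort a [mortality_schedule()].
#' @param t time (years since entry) at which to evaluate a piecewise
#'   mortality hazard; irrelevant for a constant schedule.
#' @return square matrix Q with state dimnames.
#' @examples
#' m <- od_model("progressive_3state")
#' intensity_matrix(m, rate_parameters(lambda1 = 0.00141, lambda2 = 0.3860,
#'                                     sens_crc = 0.8), mortality_schedule(0))
#' @export
intensity_matrix <- function(model, rates, mort, t = 0) {
  stopifnot(inherits(model, "od_model"), inherits(mort, "mortality_schedule"))
  if (inherits(rates, "rate_parameters")) {
    validate_rates(model, rates)
  } else if (is.list(rates)) {
    if (any(unlist(rates) < 0)) stop("negative rate")
  } else stop("'rates' must be rate_parameters or a named list")
  delta <- hazard_at(mort, t)
  s <- model$states
  Q <- matrix(0, length(s), length(s), dimnames = list(s, s))
  fn <- model$nonprog_fraction
  need <- function(nm) {
    if (is.null(rates[[nm]])) stop("missing rate '", nm, "' required by ",
                                   model$variant)
    rates[[nm]]
  }
  if (is_adenoma_variant(model)) {
    Q["Normal", "Adenoma"] <- need("lambda1a")
    if (has_nonprog_state(model)) {
      Q["Adenoma", "PCDP"] <- need("lambda1b") * (1 - fn)
      Q["Adenoma", "NonprogPCDP"] <- need("lambda1b") * fn
    } else Q["Adenoma", "PCDP"] <- need("lambda1b")
    Q["PCDP", "Clinical"] <- need("lambda2")
  } else {
    if (has_nonprog_state(model)) {
      Q["Normal", "PCDP"] <- need("lambda1") * (1 - fn)
      Q["Normal", "NonprogPCDP"] <- need("lambda1") * fn
    } else Q["Normal", "PCDP"] <- need("lambda1")
    Q["PCDP", "Clinical"] <- need("lambda2")
  }
  alive <- setdiff(s, c("Clinical", "Death"))
  Q[alive, "Death"] <- Q[alive, "Death"] + delta
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# Relative rate separation below which the Normal -> Clinical entry switches
# to a second-order expansion around the equal-rate limit; the two-exponential
# difference loses precision through cancellation well before the rates are
# equal to machine precision.
.EQUAL_RATE_TOL <- 1e-4

# (1 - exp(-a t)) / a, stable as a -> 0.
.omexp_over <- function(a, t) {
  if (a == 0) return(t)
  -expm1(-a * t) / a
}

# (1 - exp(-x)) / x, stable at 0.
.phi <- function(x) if (x == 0) 1 else -expm1(-x) / x

# Closed-form transition matrix over a duration t for the non-adenoma chains
# with constant other-cause hazard delta. States: Normal, PCDP,
# (NonprogPCDP,) Clinical, Death. Sums of exponentials, written in
# cancellation-free forms; the equal-rate degeneracy lambda1 ~ lambda2 falls
# through to an analytic limit expansion rather than a division by zero.
.tp_progressive <- function(model, l1, l2, delta, t, fn = 0) {
  s <- model$states
  P <- diag(length(s)); dimnames(P) <- list(s, s)
  if (t == 0) return(P)
  l1p <- l1 * (1 - fn)
  a <- l1 + delta   # total exit Normal
  b <- l2 + delta   # total exit progressive PCDP
  sep <- l2 - l1
  ea <- exp(-a * t); eb <- exp(-b * t)
  # Normal -> PCDP: l1p (ea - eb)/sep = l1p ea t phi(sep t), exact and stable.
  pNP <- l1p * ea * t * .phi(sep * t)
  # Normal -> Clinical: l1p l2 (om(a) - om(b))/sep with om(x)=(1-e^{-xt})/x.
  if (abs(sep) < .EQUAL_RATE_TOL * max(a, b)) {
    # second-order expansion in sep around the equal-rate limit
    om1 <- t * ea / a - (1 - ea) / a^2                       # om'(a)
    om2 <- -t^2 * ea / a - 2 * t * ea / a^2 + 2 * (1 - ea) / a^3  # om''(a)
    pNC <- l1p * l2 * (-om1 - sep / 2 * om2)
  } else {
    pNC <- l1p * l2 * (.omexp_over(a, t) - .omexp_over(b, t)) / sep
  }
  P["Normal", "Normal"] <- ea
  P["Normal", "PCDP"] <- max(pNP, 0)
  P["Normal", "Clinical"] <- max(pNC, 0)
  P["PCDP", "PCDP"] <- eb
  P["PCDP", "Clinical"] <- l2 * .omexp_over(b, t)
  P["PCDP", "Death"] <- if (delta == 0) 0 else
    max(1 - eb - P["PCDP", "Clinical"], 0)
  if (has_nonprog_state(model)) {
    l1n <- l1 * fn
    P["Normal", "NonprogPCDP"] <- l1n * exp(-delta * t) * .omexp_over(l1, t)
    P["NonprogPCDP", "NonprogPCDP"] <- exp(-delta * t)
    P["NonprogPCDP", "Death"] <- -expm1(-delta * t)
  }
  P["Normal", "Death"] <- if (delta == 0) 0 else
    max(1 - sum(P["Normal", s != "Death"]), 0)
  P
}

# Constant-delta transition matrix over duration t: closed form where the
# chain admits one, matrix exponential otherwise.
.tp_const <- function(model, rates, delta, t) {
  if (!is_adenoma_variant(model))
    return(.tp_progressive(model, rates$lambda1, rates$lambda2, delta, t,
                           model$nonprog_fraction))
  Q <- intensity_matrix(model, rates, mortality_schedule(delta))
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  dimnames(P) <- dimnames(Q)
  P
}

# Transition matrix over calendar interval [a, b], exact under a
# piecewise-constant mortality schedule (product of homogeneous pieces).
tp_interval <- function(model, rates, mort, a, b) {
  stopifnot(b >= a)
  pieces <- mortality_pieces(mort, a, b)
  P <- .tp_const(model, rates, pieces$delta[1], pieces$b[1] - pieces$a[1])
  if (nrow(pieces) > 1)
    for (i in 2:nrow(pieces))
      P <- P %*% .tp_const(model, rates, pieces$delta[i],
                           pieces$b[i] - pieces$a[i])
  P
}

#' Transition probabilities P(t)
#'
#' Probability matrix of the natural-history chain over `t` years from entry.
#' For the non-adenoma variants with constant mortality this is a closed-form
#' sum of exponentials (with an analytic limit branch when the two progression
#' rates coincide); adenoma variants use the matrix exponential. A
#' piecewise-constant mortality schedule is handled exactly by multiplying the
#' homogeneous pieces. Test sensitivities play no role here: they live in the
#' screening layer only.
#'
#' @inheritParams intensity_matrix
#' @param t non-negative time in years.
#' @param from start of the interval (years since entry), relevant only for
#'   piecewise mortality schedules; the matrix then covers `[from, from + t]`.
#' @return a row-stochastic matrix with state dimnames and attribute `"time"`.
#' @examples
#' m <- od_model("progressive_3state")
#' r <- rate_parameters(lambda1 = 0.00141, lambda2 = 0.3860, sens_crc = 0.8)
#' transition_probability(m, r, mortality_schedule(0), t = 2)
#' @export
transition_probability <- function(model, rates, mort, t, from = 0) {
  stopifnot(inherits(model, "od_model"), inherits(mort, "mortality_schedule"))
  if (inherits(rates, "rate_parameters")) validate_rates(model, rates)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("'t' must be a single non-negative time in years")
  P <- tp_interval(model, rates, mort, from, from + t)
  attr(P, "time") <- t
  P
}

#' Mean sojourn time in the progressive preclinical phase
#'
#' The expected time a progressive lesion spends in the preclinical detectable
#' phase before surfacing clinically: the reciprocal of the progression rate.
#' An interval of rates (e.g. the bounds of a 95% interval) gives the
#' reciprocal of each bound in reversed order, so the result is again an
#' ordered (lower, upper) interval.
#'
#' @param rates a [rate_parameters()] object, or a numeric vector of
#'   progression rates (length 1, or length 2 for an interval).
#' @return mean sojourn time(s) in years.
#' @examples
#' mean_sojourn_time(0.3860)                 # 2.59 years
#' mean_sojourn_time(c(0.3726, 0.3997))      # (2.50, 2.68)
#' @export
mean_sojourn_time <- function(rates) {
  l2 <- if (inherits(rates, "rate_parameters")) rates$lambda2 else rates
  if (is.null(l2) || !is.numeric(l2) || any(is.na(l2)) || any(l2 <= 0))
    stop("progression rate 'lambda2' must be positive")
  if (length(l2) == 2L) rev(1 / l2) else 1 / l2
}
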