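#' Multi-state natural-history model variants
#'
#' Defines the continuous-time Markov model of colorectal-cancer natural
#' history used throughout the package. Four variants are supported:
#'
#' * `"progressive_3state"`: Normal -> preclinical detectable phase (PCDP) ->
#'   Clinical, plus an absorbing other-cause Death state.
#' * `"overdiag_embedded"`: as above, with an additional non-progressive PCDP
#'   state entered from Normal. A non-progressive lesion is screen-detectable
#'   but never surfaces clinically (its sojourn time is infinite); its only
#'   exit is other-cause death. The split of the preclinical incidence rate
#'   into progressive/non-progressive parts is controlled by
#'   `nonprog_fraction`, a generative knob for the simulator; it defaults to 0
#'   and is *not* an estimable parameter of the likelihood.
#' * `"adenoma_4state"`: Normal -> Adenoma -> PCDP -> Clinical (+ Death).
#' * `"adenoma_overdiag"`: the adenoma chain with the non-progressive PCDP
#'   state entered from Adenoma.
#'
#' Clinical and Death are absorbing. Every other ("alive") state is exposed to
#' the other-cause mortality hazard.
#'
#' @param variant one of `"progressive_3state"`, `"overdiag_embedded"`,
#'   `"adenoma_4state"`, `"adenoma_overdiag"`.
#' @param nonprog_fraction fraction of preclinical onsets that are
#'   non-progressive, in `[0, 1]`. Only meaningful for the `overdiag_*`
#'   variants; must be 0 otherwise.
#' @return an object of class `"od_model"`: a list with `variant`, `states`,
#'   `nonprog_fraction`, and the set of `transitions` (a character matrix of
#'   from/to state labels).
#' @examples
#' od_model("progressive_3state")
#' od_model("overdiag_embedded", nonprog_fraction = 0.05)
#' @export
od_model <- function(variant = c("progressive_3state", "overdiag_embedded",
                                 "adenoma_4state", "adenoma_overdiag"),
                     nonprog_fraction = 0) {
  variant <- match.arg(variant)
  if (!is.numeric(nonprog_fraction) || length(nonprog_fraction) != 1L ||
      is.na(nonprog_fraction) || nonprog_fraction < 0 || nonprog_fraction > 1)
    stop("'nonprog_fraction' must be a single number in [0, 1]")
  if (nonprog_fraction > 0 &&
      !variant %in% c("overdiag_embedded", "adenoma_overdiag"))
    stop("'nonprog_fraction' > 0 requires an overdiagnosis-embedded variant")

  states <- switch(variant,
    progressive_3state = c("Normal", "PCDP", "Clinical", "Death"),
    overdiag_embedded  = c("Normal", "PCDP", "NonprogPCDP", "Clinical", "Death"),
    adenoma_4state     = c("Normal", "Adenoma", "PCDP", "Clinical", "Death"),
    adenoma_overdiag   = c("Normal", "Adenoma", "PCDP", "NonprogPCDP",
                           "Clinical", "Death"))
  trans <- switch(variant,
    progressive_3state = rbind(c("Normal", "PCDP"), c("PCDP", "Clinical")),
    overdiag_embedded  = rbind(c("Normal", "PCDP"), c("Normal", "NonprogPCDP"),
                               c("PCDP", "Clinical")),
    adenoma_4state     = rbind(c("Normal", "Adenoma"), c("Adenoma", "PCDP"),
                               c("PCDP", "Clinical")),
    adenoma_overdiag   = rbind(c("Normal", "Adenoma"), c("Adenoma", "PCDP"),
                               c("Adenoma", "NonprogPCDP"),
                               c("PCDP", "Clinical")))
  colnames(trans) <- c("from", "to")
  structure(list(variant = variant, states = states,
                 nonprog_fraction = nonprog_fraction, transitions = trans),
            class = "od_model")
}

#' @export
print.od_model <- function(x, ...) {
  cat("Natural-history model:", x$variant, "\n")
  cat("States:", paste(x$states, collapse = " -> "), "\n")
  if (x$nonprog_fraction > 0)
    cat("Non-progressive fraction of preclinical onsets:",
        x$nonprog_fraction, "\n")
  invisible(x)
}

is_adenoma_variant <- function(model)
  model$variant %in% c("adenoma_4state", "adenoma_overdiag")

has_nonprog_state <- function(model)
  model$variant %in% c("overdiag_embedded", "adenoma_overdiag")

#' Transition intensities and test sensitivities
#'
#' Container for the rate parameters of one model variant. All intensities are
#' per person-year; sensitivities are per-screen detection probabilities.
#' Fields not used by the chosen variant must be left `NULL`; supplying them is
#' an error rather than a silent default, and omitting a required field is an
#' error at the point of use.
#'
#' @param lambda1 Normal -> PCDP intensity (non-adenoma variants).
#' @param lambda2 PCDP -> Clinical progression intensity. Its reciprocal is the
#'   mean sojourn time in the progressive preclinical phase.
#' @param sens_crc per-screen probability that a preclinical cancer tests
#'   positive, strictly inside (0, 1).
#' @param lambda1a Normal -> Adenoma intensity (adenoma variants only).
#' @param lambda1b Adenoma -> PCDP intensity (adenoma variants only).
#' @param sens_adenoma per-screen probability that an adenoma is detected,
#'   strictly inside (0, 1) (adenoma variants only).
#' @return an object of class `"rate_parameters"`.
#' @examples
#' rate_parameters(lambda1 = 0.00141, lambda2 = 0.3860, sens_crc = 0.8025)
#' @export
rate_parameters <- function(lambda1 = NULL, lambda2 = NULL, sens_crc = NULL,
                            lambda1a = NULL, lambda1b = NULL,
                            sens_adenoma = NULL) {
  chk_rate <- function(x, nm) {
    if (is.null(x)) return(invisible(NULL))
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive intensity", nm))
  }
  chk_sens <- function(x, nm) {
    if (is.null(x)) return(invisible(NULL))
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
      stop(sprintf("'%s' must be strictly inside (0, 1)", nm))
  }
  chk_rate(lambda1, "lambda1"); chk_rate(lambda2, "lambda2")
  chk_rate(lambda1a, "lambda1a"); chk_rate(lambda1b, "lambda1b")
  chk_sens(sens_crc, "sens_crc"); chk_sens(sens_adenoma, "sens_adenoma")
  out <- list(lambda1 = lambda1, lambda2 = lambda2, sens_crc = sens_crc,
              lambda1a = lambda1a, lambda1b = lambda1b,
              sens_adenoma = sens_adenoma)
  structure(out[!vapply(out, is.null, logical(1))], class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Rate parameters (per person-year; sensitivities per screen):\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Check that `rates` carries exactly the fields the variant needs.
validate_rates <- function(model, rates) {
  stopifnot(inherits(model, "od_model"), inherits(rates, "rate_parameters"))
  needed <- if (is_adenoma_variant(model))
    c("lambda1a", "lambda1b", "lambda2", "sens_crc", "sens_adenoma")
  else c("lambda1", "lambda2", "sens_crc")
  missing <- setdiff(needed, names(rates))
  if (length(missing))
    stop("missing rate parameter(s) for variant '", model$variant, "': ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(rates), needed)
  if (length(extra))
    stop("rate parameter(s) not used by variant '", model$variant, "': ",
         paste(extra, collapse = ", "), " (remove rather than ignore)")
  invisible(TRUE)
}

#' Serialize rate parameters as flat JSON
#'
#' @param rates a [rate_parameters()] object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "rate_parameters"))
  jsonlite::write_json(unclass(rates), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rate_parameters, as.list(x))
}

#' Other-cause mortality schedule
#'
#' The competing hazard of death from causes other than the screened cancer,
#' either constant or piecewise-constant on a time grid (years since cohort
#' entry). Evaluation outside the provided grid is an error, not an
#' extrapolation.
#'
#' @param rate non-negative hazard(s), per person-year. A scalar gives a
#'   constant hazard valid at all times.
#' @param breaks for a piecewise schedule, the interval boundaries: a numeric
#'   vector of length `length(rate) + 1`, strictly increasing, defining
#'   `[breaks[i], breaks[i+1])` for `rate[i]`.
#' @return an object of class `"mortality_schedule"`.
#' @examples
#' mortality_schedule(0.01)
#' mortality_schedule(c(0.005, 0.01, 0.02), breaks = c(0, 5, 10, 30))
#' @export
mortality_schedule <- function(rate, breaks = NULL) {
  if (!is.numeric(rate) || any(is.na(rate)) || any(rate < 0))
    stop("'rate' must be non-negative")
  if (is.null(breaks)) {
    if (length(rate) != 1L)
      stop("a constant schedule takes a single rate; otherwise give 'breaks'")
  } else {
    if (length(breaks) != length(rate) + 1L || any(diff(breaks) <= 0))
      stop("'breaks' must be strictly increasing with length(rate) + 1 entries")
  }
  structure(list(rate = unname(rate), breaks = breaks),
            class = "mortality_schedule")
}

#' @export
print.mortality_schedule <- function(x, ...) {
  if (is.null(x$breaks)) {
    cat("Other-cause mortality: constant hazard", x$rate, "per person-year\n")
  } else {
    cat("Other-cause mortality: piecewise-constant hazard\n")
    print(data.frame(from = x$breaks[-length(x$breaks)],
                     to = x$breaks[-1], rate = x$rate))
  }
  invisible(x)
}

is_constant_mortality <- function(mort) is.null(mort$breaks)

#' Evaluate the other-cause mortality hazard
#'
#' @param mort a [mortality_schedule()].
#' @param t times (years since entry) at which to evaluate.
#' @return hazard values, per person-year.
#' @export
hazard_at <- function(mort, t) {
  stopifnot(inherits(mort, "mortality_schedule"))
  if (is_constant_mortality(mort)) return(rep(mort$rate, length(t)))
  if (any(t < mort$breaks[1] | t > mort$breaks[length(mort$breaks)]))
    stop("time outside the mortality schedule grid [",
         mort$breaks[1], ", ", mort$breaks[length(mort$breaks)], "]")
  idx <- findInterval(t, mort$breaks, rightmost.closed = TRUE)
  mort$rate[pmin(idx, length(mort$rate))]
}

# Split [a, b] at the mortality breakpoints; returns data.frame(a, b, delta).
# Used to evaluate piecewise-homogeneous transition matrices exactly.
mortality_pieces <- function(mort, a, b) {
  stopifnot(b >= a)
  if (is_constant_mortality(mort) || a == b)
    return(data.frame(a = a, b = b, delta = hazard_at(mort, (a + b) / 2)))
  cuts <- mort$breaks[mort$breaks > a & mort$breaks < b]
  edges <- c(a, cuts, b)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  data.frame(a = edges[-length(edges)], b = edges[-1],
             delta = hazard_at(mort, mids))
}
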