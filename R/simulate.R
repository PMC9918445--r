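#' Simulation configuration
#'
#' Bundles everything the individual-level cohort simulator needs. The random
#' seed is mandatory: all simulator output is deterministic given the
#' configuration.
#'
#' @param n cohort size (>= 1).
#' @param rates [rate_parameters()] for the chosen variant. The generating
#'   preclinical incidence is the *total* (progressive plus non-progressive)
#'   rate; the model's `nonprog_fraction` controls the split.
#' @param mort a [mortality_schedule()]. A piecewise schedule must cover
#'   `[0, followup]`.
#' @param design a [screening_design()] (participation and confirmation are
#'   taken from here).
#' @param model an [od_model()]; a positive `nonprog_fraction` makes the
#'   simulated world contain truly non-progressive disease that the analysis
#'   pipeline is *not* told about.
#' @param seed random seed (mandatory).
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(n, rates, mort, design,
                              model = od_model("overdiag_embedded",
                                               nonprog_fraction = 0.05),
                              seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  validate_rates(model, rates)
  stopifnot(inherits(mort, "mortality_schedule"),
            inherits(design, "screening_design"))
  structure(list(n = as.integer(n), rates = rates, mort = mort,
                 design = design, model = model, seed = as.integer(seed)),
            class = "simulation_config")
}

# Other-cause death times from entry; Inf when no death occurs before the end
# of the schedule grid (the grid must cover the follow-up horizon).
.draw_death <- function(mort, n, horizon) {
  if (is_constant_mortality(mort)) {
    if (mort$rate == 0) return(rep(Inf, n))
    return(stats::rexp(n, mort$rate))
  }
  if (mort$breaks[1] > 0 || mort$breaks[length(mort$breaks)] < horizon)
    stop("the mortality schedule must cover [0, followup] for simulation")
  e <- stats::rexp(n)
  widths <- diff(mort$breaks)
  cumhaz <- c(0, cumsum(mort$rate * widths))
  idx <- findInterval(e, cumhaz)
  out <- rep(Inf, n)
  inside <- idx <= length(mort$rate)
  out[inside] <- mort$breaks[idx[inside]] +
    (e[inside] - cumhaz[idx[inside]]) / mort$rate[idx[inside]]
  out
}

# Latent event histories, conditioned on no clinical surfacing before the
# first screen (rejection resampling). Draw order is fixed so that a screened
# cohort and its unscreened control share identical latent histories under
# the same seed.
.simulate_latents <- function(cfg) {
  n <- cfg$n; r <- cfg$rates; model <- cfg$model; d <- cfg$design
  fn <- model$nonprog_fraction
  t1 <- d$screen_times[1]
  adeno <- is_adenoma_variant(model)
  draw <- function(m) {
    if (adeno) {
      a_onset <- -d$lead_time + stats::rexp(m, r$lambda1a)
      onset <- a_onset + stats::rexp(m, r$lambda1b)  # PCDP entry
    } else {
      a_onset <- rep(NA_real_, m)
      onset <- -d$lead_time + stats::rexp(m, r$lambda1)
    }
    nonprog <- stats::runif(m) < fn
    clinical <- onset + stats::rexp(m, r$lambda2)
    clinical[nonprog] <- Inf
    data.frame(adenoma_onset = a_onset, onset = onset, nonprog = nonprog,
               clinical = clinical)
  }
  lat <- draw(n)
  bad <- which(lat$clinical <= t1)
  while (length(bad)) {
    lat[bad, ] <- draw(length(bad))
    bad <- bad[lat$clinical[bad] <= t1]
  }
  lat$death <- .draw_death(cfg$mort, n, d$followup)
  lat
}

#' Simulate a screened cohort individual by individual
#'
#' Generates latent disease histories (exponential waiting times per
#' transition intensity, a Bernoulli non-progressive label per onset,
#' competing other-cause death), runs the screening programme over them
#' (all-or-none participation, independent per-screen detection, confirmation
#' of positives, exit on detection), and tabulates the detection-mode counts
#' together with ground-truth labels no real programme observes: which
#' screen-detected cases were truly overdiagnosed (non-progressive, or dead of
#' other causes before their latent clinical date), which carried lead time
#' beyond the horizon, and what the same individuals would have contributed
#' without screening.
#'
#' @param config a [simulation_config()].
#' @param keep_individuals return the per-subject record as `$individuals`.
#' @return list with `counts` (a [detection_mode_counts()] table), `truth`
#'   (named list of ground-truth tallies), and the echoed `config`.
#' @examples
#' cfg <- simulation_config(
#'   n = 20000, rates = taiwan_rates(), mort = mortality_schedule(0.01),
#'   design = rct_design("taiwan"), seed = 1)
#' sim <- simulate_cohort(cfg)
#' sim$truth$n_overdiagnosed
#' @export
simulate_cohort <- function(config, keep_individuals = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)

  d <- config$design; r <- config$rates; model <- config$model
  st <- d$screen_times; k <- length(st); Tend <- d$followup
  w_last <- program_end(d)
  adeno <- is_adenoma_variant(model)
  lat <- .simulate_latents(config)
  n <- config$n
  participant <- stats::runif(n) < d$participation

  exited <- !participant            # refusers never enter the screen loop
  det_round <- integer(n)           # confirmed detection round, 0 = none
  unconf_round <- integer(n)
  removed_ad <- logical(n)
  att_first <- 0; neg_repeat <- 0
  det_is_first <- logical(n)

  for (rd in seq_len(k)) {
    t_r <- st[rd]
    att <- !exited & lat$death > t_r & lat$clinical > t_r
    in_pcdp <- att & lat$onset <= t_r
    pos_crc <- in_pcdp & stats::runif(n) < r$sens_crc
    pos <- pos_crc
    if (adeno) {
      in_ad <- att & lat$adenoma_onset <= t_r & lat$onset > t_r
      pos_ad <- in_ad & stats::runif(n) < r$sens_adenoma
      pos <- pos | pos_ad
    }
    conf <- pos & stats::runif(n) < d$confirmation
    if (adeno) {
      rm_now <- conf & !pos_crc
      removed_ad <- removed_ad | rm_now
      conf_crc <- conf & pos_crc
    } else conf_crc <- conf
    newdet <- conf_crc & det_round == 0
    det_round[newdet] <- rd
    det_is_first[newdet] <- rd == 1L
    unc <- pos & !conf
    unconf_round[unc & unconf_round == 0] <- rd
    if (rd == 1L) att_first <- sum(att)
    else neg_repeat <- neg_repeat + sum(att & !pos)
    exited <- exited | pos   # any positive (confirmed or not) leaves
  }

  death_or_T <- pmin(lat$death, Tend)
  surf <- lat$clinical <= death_or_T          # would surface within follow-up
  detected <- det_round > 0
  unconf <- unconf_round > 0 & !detected & !removed_ad
  free <- participant & !detected & !(unconf_round > 0) & !removed_ad
  interval_case <- free & surf & lat$clinical <= w_last
  postprog_case <- free & surf & lat$clinical > w_last
  unconf_case <- unconf & surf
  refuser_case <- !participant & surf

  overdx <- detected & (lat$nonprog | lat$death < lat$clinical)
  lead_beyond <- detected & !overdx & lat$clinical > Tend

  # First-round attenders not attributed to a first-round cancer mode; the
  # same convention as the analytic expected counts.
  obs <- c(
    prevalent_normal = att_first - sum(detected & det_is_first) -
      sum(unconf_case & unconf_round == 1L),
    prevalent_crc = sum(detected & det_is_first),
    interval_crc = sum(interval_case),
    repeat_normal = neg_repeat,
    repeat_crc = sum(detected & !det_is_first),
    refuser_normal = sum(!participant) - sum(refuser_case),
    refuser_crc = sum(refuser_case))
  if (d$confirmation < 1)
    obs <- c(obs,
             positive_unconfirmed_first = sum(unconf_case & unconf_round == 1L),
             positive_unconfirmed_repeat = sum(unconf_case & unconf_round > 1L))
  counts <- do.call(detection_mode_counts, as.list(obs))

  truth <- list(
    n = n, n_participant = sum(participant),
    n_detected = sum(detected),
    n_overdiagnosed = sum(overdx),
    n_lead_beyond_horizon = sum(lead_beyond),
    would_be_clinical = sum(surf),        # control-world count, same people
    screened_counted = sum(detected) + sum(interval_case) +
      sum(postprog_case) + sum(unconf_case) + sum(refuser_case),
    n_post_program = sum(postprog_case),
    n_adenoma_removed = if (adeno) sum(removed_ad) else 0L,
    n_adenoma_averted = if (adeno) sum(removed_ad & surf) else 0L,
    n_adenoma_would_pcdp = if (adeno)
      sum(removed_ad & lat$onset <= death_or_T) else 0L,
    seed = config$seed)

  out <- list(counts = counts, truth = truth, config = config)
  if (keep_individuals)
    out$individuals <- data.frame(
      lat, participant = participant, det_round = det_round,
      unconf_round = unconf_round, overdiagnosed = overdx,
      mode = ifelse(detected & det_is_first, "prevalent_crc",
             ifelse(detected, "repeat_crc",
             ifelse(unconf_case & unconf_round == 1L, "positive_unconfirmed_first",
             ifelse(unconf_case, "positive_unconfirmed_repeat",
             ifelse(interval_case, "interval_crc",
             ifelse(postprog_case, "post_program",
             ifelse(refuser_case, "refuser_crc", "none"))))))))
  out
}

#' Simulate the matched unscreened control population
#'
#' The same latent histories as [simulate_cohort()] under the same seed, with
#' screening switched off: counts clinical cancers surfacing before the
#' earlier of other-cause death and the follow-up horizon. Non-progressive
#' lesions never surface.
#'
#' @param config a [simulation_config()].
#' @return list with `clinical_count`, `n`, and the echoed `config`.
#' @export
simulate_control <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  lat <- .simulate_latents(config)
  cnt <- sum(lat$clinical <= pmin(lat$death, config$design$followup))
  list(clinical_count = cnt, n = config$n, config = config)
}
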