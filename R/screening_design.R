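#' Screening programme design
#'
#' Describes an organised stool-test screening programme: the screen schedule,
#' follow-up horizon, cohort size, the participant/refuser split (attendance is
#' all-or-none: an invitee is a lifelong participant or a lifelong refuser),
#' and the probability that a positive test receives diagnostic confirmation.
#'
#' Disease may already be present at the first screen: the natural-history
#' process is assumed to have run for `lead_time` years before entry, and the
#' cohort is conditioned on being alive and not yet clinically diagnosed at
#' entry (subjects surfacing before the first screen are excluded from the
#' prevalent-screen denominator). `lead_time` values beyond ~25 years put the
#' preclinical prevalence at its quasi-stationary value `lambda1 / lambda2`.
#'
#' Interval cancers are ascertained between consecutive screens. After the
#' final screen the default window extends one regular inter-screen gap
#' (`interval_cap = "next_screen"`); clinical cases surfacing later are not
#' part of the detection-mode data (the digital twin accounts for them as a
#' separate post-programme component). `interval_cap = "followup"` extends the
#' final window to the follow-up horizon instead.
#'
#' @param screen_times ordered screen times in years since entry, starting at
#'   or after 0 (typically `0, 2, 4, ...` for a biennial programme).
#' @param followup follow-up horizon T in years since entry; at least the last
#'   screen time.
#' @param cohort_size number of invited subjects.
#' @param participation probability of being a (lifelong) participant,
#'   in (0, 1].
#' @param confirmation probability that a positive test is followed by
#'   diagnostic confirmation; unconfirmed positives leave the programme and
#'   their later clinical cancers form the positive-unconfirmed modes.
#' @param lead_time years of disease natural history accrued before entry.
#' @param interval_cap `"next_screen"` or `"followup"`; see Details.
#' @return an object of class `"screening_design"`.
#' @examples
#' screening_design(screen_times = c(0, 2, 4), followup = 8.5,
#'                  cohort_size = 74998, participation = 0.60)
#' @export
screening_design <- function(screen_times, followup, cohort_size,
                             participation, confirmation = 1,
                             lead_time = 30,
                             interval_cap = c("next_screen", "followup")) {
  interval_cap <- match.arg(interval_cap)
  if (!is.numeric(screen_times) || length(screen_times) < 1L ||
      any(is.na(screen_times)) || screen_times[1] < 0 ||
      is.unsorted(screen_times, strictly = TRUE))
    stop("'screen_times' must be strictly increasing and start at >= 0")
  if (!is.numeric(followup) || length(followup) != 1L ||
      followup < screen_times[length(screen_times)])
    stop("'followup' must be at least the last screen time")
  if (!is.numeric(cohort_size) || length(cohort_size) != 1L || cohort_size < 1)
    stop("'cohort_size' must be >= 1")
  if (!is.numeric(participation) || length(participation) != 1L ||
      participation <= 0 || participation > 1)
    stop("'participation' must be in (0, 1]")
  if (!is.numeric(confirmation) || length(confirmation) != 1L ||
      confirmation < 0 || confirmation > 1)
    stop("'confirmation' must be in [0, 1]")
  if (!is.numeric(lead_time) || length(lead_time) != 1L || lead_time < 0)
    stop("'lead_time' must be non-negative")
  structure(list(screen_times = screen_times, followup = followup,
                 cohort_size = cohort_size, participation = participation,
                 confirmation = confirmation, lead_time = lead_time,
                 interval_cap = interval_cap),
            class = "screening_design")
}

#' @export
print.screening_design <- function(x, ...) {
  cat("Screening design:\n")
  cat("  screens at years:", paste(x$screen_times, collapse = ", "), "\n")
  cat("  follow-up horizon:", x$followup, "y; cohort:", x$cohort_size, "\n")
  cat(sprintf("  participation %.3f; confirmation of positives %.3f\n",
              x$participation, x$confirmation))
  cat("  pre-entry disease accrual:", x$lead_time,
      "y; final interval window:", x$interval_cap, "\n")
  invisible(x)
}

# End of the final interval-cancer ascertainment window.
program_end <- function(design) {
  st <- design$screen_times
  k <- length(st)
  if (design$interval_cap == "followup" || k == 1L) return(design$followup)
  gap <- st[k] - st[k - 1L]
  min(st[k] + gap, design$followup)
}

#' Read or write a screening design as YAML
#'
#' @param path YAML file with the fields of [screening_design()].
#' @param design a [screening_design()] object.
#' @return `read_design` returns a [screening_design()]; `write_design`
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(screening_design, x)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "screening_design"))
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}

#' Built-in programme designs
#'
#' Documented design assumptions for the three study settings analysed in the
#' package: the two guaiac-FOBT randomised trials (Nottingham, UK and Funen,
#' Denmark) and a Taiwan-like biennial FIT service-screening programme. The
#' trial papers do not print the full round structure; round counts are chosen
#' to reproduce the published repeat-test totals and the follow-up horizon is
#' the published mean follow-up. All values can be overridden by constructing
#' a [screening_design()] directly.
#'
#' @param style `"nottingham"`, `"funen"`, or `"taiwan"`.
#' @return a [screening_design()].
#' @examples
#' rct_design("funen")
#' @export
rct_design <- function(style = c("nottingham", "funen", "taiwan")) {
  style <- match.arg(style)
  switch(style,
    nottingham = screening_design(
      screen_times = c(0, 2, 4), followup = 8.5, cohort_size = 74998,
      participation = 0.596, confirmation = 0.85),
    funen = screening_design(
      screen_times = c(0, 2, 4, 6), followup = 10.0, cohort_size = 30966,
      participation = 0.672, confirmation = 1),
    taiwan = screening_design(
      screen_times = c(0, 2, 4, 6, 8), followup = 11.0,
      cohort_size = 5417699, participation = 0.70, confirmation = 1,
      lead_time = 20))
}

#' Taiwan-like FIT parameter preset
#'
#' The fitted natural-history parameters of the biennial FIT programme
#' (preclinical incidence 1.41 per 1000 person-years, progression rate 0.3860
#' per year so a mean sojourn time of 2.59 years, FIT sensitivity 80.25%), and
#' the adenoma-extended counterpart.
#'
#' @param adenoma if `TRUE`, return the adenoma-extended parameter set.
#' @return a [rate_parameters()] object.
#' @export
taiwan_rates <- function(adenoma = FALSE) {
  if (adenoma)
    rate_parameters(lambda1a = 0.00149, lambda1b = 0.0839, lambda2 = 0.5300,
                    sens_adenoma = 0.6348, sens_crc = 0.8286)
  else
    rate_parameters(lambda1 = 0.00141, lambda2 = 0.3860, sens_crc = 0.8025)
}
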