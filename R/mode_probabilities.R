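#' Detection-mode probabilities under a screening design
#'
#' Propagates the natural-history chain through a screening programme and
#' returns, per invited subject, the probability of every detection-mode
#' outcome. Within each stratum the subject-level fates form an exhaustive
#' partition:
#'
#' * participants: confirmed detection at the first screen
#'   (`prevalent_crc`), confirmed detection at a repeat screen (`repeat_crc`),
#'   an unconfirmed positive whose cancer later surfaces clinically
#'   (`positive_unconfirmed_first` / `_repeat`), a clinically surfacing
#'   interval cancer within an ascertainment window (`interval_crc`), a
#'   clinical cancer after the final window but before the follow-up horizon
#'   (`post_program_clinical`), or no cancer event (`no_crc`);
#' * refusers: a clinical cancer by the horizon (`refuser_crc`) or none
#'   (`refuser_normal`).
#'
#' The chain starts `lead_time` years before entry and both strata are
#' conditioned on being alive and (by default) not yet clinically diagnosed at
#' the first screen. At an attended screen a preclinical cancer tests positive
#' with probability `sens_crc`, independently across screens; a positive is
#' confirmed (diagnosed) with the design's confirmation probability, and an
#' unconfirmed positive leaves the programme and progresses naturally. In the
#' adenoma variants an adenoma is detected with probability `sens_adenoma` and,
#' if confirmed, removed (the subject leaves the cancer pathway); the expected
#' number of removals and the expected would-be cancers among them (the
#' polypectomy offset) are returned as bookkeeping for the digital twin.
#'
#' Expected counts for the published-style table cells, including the
#' negative-test "Normal" cells, are available via [expected_mode_counts()].
#'
#' @inheritParams intensity_matrix
#' @param design a [screening_design()].
#' @param prior_clinical handling of subjects surfacing clinically before the
#'   first screen: excluded from the cohort (default) or, for the refuser
#'   stratum, pooled into the refuser cancers.
#' @return an object of class `"mode_probabilities"`: a list with numeric
#'   vectors `participant` and `refuser` (each an exhaustive fate partition),
#'   per-subject expected test counts `prevalent_normal` and `repeat_normal`,
#'   and for adenoma variants `adenoma_removed` and `adenoma_offset`.
#' @examples
#' mode_probabilities(od_model("progressive_3state"),
#'                    rate_parameters(lambda1 = 0.00147, lambda2 = 0.3475,
#'                                    sens_crc = 0.534),
#'                    mortality_schedule(0.01), rct_design("nottingham"))
#' @export
mode_probabilities <- function(model, rates, mort, design,
                               prior_clinical = c("exclude", "pool_refuser")) {
  stopifnot(inherits(design, "screening_design"))
  prior_clinical <- match.arg(prior_clinical)
  if (inherits(rates, "rate_parameters")) validate_rates(model, rates)
  s <- model$states
  alive <- setdiff(s, c("Clinical", "Death"))
  pcdp_states <- intersect(c("PCDP", "NonprogPCDP"), s)
  st <- design$screen_times
  k <- length(st)
  Tend <- design$followup
  sens <- rates$sens_crc
  sens_ad <- if (is_adenoma_variant(model)) rates$sens_adenoma else NULL
  cf <- design$confirmation

  # State distribution at the first screen. The pre-entry segment uses the
  # disease chain without other-cause mortality: conditioning on being alive
  # at entry cancels a constant hazard exactly (see vignette).
  M0 <- .tp_const(model, rates, 0, design$lead_time + st[1])
  pi_raw <- M0["Normal", ]
  prior_clin <- pi_raw["Clinical"]
  v <- pi_raw[alive] / sum(pi_raw[alive])

  screen_det <- numeric(k)      # confirmed detections, per round
  unconf_surf <- numeric(k)     # unconfirmed positives surfacing by T
  interval <- 0
  attend <- numeric(k)          # P(alive, undiagnosed, in programme)
  positives <- numeric(k)       # all positive tests (CRC + adenoma)
  removed <- 0; offset <- 0     # adenoma bookkeeping
  refuser_v <- v                # refusers share the entry distribution

  for (r in seq_len(k)) {
    attend[r] <- sum(v)
    p_pool <- sum(v[pcdp_states])
    det <- p_pool * sens
    positives[r] <- det
    screen_det[r] <- det * cf
    # Unconfirmed positives progress naturally from t_r; only progressive
    # preclinical cancers can surface by T.
    if (cf < 1 && "PCDP" %in% s) {
      Mr <- tp_interval(model, rates, mort, st[r], Tend)
      unconf_surf[r] <- v["PCDP"] * sens * (1 - cf) * Mr["PCDP", "Clinical"]
    }
    v[pcdp_states] <- v[pcdp_states] * (1 - sens)
    if (!is.null(sens_ad) && "Adenoma" %in% s) {
      ad_det <- v["Adenoma"] * sens_ad
      positives[r] <- positives[r] + ad_det
      removed <- removed + ad_det * cf
      # Polypectomy offset: a removed adenoma is counted by the probability
      # that it would have become a preclinical cancer during follow-up while
      # its host was alive (not merely a clinically surfacing one -- removal
      # of a would-be non-surfacing cancer is precisely overdiagnosis).
      offset <- offset + ad_det * cf *
        .p_adenoma_to_pcdp(rates$lambda1b, mort, st[r], Tend)
      if (cf < 1) {
        Mr <- tp_interval(model, rates, mort, st[r], Tend)
        unconf_surf[r] <- unconf_surf[r] +
          ad_det * (1 - cf) * Mr["Adenoma", "Clinical"]
      }
      v["Adenoma"] <- v["Adenoma"] * (1 - sens_ad)
    }
    w_end <- if (r < k) st[r + 1] else program_end(design)
    M <- tp_interval(model, rates, mort, st[r], w_end)
    interval <- interval + sum(v * M[alive, "Clinical"])
    v <- as.vector(v %*% M[alive, alive])
    names(v) <- alive
  }

  w_last <- program_end(design)
  post_program <- if (w_last < Tend) {
    M <- tp_interval(model, rates, mort, w_last, Tend)
    sum(v * M[alive, "Clinical"])
  } else 0

  # Refusers: clinical surfacing between entry and the horizon.
  Mref <- tp_interval(model, rates, mort, st[1], Tend)
  refuser_crc <- sum(refuser_v * Mref[alive, "Clinical"])
  if (prior_clinical == "pool_refuser")  # alive-only conditioning; pre-entry
    refuser_crc <- prior_clin + (1 - prior_clin) * refuser_crc  # cases pooled

  part <- c(prevalent_crc = unname(screen_det[1]),
            positive_unconfirmed_first = unname(unconf_surf[1]),
            positive_unconfirmed_repeat = sum(unconf_surf[-1]),
            repeat_crc = sum(screen_det[-1]),
            interval_crc = interval,
            post_program_clinical = post_program)
  part <- c(part, no_crc = 1 - sum(part))
  ref <- c(refuser_crc = refuser_crc, refuser_normal = 1 - refuser_crc)

  bad <- c(part, ref)
  if (any(bad < -1e-12) || any(bad > 1 + 1e-12))
    stop("detection-mode probabilities outside [0, 1]; rates and design ",
         "are inconsistent: ",
         paste(sprintf("%s=%.3g", names(bad), bad), collapse = ", "))

  out <- list(
    participant = pmin(pmax(part, 0), 1),
    refuser = pmin(pmax(ref, 0), 1),
    prevalent_normal = unname(attend[1] - screen_det[1] - unconf_surf[1]),
    repeat_normal = sum(attend[-1] - positives[-1]),
    detections_by_round = screen_det,
    attendance_by_round = attend,
    model = model, design = design)
  if (!is.null(sens_ad)) {
    out$adenoma_removed <- removed
    out$adenoma_offset <- offset
  }
  structure(out, class = "mode_probabilities")
}

# P(an adenoma present at time a enters the preclinical phase before
# min(b, host death)), exact under a piecewise-constant mortality schedule.
.p_adenoma_to_pcdp <- function(lambda1b, mort, a, b) {
  pieces <- mortality_pieces(mort, a, b)
  p <- 0; surv <- 1
  for (i in seq_len(nrow(pieces))) {
    rate <- lambda1b + pieces$delta[i]
    w <- pieces$b[i] - pieces$a[i]
    p <- p + surv * lambda1b / rate * -expm1(-rate * w)
    surv <- surv * exp(-rate * w)
  }
  p
}

#' @export
print.mode_probabilities <- function(x, ...) {
  cat("Per-subject detection-mode probabilities\n")
  cat("Participant fates:\n")
  print(round(x$participant, 6))
  cat("Refuser fates:\n")
  print(round(x$refuser, 6))
  invisible(x)
}

#' Expected detection-mode counts
#'
#' Scales the per-subject mode probabilities to expected table-cell counts,
#' including the negative-test cells (`prevalent_normal`, `repeat_normal`).
#'
#' @param probs a [mode_probabilities()] object.
#' @param n_participant,n_refuser stratum sizes. Defaults come from the
#'   design's cohort size and participation probability.
#' @param modes which cells to return; defaults to all canonical table cells.
#' @return named numeric vector of expected counts.
#' @export
expected_mode_counts <- function(probs,
                                 n_participant = NULL, n_refuser = NULL,
                                 modes = MODE_TABLE$mode) {
  stopifnot(inherits(probs, "mode_probabilities"))
  d <- probs$design
  if (is.null(n_participant))
    n_participant <- d$cohort_size * d$participation
  if (is.null(n_refuser))
    n_refuser <- d$cohort_size * (1 - d$participation)
  e <- c(prevalent_normal = n_participant * probs$prevalent_normal,
         prevalent_crc = n_participant * probs$participant[["prevalent_crc"]],
         positive_unconfirmed_first =
           n_participant * probs$participant[["positive_unconfirmed_first"]],
         positive_unconfirmed_repeat =
           n_participant * probs$participant[["positive_unconfirmed_repeat"]],
         interval_crc = n_participant * probs$participant[["interval_crc"]],
         repeat_normal = n_participant * probs$repeat_normal,
         repeat_crc = n_participant * probs$participant[["repeat_crc"]],
         refuser_normal = n_refuser * probs$refuser[["refuser_normal"]],
         refuser_crc = n_refuser * probs$refuser[["refuser_crc"]])
  e[intersect(modes, names(e))]
}

#' Multinomial log-likelihood of detection-mode counts
#'
#' The kernel `sum(n_m * log(p_m))` over the cancer detection modes present in
#' the data, within each stratum, plus the implicit no-event remainder cell
#' that completes the partition (stratum sizes are taken from the count
#' table's first-round and refuser rows). A positive count on a
#' zero-probability mode yields `-Inf` with a warning, never an error, so
#' optimisers can recover.
#'
#' @param counts a [detection_mode_counts()] table.
#' @param probs a [mode_probabilities()] object.
#' @return the log-likelihood (a scalar).
#' @export
log_likelihood <- function(counts, probs) {
  stopifnot(inherits(counts, "mode_counts"),
            inherits(probs, "mode_probabilities"))
  v <- counts_vector(counts)
  ns <- stratum_sizes(counts)
  part_modes <- intersect(names(v), setdiff(CRC_MODES, "refuser_crc"))
  n_part <- v[part_modes]
  p_part <- probs$participant[part_modes]
  # Modes absent from the data fold into the remainder cell.
  p_rest <- 1 - sum(p_part)
  n_rest <- ns[["participant"]] - sum(n_part)
  if (n_rest < 0) stop("participant cancer counts exceed the stratum size")
  nn <- c(n_part, n_rest)
  pp <- c(p_part, p_rest)
  if ("refuser_crc" %in% names(v)) {
    n_ref <- v[["refuser_crc"]]
    nn <- c(nn, n_ref, ns[["refuser"]] - n_ref)
    pp <- c(pp, probs$refuser[["refuser_crc"]], probs$refuser[["refuser_normal"]])
  }
  ll <- 0
  for (i in seq_along(nn)) {
    if (nn[i] == 0) next
    if (pp[i] <= 0) {
      warning("count > 0 on a zero-probability detection mode")
      return(-Inf)
    }
    ll <- ll + nn[i] * log(pp[i])
  }
  unname(ll)
}
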