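# Canonical detection-mode keys, their stratum, and the screening round they
# summarise (1 = prevalent/first round, NA = pooled over repeat rounds or over
# the whole follow-up).
MODE_TABLE <- data.frame(
  mode = c("prevalent_normal", "prevalent_crc",
           "positive_unconfirmed_first", "positive_unconfirmed_repeat",
           "interval_crc", "repeat_normal", "repeat_crc",
           "refuser_normal", "refuser_crc"),
  stratum = c(rep("participant", 7), rep("refuser", 2)),
  round = c(1, 1, 1, NA, NA, NA, NA, NA, NA),
  stringsAsFactors = FALSE)

# CRC-event modes that enter the fitting likelihood.
CRC_MODES <- c("prevalent_crc", "positive_unconfirmed_first",
               "positive_unconfirmed_repeat", "interval_crc", "repeat_crc",
               "refuser_crc")

#' Detection-mode count table
#'
#' Observed cancer and negative-test counts by detection mode, the data the
#' screening likelihood and the goodness-of-fit consume. A mode absent from a
#' dataset (e.g. the unconfirmed-positive rows of the Funen trial) is simply
#' omitted — missing is not zero. Counts must be non-negative integers.
#'
#' The participant "Normal" rows are test counts, not subject counts:
#' `prevalent_normal` is the number of first screens without a confirmed (or
#' later-surfacing unconfirmed) cancer, and `repeat_normal` the total number
#' of negative repeat tests, which can exceed the cohort size.
#'
#' @param ... named counts among `prevalent_normal`, `prevalent_crc`,
#'   `positive_unconfirmed_first`, `positive_unconfirmed_repeat`,
#'   `interval_crc`, `repeat_normal`, `repeat_crc`, `refuser_normal`,
#'   `refuser_crc`.
#' @param predicted optional named numeric vector of model-predicted counts
#'   for (a subset of) the same modes.
#' @return a data.frame of class `"mode_counts"` with columns
#'   `stratum`, `mode`, `round`, `observed` (and `predicted` if given).
#' @examples
#' detection_mode_counts(prevalent_normal = 20635, prevalent_crc = 37,
#'                       interval_crc = 148, repeat_normal = 66025,
#'                       repeat_crc = 83, refuser_normal = 9895,
#'                       refuser_crc = 195)
#' @export
detection_mode_counts <- function(..., predicted = NULL) {
  obs <- c(...)
  if (is.null(names(obs)) || any(!nzchar(names(obs))))
    stop("all counts must be named")
  bad <- setdiff(names(obs), MODE_TABLE$mode)
  if (length(bad)) stop("unknown detection mode(s): ",
                        paste(bad, collapse = ", "))
  if (any(is.na(obs)) || any(obs < 0) || any(obs != round(obs)))
    stop("counts must be non-negative integers; omit missing modes entirely")
  idx <- match(names(obs), MODE_TABLE$mode)
  out <- data.frame(stratum = MODE_TABLE$stratum[idx], mode = names(obs),
                    round = MODE_TABLE$round[idx], observed = as.numeric(obs),
                    stringsAsFactors = FALSE)
  if (!is.null(predicted)) {
    badp <- setdiff(names(predicted), names(obs))
    if (length(badp)) stop("'predicted' has modes absent from the counts: ",
                           paste(badp, collapse = ", "))
    out$predicted <- unname(predicted[match(out$mode, names(predicted))])
  }
  out <- out[order(match(out$mode, MODE_TABLE$mode)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mode_counts", "data.frame")
  out
}

#' @export
print.mode_counts <- function(x, ...) {
  cat("Detection-mode counts (", nrow(x), " cells)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Named vector of observed counts.
counts_vector <- function(counts, col = "observed") {
  stopifnot(inherits(counts, "mode_counts"))
  stats::setNames(counts[[col]], counts$mode)
}

# Stratum sizes implied by the count table: participants from the first-round
# rows (every participant is screened once), refusers from the refuser rows.
stratum_sizes <- function(counts) {
  v <- counts_vector(counts)
  first <- intersect(c("prevalent_normal", "prevalent_crc",
                       "positive_unconfirmed_first"), names(v))
  ref <- intersect(c("refuser_normal", "refuser_crc"), names(v))
  if (!"prevalent_normal" %in% first || !"refuser_normal" %in% ref)
    stop("counts must include 'prevalent_normal' and 'refuser_normal' ",
         "to determine the stratum sizes")
  c(participant = sum(v[first]), refuser = sum(v[ref]))
}

#' Read or write detection-mode counts as CSV
#'
#' The CSV schema has columns `stratum, mode, round, observed` and optionally
#' `predicted`; missing modes are omitted rows, never zero-filled.
#'
#' @param path CSV file.
#' @param counts a `"mode_counts"` table.
#' @return `read_mode_counts` returns a `"mode_counts"` table;
#'   `write_mode_counts` returns `path` invisibly.
#' @export
read_mode_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mode", "observed") %in% names(x)))
    stop("counts CSV needs at least columns 'mode' and 'observed'")
  obs <- stats::setNames(x$observed, x$mode)
  pred <- if ("predicted" %in% names(x) && !all(is.na(x$predicted)))
    stats::setNames(x$predicted, x$mode) else NULL
  do.call(detection_mode_counts, c(as.list(obs), list(predicted = pred)))
}

#' @rdname read_mode_counts
#' @export
write_mode_counts <- function(counts, path) {
  stopifnot(inherits(counts, "mode_counts"))
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Published detection-mode tables of the two guaiac-FOBT trials
#'
#' The observed and model-predicted cancer counts by detection mode of the
#' Nottingham (UK) and Funen (Denmark) randomised trials, as published. The
#' Nottingham layout has 9 cells including the two positive-without-
#' confirmation rows; the Funen layout has 7 cells (those rows do not occur).
#'
#' @param style `"nottingham"` or `"funen"`.
#' @return a `"mode_counts"` table with both `observed` and `predicted`
#'   columns.
#' @examples
#' make_rct_fixture("funen")
#' @export
make_rct_fixture <- function(style = c("nottingham", "funen")) {
  style <- match.arg(style)
  if (style == "nottingham") {
    detection_mode_counts(
      prevalent_normal = 44733, prevalent_crc = 104,
      positive_unconfirmed_first = 28, positive_unconfirmed_repeat = 57,
      interval_crc = 164, repeat_normal = 88008, repeat_crc = 132,
      refuser_normal = 30015, refuser_crc = 400,
      predicted = c(prevalent_normal = 44735.42, prevalent_crc = 101.58,
                    positive_unconfirmed_first = 27.76,
                    positive_unconfirmed_repeat = 66.03,
                    interval_crc = 140.04, repeat_normal = 87977.51,
                    repeat_crc = 109.69, refuser_normal = 30014.06,
                    refuser_crc = 400.94))
  } else {
    detection_mode_counts(
      prevalent_normal = 20635, prevalent_crc = 37, interval_crc = 148,
      repeat_normal = 66025, repeat_crc = 83,
      refuser_normal = 9895, refuser_crc = 195,
      predicted = c(prevalent_normal = 20630.24, prevalent_crc = 41.76,
                    interval_crc = 147.23, repeat_normal = 66014.12,
                    repeat_crc = 67.74, refuser_normal = 9895.71,
                    refuser_crc = 194.29))
  }
}
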