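#' Pearson chi-square goodness of fit by detection mode
#'
#' Internal-validity check comparing observed and model-predicted counts cell
#' by cell: the statistic is `sum((O - E)^2 / E)` over the present cells, with
#' degrees of freedom `cells - n_params`. That df convention (number of table
#' cells minus the number of fitted natural-history parameters) reproduces the
#' published trial values: 9 cells - 3 parameters = 6 df for the Nottingham
#' layout, 7 - 3 = 4 for Funen. Cells are not pooled at small expectations and
#' no continuity correction is applied.
#'
#' @param observed named numeric vector of observed counts, or a
#'   [detection_mode_counts()] table carrying both `observed` and `predicted`
#'   columns (in which case `expected` may be omitted).
#' @param expected named numeric vector of expected counts on the same cells;
#'   all strictly positive.
#' @param n_params number of estimated parameters absorbed by the expected
#'   counts (3 for the standard model variants).
#' @return an object of class `"od_gof"`: `statistic`, `df`, `p.value`, and
#'   the per-cell `contributions`.
#' @examples
#' gof <- pearson_chi_square(make_rct_fixture("nottingham"), n_params = 3)
#' gof$statistic   # ~9.94 on 6 df
#' @export
pearson_chi_square <- function(observed, expected = NULL, n_params = 3) {
  if (inherits(observed, "mode_counts")) {
    if (is.null(expected)) {
      if (is.null(observed$predicted))
        stop("counts table has no 'predicted' column; supply 'expected'")
      expected <- counts_vector(observed, "predicted")
    }
    observed <- counts_vector(observed)
  }
  if (is.null(names(observed)) || is.null(names(expected)))
    stop("'observed' and 'expected' must be named")
  if (!setequal(names(observed), names(expected)))
    stop("mismatched cell keys between observed and expected")
  expected <- expected[names(observed)]
  if (any(expected <= 0)) stop("all expected cells must be positive")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  contrib <- (observed - expected)^2 / expected
  df <- length(observed) - n_params
  if (df < 1) stop("degrees of freedom below 1: too few cells for n_params")
  stat <- sum(contrib)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 contributions = contrib),
            class = "od_gof")
}

#' @export
print.od_gof <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4f on %d df (p = %.4f)\n",
              x$statistic, x$df, x$p.value))
  cat("Per-cell contributions:\n")
  print(round(x$contributions, 4))
  invisible(x)
}

#' Goodness of fit of a fitted model
#'
#' Convenience wrapper: expected counts from the fit, observed from its data,
#' `n_params` from the number of free parameters.
#'
#' @param fit an [od_fit()].
#' @return an `"od_gof"` object.
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "od_fit"))
  pearson_chi_square(counts_vector(fit$counts), fitted(fit),
                     n_params = length(fit$parameters))
}
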