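#' Prior specification for the transition parameters
#'
#' Inverse-gamma priors on the transition intensities themselves (default
#' shape 0.001, scale 0.001, a standard vague choice for positive rates) and a
#' beta prior on each per-screen sensitivity (default beta(1, 1), i.e. uniform
#' on (0, 1)). A uniform-on-a-box alternative for the rates is provided to
#' check prior washout.
#'
#' @param rate_prior `"invgamma"` or `"uniform"`.
#' @param rate_shape,rate_scale inverse-gamma hyperparameters (both > 0).
#' @param rate_range support of the uniform alternative.
#' @param sens_shape1,sens_shape2 beta hyperparameters for sensitivities.
#' @return an object of class `"od_prior"`.
#' @export
od_prior <- function(rate_prior = c("invgamma", "uniform"),
                     rate_shape = 0.001, rate_scale = 0.001,
                     rate_range = c(1e-8, 5),
                     sens_shape1 = 1, sens_shape2 = 1) {
  rate_prior <- match.arg(rate_prior)
  if (rate_shape <= 0 || rate_scale <= 0)
    stop("inverse-gamma shape and scale must be positive")
  if (sens_shape1 <= 0 || sens_shape2 <= 0)
    stop("beta hyperparameters must be positive")
  structure(list(rate_prior = rate_prior, rate_shape = rate_shape,
                 rate_scale = rate_scale, rate_range = rate_range,
                 sens_shape1 = sens_shape1, sens_shape2 = sens_shape2),
            class = "od_prior")
}

.log_prior_rate <- function(lambda, prior) {
  if (prior$rate_prior == "invgamma")
    -(prior$rate_shape + 1) * log(lambda) - prior$rate_scale / lambda
  else if (lambda >= prior$rate_range[1] && lambda <= prior$rate_range[2]) 0
  else -Inf
}

#' MCMC sampler configuration
#'
#' Random-walk Metropolis settings. Proposals are normal on the transformed
#' scale (log for rates, logit for sensitivities); a single global step-size
#' multiplier is adapted during burn-in towards a ~25% acceptance rate and
#' then frozen, preserving detailed balance for the retained draws.
#'
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded per chain.
#' @param n_chains number of chains, run sequentially with seeds
#'   `seed, seed + 1, ...`.
#' @param seed mandatory random seed (recorded in the output).
#' @param proposal_scale relative per-parameter proposal standard deviations
#'   on the transformed scale, in the order (rates..., sensitivities...).
#' @param adapt adapt the global step size during burn-in.
#' @return an object of class `"od_mcmc_control"`.
#' @export
od_mcmc_control <- function(n_iter = 20000, n_burnin = 5000, n_chains = 2,
                            seed = 1, proposal_scale = NULL, adapt = TRUE) {
  if (n_burnin < 0 || n_iter <= n_burnin)
    stop("need n_iter > n_burnin >= 0")
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 proposal_scale = proposal_scale, adapt = isTRUE(adapt)),
            class = "od_mcmc_control")
}

# Free parameters of a variant, in estimation order.
free_parameters <- function(model) {
  if (is_adenoma_variant(model))
    stop("the adenoma-extended variants are not identifiable from cancer-only ",
         "detection-mode counts (no adenoma detection modes exist in the ",
         "table schema); supply their rates directly")
  c("lambda1", "lambda2", "sens_crc")
}

.theta_to_rates <- function(theta, pnames) {
  vals <- ifelse(grepl("^sens", pnames), stats::plogis(theta), exp(theta))
  do.call(rate_parameters, as.list(stats::setNames(vals, pnames)))
}

.rates_to_theta <- function(rates, pnames) {
  vapply(pnames, function(nm) {
    if (grepl("^sens", nm)) stats::qlogis(rates[[nm]]) else log(rates[[nm]])
  }, numeric(1))
}

#' Fit the overdiagnosis-embedded natural-history model
#'
#' Learns the transition intensities and the per-screen test sensitivity from
#' aggregate detection-mode counts, by maximum likelihood (`method = "mle"`) or
#' by random-walk Metropolis MCMC targeting likelihood x prior
#' (`method = "mcmc"`, the main analysis route; it also runs the MLE first for
#' starting values and for the reported maximised log-likelihood).
#'
#' The likelihood is multinomial over subject fates within each stratum (see
#' [log_likelihood()]); optimisation and sampling are on log-rates and
#' logit-sensitivities. The non-progressive fraction of the
#' overdiagnosis-embedded variant is fixed (default 0), not estimated: the
#' excess incidence of non-progressive disease is inferred downstream by the
#' digital-twin comparison, not by direct estimation.
#'
#' @param counts a [detection_mode_counts()] table. Must contain at least as
#'   many informative cancer-mode cells as free parameters, otherwise the
#'   model is unidentifiable and an error is raised.
#' @param design a [screening_design()].
#' @param model an [od_model()] (non-adenoma variants only).
#' @param mort a [mortality_schedule()].
#' @param method `"mle"` or `"mcmc"`.
#' @param prior an [od_prior()] (MCMC only).
#' @param control an [od_mcmc_control()] (MCMC only).
#' @param start optional [rate_parameters()] starting values.
#' @return an object of class `"od_fit"` with components `rates` (point
#'   estimates: posterior medians for MCMC, the MLE otherwise), `estimates`,
#'   `logLik`, `converged`, `draws` (post-burn-in matrix with iteration/chain
#'   columns, MCMC only), `summary` (posterior summary, MCMC only),
#'   `acceptance`, and the inputs. Standard methods (`print`, `summary`,
#'   `coef`, `logLik`, `confint`, `residuals`, `fitted`, `plot`, `simulate`,
#'   `predict`) are available.
#' @examples
#' \donttest{
#' fit <- od_fit(make_rct_fixture("funen"), rct_design("funen"),
#'               mort = mortality_schedule(0.01), method = "mle")
#' coef(fit)
#' mean_sojourn_time(fit$rates)
#' }
#' @export
od_fit <- function(counts, design, model = od_model("progressive_3state"),
                   mort = mortality_schedule(0.01),
                   method = c("mle", "mcmc"),
                   prior = od_prior(), control = od_mcmc_control(),
                   start = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "mode_counts"),
            inherits(design, "screening_design"))
  pnames <- free_parameters(model)
  informative <- intersect(counts$mode, CRC_MODES)
  if (length(informative) < length(pnames))
    stop("unidentifiable: ", length(informative), " informative cancer-mode ",
         "cell(s) for ", length(pnames), " free parameters")

  ll_fun <- function(theta) {
    r <- tryCatch(.theta_to_rates(theta, pnames), error = function(e) NULL)
    if (is.null(r)) return(-Inf)
    pr <- tryCatch(mode_probabilities(model, r, mort, design),
                   error = function(e) NULL)
    if (is.null(pr)) return(-Inf)
    suppressWarnings(log_likelihood(counts, pr))
  }

  if (is.null(start)) {
    v <- counts_vector(counts)
    crude <- sum(v[intersect(names(v), CRC_MODES)]) /
      (sum(stratum_sizes(counts)) * design$followup)
    start <- do.call(rate_parameters, as.list(stats::setNames(
      c(max(crude, 1e-6), 0.4, 0.7), pnames)))
  }
  theta0 <- .rates_to_theta(start, pnames)

  opt <- stats::optim(theta0, ll_fun, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-12))
  opt <- stats::optim(opt$par, ll_fun, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-12))
  converged <- opt$convergence == 0
  if (!converged)
    warning("maximum-likelihood optimisation did not converge (code ",
            opt$convergence, ")")
  mle_rates <- .theta_to_rates(opt$par, pnames)

  out <- list(method = method, parameters = pnames, rates = mle_rates,
              estimates = stats::setNames(
                vapply(pnames, function(n) mle_rates[[n]], numeric(1)), pnames),
              logLik = opt$value, converged = converged,
              counts = counts, design = design, model = model, mort = mort,
              call = match.call())

  if (method == "mcmc") {
    mc <- .run_mcmc(ll_fun, opt$par, pnames, prior, control)
    med <- apply(mc$draws[, pnames, drop = FALSE], 2, stats::median)
    out$rates <- .theta_to_rates(
      .rates_to_theta(do.call(rate_parameters, as.list(med)), pnames), pnames)
    out$estimates <- med
    out$draws <- mc$draws
    out$summary <- mc$summary
    out$acceptance <- mc$acceptance
    out$prior <- prior
    out$control <- control
    out$seed <- control$seed
  }
  class(out) <- "od_fit"
  out
}

# Random-walk Metropolis on the transformed scale. Deterministic under the
# control seed; the caller's RNG state is restored afterwards.
.run_mcmc <- function(ll_fun, theta_start, pnames, prior, control) {
  logpost <- function(theta) {
    ll <- ll_fun(theta)
    if (!is.finite(ll)) return(-Inf)
    lp <- ll
    for (i in seq_along(pnames)) {
      if (grepl("^sens", pnames[i])) {
        s <- stats::plogis(theta[i])
        lp <- lp + stats::dbeta(s, prior$sens_shape1, prior$sens_shape2,
                                log = TRUE) + log(s) + log1p(-s)
      } else {
        lam <- exp(theta[i])
        lp <- lp + .log_prior_rate(lam, prior) + theta[i]  # Jacobian
      }
    }
    lp
  }

  rel <- control$proposal_scale
  if (is.null(rel)) rel <- rep(0.08, length(pnames))
  npar <- length(pnames)
  keep_total <- (control$n_iter - control$n_burnin) * control$n_chains
  draws <- matrix(NA_real_, keep_total, npar + 2,
                  dimnames = list(NULL, c("iteration", "chain", pnames)))
  acc_post <- 0; n_post <- 0
  row <- 0

  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  for (ch in seq_len(control$n_chains)) {
    set.seed(control$seed + ch - 1L)
    theta <- theta_start +
      if (ch == 1) 0 else stats::rnorm(npar, 0, 0.05)
    lp <- logpost(theta)
    step <- 1
    batch_acc <- 0
    for (it in seq_len(control$n_iter)) {
      prop <- theta + stats::rnorm(npar, 0, rel * step)
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop
        batch_acc <- batch_acc + 1
        if (it > control$n_burnin) acc_post <- acc_post + 1
      }
      if (it > control$n_burnin) n_post <- n_post + 1
      if (control$adapt && it <= control$n_burnin && it %% 100 == 0) {
        step <- step * exp((batch_acc / 100 - 0.25))
        batch_acc <- 0
      }
      if (it > control$n_burnin) {
        row <- row + 1
        vals <- ifelse(grepl("^sens", pnames), stats::plogis(theta),
                       exp(theta))
        draws[row, ] <- c(it - control$n_burnin, ch, vals)
      }
    }
  }
  acc_rate <- acc_post / n_post
  if (acc_rate < 0.05 || acc_rate > 0.8)
    warning(sprintf(
      "post-adaptation acceptance rate %.2f outside [0.05, 0.8]; adjust ",
      acc_rate), "'proposal_scale' or lengthen burn-in")

  summ <- do.call(rbind, lapply(pnames, function(nm) {
    x <- draws[, nm]
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(parameter = nm, mean = mean(x), median = q[2],
               q2.5 = q[1], q97.5 = q[3], ess = effective_size(x),
               stringsAsFactors = FALSE)
  }))
  summ$acceptance <- acc_rate
  list(draws = draws, summary = summ, acceptance = acc_rate)
}

# Effective sample size from the initial positive autocorrelation sequence.
effective_size <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) { if (r < 0.05) break; s <- s + r }
  max(1, n / (1 + 2 * s))
}

#' Equal-tailed credible interval from posterior draws
#'
#' Type-7 (linear interpolation) quantiles, the documented convention for all
#' interval endpoints in this package.
#'
#' @param samples numeric vector or matrix of post-burn-in draws (columns =
#'   parameters). At least 100 draws are required.
#' @param level interval probability.
#' @return for a vector, `c(lower, upper)`; for a matrix, a two-column matrix
#'   with one row per parameter.
#' @examples
#' credible_interval(1:100, level = 0.5)   # 25.75, 75.25
#' @export
credible_interval <- function(samples, level = 0.95) {
  if (is.matrix(samples)) {
    out <- t(apply(samples, 2, credible_interval, level = level))
    colnames(out) <- c("lower", "upper")
    return(out)
  }
  if (length(samples) < 100)
    stop("need at least 100 draws for a credible interval")
  a <- (1 - level) / 2
  stats::setNames(stats::quantile(samples, c(a, 1 - a), names = FALSE,
                                  type = 7), c("lower", "upper"))
}

#' Write posterior draws as a flat CSV
#'
#' Columns: iteration, chain, one column per parameter.
#'
#' @param fit an MCMC [od_fit()].
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "od_fit"))
  if (is.null(fit$draws)) stop("fit has no posterior draws (method = 'mle')")
  utils::write.csv(as.data.frame(fit$draws), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.od_fit <- function(x, digits = 4, ...) {
  cat("Overdiagnosis-embedded natural-history model fit (",
      x$model$variant, ", ", toupper(x$method), ")\n", sep = "")
  if (x$method == "mcmc") {
    s <- x$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-10s %.5g  (95%% CrI %.5g, %.5g)\n", s$parameter[i],
                  s$median[i], s$q2.5[i], s$q97.5[i]))
    cat(sprintf("  acceptance rate %.2f; seed %d\n", x$acceptance, x$seed))
  } else {
    for (nm in x$parameters)
      cat(sprintf("  %-10s %.5g\n", nm, x$estimates[[nm]]))
  }
  cat(sprintf("  mean sojourn time %.3g y; logLik %.3f%s\n",
              mean_sojourn_time(x$rates), x$logLik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.od_fit <- function(object, ...) object$estimates

#' @export
logLik.od_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$parameters),
            nobs = sum(counts_vector(object$counts)), class = "logLik")
}

#' @export
confint.od_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$draws))
    stop("credible intervals require method = 'mcmc'")
  m <- object$draws[, object$parameters, drop = FALSE]
  if (!missing(parm)) m <- m[, parm, drop = FALSE]
  credible_interval(m, level = level)
}

#' @export
summary.od_fit <- function(object, ...) {
  out <- list(fit = object,
              expected = fitted(object),
              observed = counts_vector(object$counts))
  class(out) <- "summary.od_fit"
  out
}

#' @export
print.summary.od_fit <- function(x, ...) {
  print(x$fit)
  cat("\nObserved vs expected counts by detection mode:\n")
  print(data.frame(observed = x$observed,
                   expected = round(x$expected[names(x$observed)], 2)))
  invisible(x)
}

#' @export
fitted.od_fit <- function(object, ...) {
  pr <- mode_probabilities(object$model, object$rates, object$mort,
                           object$design)
  ns <- stratum_sizes(object$counts)
  expected_mode_counts(pr, ns[["participant"]], ns[["refuser"]],
                       modes = object$counts$mode)
}

#' @export
residuals.od_fit <- function(object, type = c("pearson"), ...) {
  type <- match.arg(type)
  o <- counts_vector(object$counts)
  e <- fitted(object)[names(o)]
  (o - e) / sqrt(e)
}

#' @export
plot.od_fit <- function(x, ...) {
  o <- counts_vector(x$counts)
  e <- fitted(x)[names(o)]
  crc <- intersect(names(o), CRC_MODES)
  m <- rbind(observed = o[crc], expected = e[crc])
  graphics::barplot(m, beside = TRUE, las = 2, cex.names = 0.7,
                    legend.text = rownames(m),
                    main = "Cancer counts by detection mode",
                    ylab = "count", ...)
  invisible(x)
}

#' @export
simulate.od_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(i) {
    cfg <- simulation_config(
      n = round(sum(stratum_sizes(object$counts))),
      rates = object$rates, mort = object$mort,
      design = object$design, model = object$model, seed = seed + i - 1L)
    simulate_cohort(cfg)$counts
  })
}

#' Predict the digitally screened twin from a fitted model
#'
#' Applies the learned parameters to a comparator population as if it had been
#' screened; see [predict_screened_twin()].
#'
#' @param object an [od_fit()].
#' @param cohort_size comparator population size (defaults to the fitting
#'   design's cohort size).
#' @param followup horizon in years (defaults to the fitting design's).
#' @param design optionally a different [screening_design()].
#' @param ... unused.
#' @return a `"twin_prediction"` object.
#' @export
predict.od_fit <- function(object, cohort_size = NULL, followup = NULL,
                           design = NULL, ...) {
  d <- if (is.null(design)) object$design else design
  if (is.null(cohort_size)) cohort_size <- d$cohort_size
  if (is.null(followup)) followup <- d$followup
  predict_screened_twin(object$model, object$rates, object$mort, d,
                        cohort_size = cohort_size, followup = followup)
}
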