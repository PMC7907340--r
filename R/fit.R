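#' Fit the Rogers random predator equation by maximum likelihood
#'
#' Estimates the attack coefficient \eqn{a} and handling time \eqn{h} of a
#' Type II functional response from depletion trials, by maximising a
#' binomial log-likelihood in which the success probability of each trial is
#' the Rogers expected proportion consumed,
#' \eqn{p_i = N_e(a, h, T, N_{0,i}) / N_{0,i}} (clamped away from 0 and 1).
#' Prey that died without signs of predation (`dead_unconsumed`) are treated
#' as background mortality: they are excluded from the consumed count and no
#' adjustment is made to the offered count. Trials flagged `excluded = TRUE`
#' never enter the fit.
#'
#' Optimisation is on \eqn{(\log a, \log h)} (boundary-safe), with
#' multi-start: `n_starts` jittered starting points around a moment-based
#' initial guess, deterministic under `seed`, keeping the best likelihood.
#' Standard errors come from the inverse observed information (numerical
#' Hessian on the natural scale); `z = estimate / SE` with two-sided normal
#' p-values.
#'
#' The maximum feeding rate is reported under both conventions in use:
#' per experiment, \eqn{1/(T h)}, and per day, \eqn{1/h}.
#'
#' @param trials data.frame of trials with columns `density_offered`,
#'   `consumed`, and optionally `duration_days`, `dead_unconsumed`,
#'   `excluded` (see [read_trials()] for the schema).
#' @param T trial duration in days; defaults to the (single) value of
#'   `duration_days` in `trials`.
#' @param n_starts number of jittered optimiser starts (default 5).
#' @param seed integer seed for the start jitter (default 1; the fit itself
#'   is deterministic given the data).
#' @return an object of class `rogers_fit` with components `coefficients`
#'   (`a`, `h`), `se`, `z`, `p`, `vcov`, `logLik`, `T`, `n_trials`,
#'   `converged`, `max_feeding_rate` (\eqn{1/(Th)}),
#'   `max_feeding_rate_per_day` (\eqn{1/h}) and the retained `data`.
#'   Methods: `print`, `summary`, `coef`, `vcov`, `logLik`, `confint`,
#'   `predict`, `fitted`, `residuals`, `simulate`, `plot`.
#' @examples
#' trials <- generate_trials(sim_config(a = 0.85, h = 0.258, seed = 7))
#' fit <- fit_rogers(trials)
#' summary(fit)
#' @seealso [compare_fits()], [bootstrap_fit()], [classify_fr_type()]
#' @export
fit_rogers <- function(trials, T = NULL, n_starts = 5, seed = 1) {
  d <- usable_trials(trials)
  if (is.null(T)) {
    T <- unique(d$duration_days)
    if (length(T) != 1L || !is.finite(T)) {
      stop("`T` not given and `duration_days` is absent or non-unique")
    }
  }
  check_scalar(T, "T", min = 0, strict = TRUE)
  n_starts <- check_count(n_starts, "n_starts", min = 1L)
  if (length(unique(d$density_offered)) < 3L) {
    stop("need trials at >= 3 distinct prey densities")
  }
  if (sum(d$consumed) == 0) stop("total consumption is zero; cannot fit")
  if (all(d$consumed == 0L | d$consumed == d$density_offered)) {
    stop("all-or-nothing consumption in every trial: ",
         "likelihood maximised on the boundary, no finite estimates")
  }

  dens <- d$density_offered
  cons <- d$consumed
  negll <- function(lp) {
    a <- exp(lp[1]); h <- exp(lp[2])
    p <- rogers_expected_consumption(a, h, T, dens) / dens
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(dbinom(cons, dens, p, log = TRUE))
  }

  # moment-based start: initial slope for a, asymptote for h
  pbar <- tapply(cons / dens, dens, mean)
  lowp <- pbar[[1]]
  a0 <- max(-log(max(1 - lowp, 0.05)) / T, 0.01)
  top <- max(tapply(cons, dens, mean))
  h0 <- if (top > 0) T / (2 * top) else 1
  starts <- with_seed(seed, {
    jit <- matrix(rnorm(2L * n_starts, sd = 0.5), ncol = 2L)
    jit[1L, ] <- 0
    sweep(jit, 2L, log(c(a0, h0)), `+`)
  })

  best <- NULL
  for (i in seq_len(n_starts)) {
    o <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B",
            lower = c(-15, -15), upper = c(8, 8)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, coefficients = c(a = NA, h = NA),
                          diagnostics = "all optimiser starts failed"),
                     class = "rogers_fit"))
  }
  est <- exp(best$par)
  names(est) <- c("a", "h")
  conv <- best$convergence == 0L
  at_bound <- any(abs(best$par - 8) < 1e-4) || any(abs(best$par + 15) < 1e-4)
  if (at_bound) conv <- FALSE

  V <- matrix(NA_real_, 2, 2, dimnames = list(names(est), names(est)))
  se <- c(a = NA_real_, h = NA_real_)
  H <- tryCatch(
    optimHess(est, function(p) negll(log(pmax(p, 1e-12)))),
    error = function(e) NULL)
  if (!is.null(H)) {
    Vt <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vt) && all(diag(Vt) > 0)) {
      V[] <- Vt
      se <- sqrt(diag(Vt))
      names(se) <- names(est)
    }
  }
  z <- est / se
  p <- 2 * pnorm(-abs(z))

  structure(list(
    coefficients = est, se = se, z = z, p = p, vcov = V,
    logLik = -best$value, T = T, n_trials = nrow(d),
    converged = conv,
    max_feeding_rate = 1 / (T * est[["h"]]),
    max_feeding_rate_per_day = 1 / est[["h"]],
    data = d, call = match.call()
  ), class = "rogers_fit")
}

# validate the trial schema and drop excluded rows
usable_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("`trials` must be a data.frame")
  need <- c("density_offered", "consumed")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("`trials` is missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- trials
  if (!"dead_unconsumed" %in% names(d)) d$dead_unconsumed <- 0L
  if (!"duration_days" %in% names(d)) d$duration_days <- NA_real_
  if ("excluded" %in% names(d)) d <- d[!isTRUE_vec(d$excluded), , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable (non-excluded) trials")
  with(d, {
    if (any(density_offered < 0) || any(consumed < 0) || any(dead_unconsumed < 0))
      stop("negative counts in trials")
    if (any(consumed + dead_unconsumed > density_offered))
      stop("consumed + dead_unconsumed exceeds density_offered")
  })
  d
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.rogers_fit <- function(x, digits = 4, ...) {
  cat("Rogers random predator fit\n")
  if (!isTRUE(x$converged)) cat("  ** optimiser did not converge **\n")
  cat(sprintf("  a = %s (SE %s) /day,  h = %s (SE %s) day/prey\n",
              format(x$coefficients[["a"]], digits = digits),
              format(x$se[["a"]], digits = digits),
              format(x$coefficients[["h"]], digits = digits),
              format(x$se[["h"]], digits = digits)))
  cat(sprintf("  max feeding rate: %s prey/experiment (T = %g d), %s prey/day\n",
              format(x$max_feeding_rate, digits = digits), x$T,
              format(x$max_feeding_rate_per_day, digits = digits)))
  invisible(x)
}

#' @export
summary.rogers_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p)
  structure(list(coefficients = tab, logLik = object$logLik, T = object$T,
                 n_trials = object$n_trials, converged = object$converged,
                 max_feeding_rate = object$max_feeding_rate,
                 max_feeding_rate_per_day = object$max_feeding_rate_per_day),
            class = "summary.rogers_fit")
}

#' @export
print.summary.rogers_fit <- function(x, ...) {
  cat("Rogers random predator fit (binomial likelihood)\n")
  cat(sprintf("%d trials, T = %g day(s), logLik = %.3f%s\n\n", x$n_trials,
              x$T, x$logLik, if (x$converged) "" else "  [not converged]"))
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nMax feeding rate: %.4g prey/experiment (1/Th), %.4g prey/day (1/h)\n",
              x$max_feeding_rate, x$max_feeding_rate_per_day))
  invisible(x)
}

#' @export
coef.rogers_fit <- function(object, ...) object$coefficients

#' @export
vcov.rogers_fit <- function(object, ...) object$vcov

#' @export
logLik.rogers_fit <- function(object, ...) {
  structure(object$logLik, df = 2L, nobs = object$n_trials, class = "logLik")
}

#' @export
confint.rogers_fit <- function(object, parm = c("a", "h"), level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  zq <- qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[parm]
  se <- object$se[parm]
  out <- cbind(est - zq * se, est + zq * se)
  colnames(out) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                 trim = TRUE), " %")
  out
}

#' Predicted consumption from a fitted Rogers model
#'
#' @param object a `rogers_fit`.
#' @param newdata data.frame with a `density_offered` column, or a numeric
#'   vector of densities; defaults to the fitted data.
#' @param boot optional [bootstrap_fit()] ensemble; when supplied, percentile
#'   confidence limits are attached.
#' @param level confidence level for bootstrap limits.
#' @param ... unused.
#' @return numeric vector of expected consumption, or (with `boot`) a
#'   data.frame with columns `density_offered`, `fit`, `lwr`, `upr`.
#' @export
predict.rogers_fit <- function(object, newdata = NULL, boot = NULL,
                               level = 0.95, ...) {
  dens <- if (is.null(newdata)) {
    object$data$density_offered
  } else if (is.data.frame(newdata)) {
    newdata$density_offered
  } else {
    newdata
  }
  if (is.null(dens)) stop("`newdata` must supply `density_offered`")
  fit <- rogers_expected_consumption(object$coefficients[["a"]],
                                     object$coefficients[["h"]],
                                     object$T, dens)
  if (is.null(boot)) return(fit)
  stopifnot(inherits(boot, "fr_boot"))
  band <- predict(boot, densities = dens, level = level)
  data.frame(density_offered = dens, fit = fit,
             lwr = band$lwr, upr = band$upr)
}

#' @export
fitted.rogers_fit <- function(object, ...) predict(object)

#' @export
residuals.rogers_fit <- function(object,
                                 type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$data$consumed - mu
  if (type == "pearson") {
    n0 <- object$data$density_offered
    p <- pmin(pmax(mu / n0, 1e-9), 1 - 1e-9)
    r <- r / sqrt(n0 * p * (1 - p))
  }
  r
}

#' Simulate trial tables from a fitted Rogers model
#'
#' Parametric resampling: draws new consumed counts at the fitted parameter
#' values and the observed density design (binomial around the Rogers mean).
#'
#' @param object a `rogers_fit`.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` data.frames shaped like the fitted data.
#' @export
simulate.rogers_fit <- function(object, nsim = 1, seed = NULL, ...) {
  nsim <- check_count(nsim, "nsim", min = 1L)
  a <- object$coefficients[["a"]]
  h <- object$coefficients[["h"]]
  dens <- object$data$density_offered
  p <- pmin(pmax(rogers_expected_consumption(a, h, object$T, dens) / dens,
                 0), 1)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      out <- object$data
      out$consumed <- rbinom(length(dens), dens, p)
      out
    })
  })
}

#' Plot a fitted functional response curve
#'
#' Draws mean consumption per density, the fitted Rogers curve, and (when a
#' bootstrap ensemble is supplied) a shaded percentile confidence band.
#'
#' @param x a `rogers_fit`.
#' @param boot optional [bootstrap_fit()] ensemble for the band.
#' @param level band level (default 0.95).
#' @param n_grid curve resolution.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rogers_fit <- function(x, boot = NULL, level = 0.95, n_grid = 100, ...) {
  dens <- x$data$density_offered
  grid <- seq(min(dens), max(dens), length.out = n_grid)
  curve_y <- rogers_expected_consumption(x$coefficients[["a"]],
                                         x$coefficients[["h"]], x$T, grid)
  ylim <- range(0, x$data$consumed, curve_y)
  plot(dens, x$data$consumed, xlab = "Prey density offered",
       ylab = "Prey consumed", ylim = ylim,
       pch = 16, col = grDevices::adjustcolor("black", 0.4), ...)
  if (!is.null(boot)) {
    band <- predict(boot, densities = grid, level = level)
    graphics::polygon(c(grid, rev(grid)), c(band$lwr, rev(band$upr)),
                      border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.3))
  }
  graphics::lines(grid, curve_y, lwd = 2)
  mean_y <- tapply(x$data$consumed, dens, mean)
  graphics::points(as.numeric(names(mean_y)), mean_y, pch = 17)
  invisible(x)
}
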