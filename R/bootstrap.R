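#' Nonparametric bootstrap of a Rogers functional response fit
#'
#' Resamples trials (rows) with replacement, refits the Rogers model on each
#' resample, and summarises the ensemble: percentile confidence bands for
#' the predicted consumption curve on a density grid, and the mean and
#' standard error of the maximum feeding rate across resamples. With the
#' conventional `n_boot = 2000` the bands visualise model variability; a
#' small ensemble (`n_boot = 30`) is the usual way to obtain a mean and SE
#' of the maximum feeding rate for impact-potential calculations.
#'
#' @param fit a [fit_rogers()] object (the data and `T` are taken from it),
#'   or a trials data.frame (then `T` may be needed).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed; required for a reproducible ensemble.
#' @param T trial duration, only used when `fit` is a data.frame.
#' @param stratified if `TRUE`, resampling is stratified by density (each
#'   density keeps its replicate count); default `FALSE`, plain row
#'   resampling.
#' @param grid density grid for the confidence bands; defaults to 50 points
#'   spanning the observed densities, plus the observed densities.
#' @param level band level (default 0.95).
#' @return object of class `fr_boot` with components `a`, `h` (per-resample
#'   estimates, `NA` for non-converged resamples), `n_boot`, `n_failed`,
#'   `band` (data.frame `density_offered`, `lwr`, `upr`), `max_feeding_rate`
#'   and `max_feeding_rate_per_day` (each a list with `mean`, `se`), and the
#'   point `fit`. Methods: `print`, `summary`, `predict`.
#' @examples
#' trials <- generate_trials(sim_config(a = 0.85, h = 0.258, seed = 3))
#' fit <- fit_rogers(trials)
#' bt <- bootstrap_fit(fit, n_boot = 30, seed = 9)
#' summary(bt)
#' @export
bootstrap_fit <- function(fit, n_boot = 2000, seed = NULL, T = NULL,
                          stratified = FALSE, grid = NULL, level = 0.95) {
  if (is.data.frame(fit)) fit <- fit_rogers(fit, T = T)
  stopifnot(inherits(fit, "rogers_fit"))
  n_boot <- check_count(n_boot, "n_boot", min = 2L)
  d <- fit$data
  n <- nrow(d)
  dens <- d$density_offered
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(min(dens), max(dens), length.out = 50), dens)))
  }

  strata <- if (stratified) split(seq_len(n), dens) else NULL
  start <- log(pmax(coef(fit), 1e-8))

  ab <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2L)
    for (b in seq_len(n_boot)) {
      idx <- if (stratified) {
        unlist(lapply(strata, function(i) i[sample.int(length(i),
                                                       replace = TRUE)]),
               use.names = FALSE)
      } else {
        sample.int(n, replace = TRUE)
      }
      rb <- refit_quick(dens[idx], d$consumed[idx], fit$T, start)
      if (!is.null(rb)) out[b, ] <- rb
    }
    out
  })

  ok <- stats::complete.cases(ab)
  n_failed <- sum(!ok)
  if (n_failed > n_boot / 2) {
    stop("bootstrap failed: ", n_failed, " of ", n_boot,
         " resamples did not converge")
  }

  curves <- vapply(which(ok), function(b) {
    rogers_expected_consumption(ab[b, 1], ab[b, 2], fit$T, grid)
  }, numeric(length(grid)))
  curves <- matrix(curves, nrow = length(grid))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(curves, 1L, quantile, probs = probs, names = FALSE)
  band <- data.frame(density_offered = grid, lwr = qs[1L, ], upr = qs[2L, ])

  mfr_day <- 1 / ab[ok, 2]
  mfr_exp <- 1 / (fit$T * ab[ok, 2])
  summ <- function(x) list(mean = mean(x), se = sd(x) / sqrt(length(x)))

  structure(list(
    a = ab[, 1], h = ab[, 2], n_boot = n_boot, n_failed = n_failed,
    band = band, level = level,
    max_feeding_rate = summ(mfr_exp),
    max_feeding_rate_per_day = summ(mfr_day),
    stratified = stratified, seed = seed, fit = fit
  ), class = "fr_boot")
}

# single-start refit used inside the bootstrap loop; returns c(a, h) or NULL
refit_quick <- function(dens, cons, T, start) {
  if (sum(cons) == 0) return(NULL)
  negll <- function(lp) {
    p <- rogers_expected_consumption(exp(lp[1]), exp(lp[2]), T, dens) / dens
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(dbinom(cons, dens, p, log = TRUE))
  }
  o <- tryCatch(
    optim(start, negll, method = "L-BFGS-B", lower = c(-15, -15),
          upper = c(8, 8)),
    error = function(e) NULL)
  if (is.null(o) || o$convergence != 0L) return(NULL)
  exp(o$par)
}

#' @export
print.fr_boot <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: %d resamples (%d failed)%s\n",
              x$n_boot, x$n_failed,
              if (x$stratified) ", stratified by density" else ""))
  cat(sprintf("  max feeding rate: %.4g +/- %.4g prey/day (1/h)\n",
              x$max_feeding_rate_per_day$mean, x$max_feeding_rate_per_day$se))
  cat(sprintf("                    %.4g +/- %.4g prey/experiment (1/Th)\n",
              x$max_feeding_rate$mean, x$max_feeding_rate$se))
  invisible(x)
}

#' @export
summary.fr_boot <- function(object, ...) {
  ok <- !is.na(object$a)
  out <- list(
    n_boot = object$n_boot, n_failed = object$n_failed,
    a = quantile(object$a[ok], c(0.025, 0.5, 0.975)),
    h = quantile(object$h[ok], c(0.025, 0.5, 0.975)),
    max_feeding_rate = object$max_feeding_rate,
    max_feeding_rate_per_day = object$max_feeding_rate_per_day)
  class(out) <- "summary.fr_boot"
  out
}

#' @export
print.summary.fr_boot <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble (%d resamples, %d failed)\n",
              x$n_boot, x$n_failed))
  cat("  a  2.5/50/97.5%:", paste(signif(x$a, 4), collapse = " / "), "\n")
  cat("  h  2.5/50/97.5%:", paste(signif(x$h, 4), collapse = " / "), "\n")
  cat(sprintf("  max feeding rate/day: %.4g +/- %.4g\n",
              x$max_feeding_rate_per_day$mean, x$max_feeding_rate_per_day$se))
  invisible(x)
}

#' Percentile band of a bootstrap ensemble at given densities
#'
#' @param object an `fr_boot` ensemble.
#' @param densities densities at which to evaluate the band; defaults to the
#'   stored grid.
#' @param level band level.
#' @param ... unused.
#' @return data.frame with `density_offered`, `lwr`, `upr`.
#' @export
predict.fr_boot <- function(object, densities = NULL, level = NULL, ...) {
  if (is.null(densities) && (is.null(level) || level == object$level)) {
    return(object$band)
  }
  if (is.null(densities)) densities <- object$band$density_offered
  if (is.null(level)) level <- object$level
  ok <- !is.na(object$a)
  curves <- vapply(which(ok), function(b) {
    rogers_expected_consumption(object$a[b], object$h[b], object$fit$T,
                                densities)
  }, numeric(length(densities)))
  curves <- matrix(curves, nrow = length(densities))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(curves, 1L, quantile, probs = probs, names = FALSE)
  data.frame(density_offered = densities, lwr = qs[1L, ], upr = qs[2L, ])
}
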