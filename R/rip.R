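#' Per-capita effect and abundance summary for one predator group
#'
#' Container pairing a group's maximum feeding rate (mean and SE, typically
#' the per-day `1/h` bootstrap summary from [bootstrap_fit()]) with its
#' field abundance (mean and SE in ind/m^2, typically from
#' [summarize_abundance()]).
#'
#' @param label group label.
#' @param fr_mean,fr_se maximum feeding rate mean (> 0) and SE (>= 0),
#'   prey per day.
#' @param abundance_mean,abundance_se abundance mean (> 0) and SE (>= 0),
#'   ind/m^2.
#' @return object of class `effect_summary`.
#' @examples
#' effect_summary("large invader", 1.099, 0.047, 14.760, 2.955)
#' @export
effect_summary <- function(label, fr_mean, fr_se,
                           abundance_mean, abundance_se) {
  check_scalar(fr_mean, "fr_mean", min = 0, strict = TRUE)
  check_scalar(fr_se, "fr_se", min = 0)
  check_scalar(abundance_mean, "abundance_mean", min = 0, strict = TRUE)
  check_scalar(abundance_se, "abundance_se", min = 0)
  structure(list(label = label, fr_mean = fr_mean, fr_se = fr_se,
                 abundance_mean = abundance_mean,
                 abundance_se = abundance_se),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%s: max feeding rate %.4g +/- %.4g prey/day, abundance %.4g +/- %.4g ind/m^2\n",
              x$label, x$fr_mean, x$fr_se, x$abundance_mean, x$abundance_se))
  invisible(x)
}

#' Relative Impact Potential of one predator group over another
#'
#' The Relative Impact Potential (RIP) combines per-capita effect and
#' numerical-response proxy: \eqn{RIP = (FR_A N_A) / (FR_B N_B)}, the ratio
#' of (maximum feeding rate x field abundance) of group A to group B. A RIP
#' above 1 predicts a greater population-level impact of A than of B.
#'
#' Uncertainty is propagated by Monte Carlo: each of the four quantities is
#' drawn independently from its summary distribution and the ratio computed
#' per draw. With `law = "normal"` (default) draws are normal with the
#' given mean and SE, restricted to positive support by rejection
#' resampling (a warning reports the rejection count when more than 1\% of
#' draws had to be redrawn). With `law = "lognormal"` draws are lognormal
#' with moment-matched mean and SE -- positive by construction and
#' right-skewed, which reflects how ratio summaries of this kind are
#' usually reported.
#'
#' @param effect_A,effect_B [effect_summary()] objects (A is the focal
#'   group, B the comparator in the denominator).
#' @param n_draws Monte Carlo draws (>= 10000; default 1e5).
#' @param seed optional integer seed.
#' @param law `"normal"` (truncated by rejection) or `"lognormal"`.
#' @return object of class `rip`: list with `labels`, `n_draws`,
#'   `rip_mean`, `rip_median`, `CI60` and `CI80` (central percentile
#'   intervals), `prob_exceeds_one` (percent of draws > 1), `quantiles`
#'   (1--99\% grid), `n_rejected`, `law`.
#' @examples
#' A <- effect_summary("invader", 1.099, 0.047, 14.760, 2.955)
#' B <- effect_summary("native", 0.157, 0.012, 17.378, 4.486)
#' rip_score(A, B, seed = 1)
#' @export
rip_score <- function(effect_A, effect_B, n_draws = 1e5, seed = NULL,
                      law = c("normal", "lognormal")) {
  stopifnot(inherits(effect_A, "effect_summary"),
            inherits(effect_B, "effect_summary"))
  law <- match.arg(law)
  n_draws <- check_count(n_draws, "n_draws", min = 10000L)

  rejected <- 0L
  draw <- function(mean, se) {
    if (se == 0) return(rep(mean, n_draws))
    if (law == "lognormal") {
      s2 <- log(1 + (se / mean)^2)
      return(rlnorm(n_draws, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2)))
    }
    x <- rnorm(n_draws, mean, se)
    bad <- x <= 0
    while (any(bad)) {
      rejected <<- rejected + sum(bad)
      x[bad] <- rnorm(sum(bad), mean, se)
      bad <- x <= 0
    }
    x
  }

  draws <- with_seed(seed, {
    (draw(effect_A$fr_mean, effect_A$fr_se) *
       draw(effect_A$abundance_mean, effect_A$abundance_se)) /
      (draw(effect_B$fr_mean, effect_B$fr_se) *
         draw(effect_B$abundance_mean, effect_B$abundance_se))
  })
  if (rejected > 0.01 * n_draws) {
    warning("rejection resampling redrew ", rejected,
            " non-positive values (> 1% of draws); a normal law may be a ",
            "poor summary for these means and SEs")
  }

  qs <- quantile(draws, c(0.01, 0.05, 0.1, 0.2, 0.25, 0.5, 0.75, 0.8, 0.9,
                          0.95, 0.99), names = TRUE)
  structure(list(
    labels = c(A = effect_A$label, B = effect_B$label),
    n_draws = n_draws,
    rip_mean = mean(draws),
    rip_median = unname(qs[["50%"]]),
    CI60 = unname(quantile(draws, c(0.2, 0.8))),
    CI80 = unname(quantile(draws, c(0.1, 0.9))),
    prob_exceeds_one = 100 * mean(draws > 1),
    quantiles = qs,
    n_rejected = rejected,
    law = law, seed = seed
  ), class = "rip")
}

#' @export
print.rip <- function(x, digits = 4, ...) {
  cat(sprintf("Relative Impact Potential: %s vs %s (%s draws, %s law)\n",
              x$labels[["A"]], x$labels[["B"]],
              format(x$n_draws, big.mark = ","), x$law))
  cat(sprintf("  mean RIP = %s (median %s)\n",
              format(x$rip_mean, digits = digits),
              format(x$rip_median, digits = digits)))
  cat(sprintf("  60%% CI: %s - %s,  80%% CI: %s - %s\n",
              format(x$CI60[1L], digits = digits),
              format(x$CI60[2L], digits = digits),
              format(x$CI80[1L], digits = digits),
              format(x$CI80[2L], digits = digits)))
  cat(sprintf("  P(RIP > 1) = %.3f%%\n", x$prob_exceeds_one))
  invisible(x)
}

#' Biplot data for impact-potential comparisons
#'
#' Lays out each group's per-capita effect (x: maximum feeding rate, mean
#' +/- SE) against its abundance (y: mean +/- SE), with iso-impact curves
#' (hyperbolae of constant feeding rate x abundance) through each group's
#' point. Groups further toward the upper right have higher impact
#' potential; two groups on the same isocline have equal FR x abundance.
#'
#' @param effects list of [effect_summary()] objects (>= 2).
#' @param n_grid points per isocline.
#' @return object of class `rip_biplot`: list with `points` (data.frame
#'   `label`, `fr_mean`, `fr_se`, `abundance_mean`, `abundance_se`,
#'   `impact`) and `isoclines` (data.frame `label`, `fr`, `abundance`).
#'   A `plot` method draws the biplot with base graphics.
#' @examples
#' eff <- list(effect_summary("A", 1.1, 0.05, 15, 3),
#'             effect_summary("B", 0.16, 0.01, 17, 4.5))
#' rip_biplot_data(eff)
#' @export
rip_biplot_data <- function(effects, n_grid = 100) {
  if (inherits(effects, "effect_summary")) effects <- list(effects)
  if (length(effects) < 2L) stop("need >= 2 effect summaries")
  stopifnot(all(vapply(effects, inherits, logical(1), "effect_summary")))
  pts <- do.call(rbind, lapply(effects, function(e) {
    data.frame(label = e$label, fr_mean = e$fr_mean, fr_se = e$fr_se,
               abundance_mean = e$abundance_mean,
               abundance_se = e$abundance_se,
               impact = e$fr_mean * e$abundance_mean,
               stringsAsFactors = FALSE)
  }))
  xr <- range(pts$fr_mean)
  xs <- seq(max(min(xr) / 3, min(xr) * 0.2), max(xr) * 1.3,
            length.out = n_grid)
  iso <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    data.frame(label = pts$label[i], fr = xs,
               abundance = pts$impact[i] / xs, stringsAsFactors = FALSE)
  }))
  structure(list(points = pts, isoclines = iso), class = "rip_biplot")
}

#' @export
print.rip_biplot <- function(x, ...) {
  cat("Impact-potential biplot data:\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' @rdname rip_biplot_data
#' @param x a `rip_biplot` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rip_biplot <- function(x, ...) {
  p <- x$points
  xlim <- range(0, p$fr_mean + p$fr_se) * 1.1
  ylim <- range(0, p$abundance_mean + p$abundance_se) * 1.1
  plot(p$fr_mean, p$abundance_mean, xlim = xlim, ylim = ylim,
       xlab = "Maximum feeding rate (prey/day)",
       ylab = expression(Abundance ~ (ind / m^2)),
       pch = 16, cex = 1.3, ...)
  graphics::arrows(p$fr_mean - p$fr_se, p$abundance_mean,
                   p$fr_mean + p$fr_se, p$abundance_mean,
                   angle = 90, code = 3, length = 0.04)
  graphics::arrows(p$fr_mean, p$abundance_mean - p$abundance_se,
                   p$fr_mean, p$abundance_mean + p$abundance_se,
                   angle = 90, code = 3, length = 0.04)
  for (lab in unique(x$isoclines$label)) {
    iso <- x$isoclines[x$isoclines$label == lab, ]
    graphics::lines(iso$fr, iso$abundance, lty = 3,
                    col = grDevices::grey(0.5))
  }
  graphics::text(p$fr_mean, p$abundance_mean, p$label, pos = 4, cex = 0.8)
  invisible(x)
}
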