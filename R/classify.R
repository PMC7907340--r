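#' Phenomenological classification of functional response type
#'
#' Fits a logistic regression of the proportion of prey consumed on prey
#' density (and optionally density squared) with a quasibinomial error
#' structure, and classifies the functional response shape from the signs
#' and significance of the polynomial terms:
#' \itemize{
#'   \item Type II: significantly negative first-order term (proportion
#'     consumed declines with density from the outset);
#'   \item Type III: significantly positive first-order term superseded by a
#'     significantly negative second-order term (sigmoidal response);
#'   \item otherwise "I/indeterminate".
#' }
#' Dispersion is estimated from Pearson residuals (the quasibinomial
#' default), so the reported tests are dispersion-adjusted t tests.
#'
#' @param trials trial data.frame (see [read_trials()]); excluded rows are
#'   dropped.
#' @param include_quadratic fit the density-squared term (default `TRUE`;
#'   required to detect Type III).
#' @param alpha significance level for the classification (default 0.05).
#' @return object of class `fr_type`: a list with `classified_type` (one of
#'   `"II"`, `"III"`, `"I/indeterminate"`), `first_order` and (optionally)
#'   `second_order` (each estimate, SE, p), `dispersion`, and the fitted
#'   `glm`.
#' @examples
#' trials <- generate_trials(sim_config(a = 0.6, h = 0.46, seed = 5,
#'                                      replicates = 25))
#' classify_fr_type(trials)
#' @export
classify_fr_type <- function(trials, include_quadratic = TRUE, alpha = 0.05) {
  d <- usable_trials(trials)
  if (length(unique(d$density_offered)) < 2L) {
    stop("need trials at >= 2 distinct prey densities")
  }
  if (sum(d$consumed) == 0) {
    warning("no prey consumed in any trial; type is indeterminate")
    return(structure(list(classified_type = "I/indeterminate",
                          first_order = NULL, second_order = NULL,
                          dispersion = NA_real_, model = NULL,
                          alpha = alpha),
                     class = "fr_type"))
  }
  form <- if (include_quadratic) {
    cbind(consumed, density_offered - consumed) ~ density_offered +
      I(density_offered^2)
  } else {
    cbind(consumed, density_offered - consumed) ~ density_offered
  }
  m <- glm(form, family = quasibinomial(), data = d)
  sm <- summary(m)
  co <- sm$coefficients
  first <- list(estimate = co[2L, 1L], se = co[2L, 2L], p = co[2L, 4L])
  second <- if (include_quadratic && nrow(co) >= 3L) {
    list(estimate = co[3L, 1L], se = co[3L, 2L], p = co[3L, 4L])
  }
  type <- "I/indeterminate"
  if (!is.na(first$p) && first$p < alpha && first$estimate < 0) {
    type <- "II"
  } else if (!is.null(second) &&
             !is.na(first$p) && first$p < alpha && first$estimate > 0 &&
             !is.na(second$p) && second$p < alpha && second$estimate < 0) {
    type <- "III"
  }
  structure(list(classified_type = type, first_order = first,
                 second_order = second, dispersion = sm$dispersion,
                 model = m, alpha = alpha),
            class = "fr_type")
}

#' @export
print.fr_type <- function(x, ...) {
  cat("Functional response type:", x$classified_type, "\n")
  if (!is.null(x$first_order)) {
    cat(sprintf("  density term: %.4g (SE %.4g), p = %.4g\n",
                x$first_order$estimate, x$first_order$se, x$first_order$p))
  }
  if (!is.null(x$second_order)) {
    cat(sprintf("  density^2 term: %.4g (SE %.4g), p = %.4g\n",
                x$second_order$estimate, x$second_order$se, x$second_order$p))
  }
  if (!is.na(x$dispersion)) {
    cat(sprintf("  quasibinomial dispersion: %.3f\n", x$dispersion))
  }
  invisible(x)
}
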