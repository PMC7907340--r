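#' Compare Rogers parameters between two predator groups
#'
#' Joint maximum-likelihood fit of two trial datasets with an indicator
#' variable for group membership, parameterised as
#' \deqn{a = a_{base} - D_a I, \quad h = h_{base} - D_h I}
#' where \eqn{I = 1} for comparator trials. \eqn{D_a} and \eqn{D_h} are thus
#' the differences \emph{base minus comparator}: a negative \eqn{D_h} means
#' the base group's handling time is smaller (it feeds faster at saturation)
#' than the comparator's. Wald z tests (difference / SE from the joint
#' observed information) give two-sided p-values.
#'
#' @param trials_base,trials_comparator trial data.frames (see
#'   [read_trials()] for the schema).
#' @param T_base,T_comparator trial durations in days; default to each
#'   table's `duration_days`.
#' @param ... passed to [fit_rogers()] for the two marginal fits used as
#'   starting values.
#' @return object of class `fr_compare` with components `Da`, `Dh`,
#'   `se_Da`, `se_Dh`, `z`, `p`, the two marginal fits, and the joint
#'   log-likelihood. Methods: `print`, `summary`, `coef`.
#' @examples
#' base <- generate_trials(sim_config(a = 0.85, h = 0.258, seed = 1))
#' comp <- generate_trials(sim_config(a = 0.85, h = 0.459, seed = 2))
#' compare_fits(base, comp)
#' @export
compare_fits <- function(trials_base, trials_comparator,
                         T_base = NULL, T_comparator = NULL, ...) {
  fit_b <- tryCatch(fit_rogers(trials_base, T = T_base, ...),
                    error = function(e) {
                      stop("base dataset unfittable: ", conditionMessage(e))
                    })
  fit_c <- tryCatch(fit_rogers(trials_comparator, T = T_comparator, ...),
                    error = function(e) {
                      stop("comparator dataset unfittable: ",
                           conditionMessage(e))
                    })

  db <- fit_b$data; dc <- fit_c$data
  dens <- c(db$density_offered, dc$density_offered)
  cons <- c(db$consumed, dc$consumed)
  Tvec <- c(rep(fit_b$T, nrow(db)), rep(fit_c$T, nrow(dc)))
  ind <- c(rep(0L, nrow(db)), rep(1L, nrow(dc)))

  # theta = (a_base, Da, h_base, Dh), natural scale; group parameters must
  # stay positive, enforced by a barrier
  negll <- function(theta) {
    a <- theta[1] - theta[2] * ind
    h <- theta[3] - theta[4] * ind
    if (any(a <= 0) || any(h < 0)) return(1e10)
    p <- numeric(length(dens))
    for (g in 0:1) {
      i <- ind == g
      if (!any(i)) next
      p[i] <- rogers_expected_consumption(a[which(i)[1]], h[which(i)[1]],
                                          Tvec[which(i)[1]], dens[i]) / dens[i]
    }
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(dbinom(cons, dens, p, log = TRUE))
  }

  start <- c(coef(fit_b)[["a"]], coef(fit_b)[["a"]] - coef(fit_c)[["a"]],
             coef(fit_b)[["h"]], coef(fit_b)[["h"]] - coef(fit_c)[["h"]])
  o <- optim(start, negll, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-12))
  est <- o$par
  names(est) <- c("a_base", "Da", "h_base", "Dh")

  H <- tryCatch(optimHess(est, negll), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(V) && all(diag(V) > 0)) sqrt(diag(V)) else rep(NA_real_, 4)
  names(se) <- names(est)

  z <- est[c("Da", "Dh")] / se[c("Da", "Dh")]
  p <- 2 * pnorm(-abs(z))

  structure(list(
    estimates = est, se = se,
    Da = est[["Da"]], Dh = est[["Dh"]],
    se_Da = se[["Da"]], se_Dh = se[["Dh"]],
    z = z, p = p, logLik = -o$value,
    fit_base = fit_b, fit_comparator = fit_c,
    converged = o$convergence == 0L
  ), class = "fr_compare")
}

#' @export
coef.fr_compare <- function(object, ...) object$estimates

#' @export
print.fr_compare <- function(x, digits = 4, ...) {
  cat("Indicator-variable comparison of Rogers parameters",
      "(difference = base - comparator)\n", sep = "")
  tab <- cbind(Estimate = c(x$Da, x$Dh), `Std. Error` = c(x$se_Da, x$se_Dh),
               `z value` = x$z, `Pr(>|z|)` = x$p)
  rownames(tab) <- c("Da", "Dh")
  printCoefmat(tab, digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
summary.fr_compare <- function(object, ...) object
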