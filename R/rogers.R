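#' Expected consumption under the Rogers random predator equation
#'
#' The Rogers random predator equation describes prey depletion in a closed
#' arena where consumed prey are not replaced:
#' \deqn{N_e = N_0 (1 - \exp(a (N_e h - T)))}
#' with attack coefficient \eqn{a} (per day), handling time \eqn{h} (days per
#' prey item) and trial duration \eqn{T} (days). Because \eqn{N_e} appears on
#' both sides, the explicit solution uses the Lambert W function:
#' \deqn{N_e = N_0 - W(a h N_0 e^{-a(T - h N_0)}) / (a h)}
#' For \eqn{h = 0} the limit is the classical random-search result
#' \eqn{N_0 (1 - e^{-aT})}.
#'
#' The Lambert argument is evaluated on the log scale internally, so the
#' function is stable for arbitrarily large \eqn{a h N_0} (where the naive
#' argument overflows).
#'
#' @param a attack coefficient, per day (\eqn{\ge 0}).
#' @param h handling time, days per prey item (\eqn{\ge 0}).
#' @param T trial duration in days (> 0).
#' @param N0 initial prey density; non-negative, vectorised.
#' @return expected number of prey consumed, same length as `N0`; always in
#'   `[0, N0]` and satisfying the implicit equation to ~1e-9.
#' @examples
#' rogers_expected_consumption(a = 0.850, h = 0.258, T = 1, N0 = c(2, 20, 70))
#' @seealso [lambert_w0()], [fit_rogers()]
#' @export
rogers_expected_consumption <- function(a, h, T, N0) {
  check_scalar(a, "a", min = 0)
  check_scalar(h, "h", min = 0)
  check_scalar(T, "T", min = 0, strict = TRUE)
  if (!is.numeric(N0) || any(N0 < 0)) {
    stop("`N0` must be a non-negative numeric vector")
  }
  if (a == 0 || length(N0) == 0) return(numeric(length(N0)))
  if (h == 0) return(N0 * (1 - exp(-a * T)))
  out <- numeric(length(N0))
  pos <- N0 > 0
  if (any(pos)) {
    n <- N0[pos]
    z <- log(a * h * n) - a * (T - h * n)
    ne <- n - lambert_w0_exp(z) / (a * h)
    out[pos] <- pmin(pmax(ne, 0), n)
  }
  out
}
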