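#' Principal branch of the Lambert W function
#'
#' Computes the principal branch \eqn{W_0(x)}, i.e. the value \eqn{w \ge -1}
#' with \eqn{w e^w = x}, for \eqn{x \ge -1/e}. The explicit solution of the
#' Rogers random predator equation is written in terms of this function, so
#' it sits at the heart of every expected-consumption calculation in the
#' package.
#'
#' Iteration is Halley's method with a branch-dependent starting value
#' (asymptotic \eqn{\log x - \log\log x} for large arguments, a series
#' expansion about the branch point for arguments near \eqn{-1/e}), run to a
#' relative tolerance of 1e-12.
#'
#' @param x numeric vector, each element \eqn{\ge -1/e}.
#' @return numeric vector of the same length, satisfying
#'   \eqn{w e^w = x} to a relative tolerance of about 1e-10 or better.
#' @examples
#' lambert_w0(c(0, exp(1), 1))   # 0, 1, 0.567143...
#' @export
lambert_w0 <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  branch <- -exp(-1)
  # tolerate representation error right at the branch point
  bad <- x < branch & abs(x - branch) > 1e-12
  if (any(bad, na.rm = TRUE)) {
    stop("lambert_w0 is undefined for x < -1/e (got ",
         format(min(x, na.rm = TRUE)), ")")
  }
  x <- pmax(x, branch)
  w <- numeric(length(x))
  near <- x < -0.25
  mid <- !near & x <= 2
  big <- x > 2
  # series about the branch point x = -1/e, w = -1
  if (any(near)) {
    p <- sqrt(2 * (exp(1) * x[near] + 1))
    w[near] <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  }
  w[mid] <- x[mid] / (1 + x[mid])
  if (any(big)) {
    l1 <- log(x[big])
    w[big] <- l1 - log(l1)
  }
  for (i in seq_len(60L)) {
    ew <- exp(w)
    f <- w * ew - x
    # Halley step
    denom <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    step <- f / denom
    step[!is.finite(step)] <- 0
    w <- w - step
    if (all(abs(step) <= 1e-13 * pmax(abs(w), 1))) break
  }
  w[x == 0] <- 0
  w
}

# W(exp(z)) without forming exp(z); needed because the Rogers argument
# a*h*N0*exp(-a*(T - h*N0)) overflows for large a*h*N0 during optimisation.
# Solves w + log(w) = z by Newton (monotone, globally convergent for w > 0).
lambert_w0_exp <- function(z) {
  w <- ifelse(z > 1, z - log(pmax(z, 2)), exp(pmin(z, 700)) / (1 + exp(pmin(z, 700))))
  w <- pmax(w, .Machine$double.xmin)
  for (i in seq_len(100L)) {
    step <- (z - w - log(w)) * w / (1 + w)
    w <- pmax(w + step, .Machine$double.xmin)
    if (all(abs(step) <= 1e-13 * pmax(w, 1))) break
  }
  w
}
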