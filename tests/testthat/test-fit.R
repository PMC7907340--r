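test_that("fit recovers generating parameters from simulated trials", {
  tr <- embryo_trials(a = 0.85, h = 0.258, seed = 31, replicates = 30)
  f <- fit_rogers(tr)
  expect_true(f$converged)
  expect_lt(abs(coef(f)[["a"]] - 0.85), 3 * f$se[["a"]])
  expect_lt(abs(coef(f)[["h"]] - 0.258), 3 * f$se[["h"]])
  expect_true(all(f$p < 0.05))
})

test_that("fitting rounded noise-free expectations recovers (a, h) within 5%", {
  # expectations realised as integers preserving each density's total
  reps <- 20
  mu <- rogers_expected_consumption(0.85, 0.258, 1, embryo_densities)
  cons <- unlist(lapply(seq_along(embryo_densities), function(i) {
    tot <- round(reps * mu[i])
    extra <- tot %% reps
    c(rep(tot %/% reps + 1, extra), rep(tot %/% reps, reps - extra))
  }))
  tr <- data.frame(density_offered = rep(embryo_densities, each = reps),
                   consumed = cons, duration_days = 1)
  f <- fit_rogers(tr)
  expect_lt(abs(coef(f)[["a"]] / 0.85 - 1), 0.05)
  expect_lt(abs(coef(f)[["h"]] / 0.258 - 1), 0.05)
})

test_that("feeding-rate conventions are exact transforms of h", {
  tr <- larvae_trials(seed = 8)
  f <- fit_rogers(tr)
  expect_identical(f$T, 2)
  expect_equal(f$max_feeding_rate, 1 / (f$T * coef(f)[["h"]]))
  expect_equal(f$max_feeding_rate_per_day, 1 / coef(f)[["h"]])
})

test_that("reported optimum beats random local perturbations", {
  tr <- embryo_trials(seed = 17)
  f <- fit_rogers(tr)
  d <- f$data
  nll <- function(a, h) {
    p <- rogers_expected_consumption(a, h, f$T, d$density_offered) /
      d$density_offered
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(dbinom(d$consumed, d$density_offered, p, log = TRUE))
  }
  at_opt <- nll(coef(f)[["a"]], coef(f)[["h"]])
  expect_equal(-at_opt, f$logLik, tolerance = 1e-8)
  set.seed(99)
  for (i in 1:100) {
    pert <- coef(f) * exp(rnorm(2, sd = 0.2))
    expect_gte(nll(pert[[1]], pert[[2]]), at_opt)
  }
})

test_that("degenerate inputs raise the documented errors", {
  dens <- rep(c(5, 10), each = 4)
  expect_error(
    fit_rogers(data.frame(density_offered = dens,
                          consumed = c(2, 1, 2, 1, 4, 3, 5, 4),
                          duration_days = 1)),
    "3 distinct")
  tr0 <- embryo_trials(seed = 3)
  tr0$consumed <- 0L
  expect_error(fit_rogers(tr0), "zero")
  trb <- embryo_trials(seed = 3)
  trb$consumed <- trb$density_offered
  expect_error(fit_rogers(trb), "boundary|all-or-nothing")
  expect_error(fit_rogers(data.frame(consumed = 1)), "missing column")
  tr <- embryo_trials(seed = 3)
  tr$duration_days <- NULL
  expect_error(fit_rogers(tr), "duration_days")
})

test_that("excluded trials and background mortality are handled", {
  tr <- embryo_trials(seed = 41)
  tr$excluded[1:10] <- TRUE
  f <- fit_rogers(tr)
  expect_equal(f$n_trials, nrow(tr) - 10)
  # dead-unconsumed prey are background mortality, not consumption
  tr2 <- embryo_trials(seed = 41, mortality_rate = 0.05)
  f2 <- fit_rogers(tr2)
  expect_true(f2$converged)
})

test_that("methods behave like a standard modelling object", {
  tr <- embryo_trials(seed = 23)
  f <- fit_rogers(tr)
  expect_named(coef(f), c("a", "h"))
  expect_equal(dim(vcov(f)), c(2L, 2L))
  expect_s3_class(logLik(f), "logLik")
  ci <- confint(f)
  expect_true(ci["a", 1] < coef(f)[["a"]] && coef(f)[["a"]] < ci["a", 2])
  expect_equal(predict(f, c(10, 40)),
               rogers_expected_consumption(coef(f)[["a"]], coef(f)[["h"]],
                                           1, c(10, 40)))
  expect_length(residuals(f), f$n_trials)
  expect_lt(abs(mean(residuals(f, "pearson"))), 0.5)
  sims <- simulate(f, nsim = 3, seed = 5)
  expect_length(sims, 3)
  expect_true(all(sims[[1]]$consumed <= sims[[1]]$density_offered))
  expect_identical(simulate(f, nsim = 2, seed = 5),
                   simulate(f, nsim = 2, seed = 5))
  expect_output(print(summary(f)), "max feeding rate", ignore.case = TRUE)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
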