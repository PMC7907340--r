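test_that("chi-square equals the brute-force Pearson statistic", {
  s <- c(12, 30, 22); n <- c(40, 45, 50)
  out <- chi_square_test(s, n)
  O <- cbind(s, n - s)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(unname(out$statistic), sum((O - E)^2 / E))
  expect_equal(unname(out$parameter), 2)
  # invariant to group reordering
  out2 <- chi_square_test(s[c(3, 1, 2)], n[c(3, 1, 2)])
  expect_equal(out$statistic, out2$statistic)
})

test_that("continuity correction defaults follow table shape", {
  # 2x2 defaults to Yates; k x 2 never corrected
  a <- chi_square_test(c(53, 31), c(77, 77))
  b <- suppressWarnings(chisq.test(cbind(c(53, 31), c(24, 46)),
                                   correct = TRUE))
  expect_equal(a$statistic, b$statistic)
  expect_equal(unname(chi_square_test(c(10, 20), c(30, 30),
                                      correct = FALSE)$statistic),
               unname(chisq.test(cbind(c(10, 20), c(20, 10)),
                                 correct = FALSE)$statistic))
  # identical proportions give a null statistic
  expect_equal(unname(chi_square_test(c(10, 20), c(20, 40),
                                      correct = FALSE)$statistic), 0)
  expect_error(chi_square_test(c(0, 0), c(10, 10)), "margin")
  expect_error(chi_square_test(c(5), c(10)), ">= 2 groups")
  expect_error(chi_square_test(c(11, 2), c(10, 10)), "successes")
})

test_that("fisher p matches full hypergeometric enumeration", {
  enum_fisher <- function(m) {
    rs <- rowSums(m); cs <- colSums(m)
    p_obs <- dhyper(m[1, 1], rs[1], rs[2], cs[1])
    ks <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- dhyper(ks, rs[1], rs[2], cs[1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tables <- list(
    matrix(c(167, 175, 8, 0), 2),
    matrix(c(5, 44, 40, 1), 2),
    matrix(c(3, 9, 7, 2), 2),
    matrix(c(0, 5, 10, 5), 2))
  for (m in tables) {
    expect_equal(fisher_exact_2x2(m), enum_fisher(m), tolerance = 1e-10)
  }
})

test_that("fisher p behaves at the extremes and under swaps", {
  even <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(fisher_exact_2x2(even), 1)
  split <- matrix(c(0, 45, 45, 0), 2)
  expect_lt(fisher_exact_2x2(split), 1e-20)
  m <- matrix(c(3, 9, 7, 2), 2)
  expect_equal(fisher_exact_2x2(m), fisher_exact_2x2(m[2:1, ]))
  expect_equal(fisher_exact_2x2(m), fisher_exact_2x2(m[, 2:1]))
  expect_equal(fisher_exact_2x2(m), fisher_exact_2x2(t(m)))
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("survival summary aggregates and attributes mortality", {
  tr <- rbind(
    data.frame(predator_group = "control", prey_type = "larva",
               density_offered = rep(10, 8), consumed = 0,
               dead_unconsumed = 0, duration_days = 2,
               replicate_id = as.character(1:8), excluded = FALSE),
    data.frame(predator_group = "invader", prey_type = "larva",
               density_offered = rep(10, 8), consumed = rep(c(2, 3), 4),
               dead_unconsumed = 0, duration_days = 2,
               replicate_id = as.character(1:8), excluded = FALSE),
    data.frame(predator_group = "inert", prey_type = "larva",
               density_offered = rep(10, 8), consumed = 0,
               dead_unconsumed = 0, duration_days = 2,
               replicate_id = as.character(1:8), excluded = FALSE))
  s <- survival_summary(tr)
  expect_equal(s$survival[s$group == "control"], 1)
  expect_equal(s$survival[s$group == "invader"], 0.75)
  expect_true(s$predation_attributed[s$group == "invader"])
  expect_false(s$predation_attributed[s$group == "inert"])
  expect_true(is.na(s$p_vs_control[s$group == "control"]))
  expect_error(survival_summary(tr[tr$predator_group != "control", ]),
               "control")
})
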