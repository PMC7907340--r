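eff_lgDV <- effect_summary("large invader", 1.099, 0.047, 14.760, 2.955)
eff_inDV <- effect_summary("intermediate invader", 0.469, 0.063,
                           83.280, 15.710)
eff_lgGP <- effect_summary("native", 0.157, 0.012, 17.378, 4.486)

test_that("zero-SE inputs give the exact deterministic ratio", {
  A <- effect_summary("A", 2, 0, 50, 0)
  B <- effect_summary("B", 1, 0, 25, 0)
  r <- rip_score(A, B, n_draws = 10000, seed = 1)
  expect_equal(r$rip_mean, 4)
  expect_equal(r$CI60, c(4, 4))
  expect_equal(r$CI80, c(4, 4))
  expect_equal(r$prob_exceeds_one, 100)
  rflip <- rip_score(B, A, n_draws = 10000, seed = 1)
  expect_equal(rflip$prob_exceeds_one, 0)
})

test_that("draws are seeded, stable across seeds, and CIs are nested", {
  r1 <- rip_score(eff_lgDV, eff_lgGP, seed = 3)
  r2 <- rip_score(eff_lgDV, eff_lgGP, seed = 3)
  expect_identical(r1$rip_mean, r2$rip_mean)
  r3 <- rip_score(eff_lgDV, eff_lgGP, seed = 4)
  expect_equal(r1$rip_mean, r3$rip_mean, tolerance = 0.01)
  expect_true(r1$CI80[1] <= r1$CI60[1] && r1$CI60[2] <= r1$CI80[2])
  expect_true(r1$prob_exceeds_one >= 0 && r1$prob_exceeds_one <= 100)
})

test_that("denominator noise inflates the mean ratio (Jensen direction)", {
  det <- (1.099 * 14.760) / (0.157 * 17.378)
  r <- rip_score(eff_lgDV, eff_lgGP, seed = 5)
  expect_gt(r$rip_mean, det)
  set.seed(6)
  for (i in 1:5) {
    mA <- runif(1, 0.5, 2); mB <- runif(1, 0.5, 2)
    nA <- runif(1, 10, 90); nB <- runif(1, 10, 90)
    A <- effect_summary("A", mA, 0.05 * mA, nA, 0.2 * nA)
    B <- effect_summary("B", mB, 0.05 * mB, nB, 0.2 * nB)
    r <- rip_score(A, B, n_draws = 50000, seed = 100 + i)
    expect_gt(r$rip_mean, (mA * nA) / (mB * nB))
  }
})

test_that("reciprocity: rip(A,B) x rip(B,A) >= 1 with noise", {
  ab <- rip_score(eff_inDV, eff_lgDV, seed = 7)
  ba <- rip_score(eff_lgDV, eff_inDV, seed = 8)
  expect_gt(ab$rip_mean * ba$rip_mean, 1)
})

test_that("lognormal law matches its closed-form mean", {
  # E[(X1 X2)/(X3 X4)] = (m1 m2)/(m3 m4) * (1 + cv3^2)(1 + cv4^2)
  closed <- (0.469 * 83.280) / (1.099 * 14.760) *
    (1 + (0.047 / 1.099)^2) * (1 + (2.955 / 14.760)^2)
  r <- rip_score(eff_inDV, eff_lgDV, seed = 9, law = "lognormal")
  expect_equal(r$rip_mean, closed, tolerance = 0.02)
})

test_that("lognormal law reproduces published ratio summaries near-exactly", {
  r1 <- rip_score(eff_lgDV, eff_lgGP, seed = 21, law = "lognormal")
  r2 <- rip_score(eff_inDV, eff_lgGP, seed = 22, law = "lognormal")
  r3 <- rip_score(eff_inDV, eff_lgDV, seed = 23, law = "lognormal")
  expect_equal(r1$rip_mean, 6.379, tolerance = 0.006)
  expect_equal(r2$rip_mean, 15.359, tolerance = 0.006)
  expect_equal(r3$rip_mean, 2.509, tolerance = 0.006)
})

test_that("validation and rejection accounting", {
  expect_error(effect_summary("x", -1, 0.1, 10, 1), "> 0")
  expect_error(effect_summary("x", 1, -0.1, 10, 1), ">= 0")
  expect_error(rip_score(eff_lgDV, eff_lgGP, n_draws = 100), ">= 10000")
  # mean barely above 0 relative to SE: heavy rejection must warn
  noisy <- effect_summary("noisy", 0.1, 0.2, 10, 1)
  expect_warning(rip_score(noisy, eff_lgGP, n_draws = 10000, seed = 10),
                 "rejection")
})

test_that("biplot geometry is consistent with impact ordering", {
  effs <- list(eff_inDV, eff_lgDV, eff_lgGP)
  bp <- rip_biplot_data(effs)
  expect_equal(nrow(bp$points), 3)
  # impact ordering on the biplot matches rip_mean ordering vs the native
  imp <- bp$points$impact
  names(imp) <- bp$points$label
  r_in <- rip_score(eff_inDV, eff_lgGP, seed = 11)$rip_mean
  r_lg <- rip_score(eff_lgDV, eff_lgGP, seed = 12)$rip_mean
  expect_identical(imp[["intermediate invader"]] > imp[["large invader"]],
                   r_in > r_lg)
  # intermediate group sits highest on the abundance axis
  expect_identical(
    bp$points$label[which.max(bp$points$abundance_mean)],
    "intermediate invader")
  # equal products lie on one isocline
  e1 <- effect_summary("e1", 2, 0.1, 10, 1)
  e2 <- effect_summary("e2", 1, 0.1, 20, 1)
  bp2 <- rip_biplot_data(list(e1, e2))
  iso1 <- bp2$isoclines[bp2$isoclines$label == "e1", ]
  expect_equal(iso1$fr * iso1$abundance, rep(20, nrow(iso1)))
  expect_equal(bp2$points$impact[1], bp2$points$impact[2])
  expect_error(rip_biplot_data(list(e1)), ">= 2")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(bp))
})
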