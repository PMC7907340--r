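test_that("density and allocation arithmetic", {
  expect_equal(density_from_quadrat(37, 0.25), 148)
  expect_equal(density_from_quadrat(0), 0)
  expect_equal(density_from_quadrat(21, 0.25), 84)
  expect_error(density_from_quadrat(5, 0), "> 0")
  expect_equal(allocate_published_abundance(100, c(0.2, 0.5, 0.3)),
               c(20, 50, 30))
  expect_equal(allocate_published_abundance(0, c(0.5, 0.5)), c(0, 0))
  # allocation conserves the total
  p <- c(0.11, 0.47, 0.42)
  expect_equal(sum(allocate_published_abundance(870, p)), 870)
  expect_error(allocate_published_abundance(10, c(0.5, 0.4)), "sum to 1")
})

test_that("summaries report mean, SE and provenance per group", {
  q <- rbind(
    generate_quadrat_survey(80, 4, 6, seed = 1, group = "invader"),
    generate_quadrat_survey(17, 4, 5, seed = 2, group = "native"),
    data.frame(site = "lit_1", group = "invader", count = 120, area_m2 = 1,
               source = "literature"))
  s <- summarize_abundance(q)
  expect_setequal(s$group, c("invader", "native"))
  inv <- s[s$group == "invader", ]
  expect_equal(inv$n_samples, 7)
  expect_equal(inv$n_literature, 1)
  d <- q$count[q$group == "invader"] / q$area_m2[q$group == "invader"]
  expect_equal(inv$mean_density, mean(d))
  expect_equal(inv$se_density, sd(d) / sqrt(7))
  # ordering invariance
  s2 <- summarize_abundance(q[sample(nrow(q)), ])
  expect_equal(s[order(s$group), ], s2[order(s2$group), ],
               ignore_attr = TRUE)
  # degenerate single sample
  expect_warning(one <- summarize_abundance(q[q$site == "lit_1", ]),
                 "single sample")
  expect_equal(one$se_density, 0)
  # identical samples give SE 0
  same <- data.frame(site = c("a", "b"), group = "g", count = 10,
                     area_m2 = 0.25, source = "field")
  expect_equal(summarize_abundance(same)$se_density, 0)
})

test_that("survey generated at a field-scale mean is recovered within 2 SE", {
  q <- generate_quadrat_survey(870, dispersion = 3, n_sites = 40, seed = 3,
                               group = "invader")
  s <- summarize_abundance(q)
  expect_lt(abs(s$mean_density - 870), 2 * s$se_density)
})

test_that("quasi-Poisson comparison detects a field-scale contrast", {
  q <- rbind(generate_quadrat_survey(83, 4, 30, seed = 4, group = "mid"),
             generate_quadrat_survey(17, 4, 30, seed = 5, group = "native"))
  cmp <- compare_abundance(q)
  expect_lt(cmp$omnibus$p, 0.01)
  expect_lt(cmp$pairwise$p_holm[1], 0.01)
  # log-scale estimate is the density ratio
  expect_equal(exp(abs(cmp$pairwise$estimate[1])),
               83 / 17, tolerance = 0.5)
  expect_error(compare_abundance(q[q$group == "mid", ]), ">= 2 groups")
  q0 <- q; q0$count <- 0
  expect_error(compare_abundance(q0), "zero")
})

test_that("permuting group labels destroys the signal", {
  q <- rbind(generate_quadrat_survey(83, 4, 30, seed = 6, group = "a"),
             generate_quadrat_survey(17, 4, 30, seed = 7, group = "b"))
  set.seed(8)
  ps <- replicate(11, {
    qp <- q
    qp$group <- sample(qp$group)
    compare_abundance(qp)$omnibus$p
  })
  expect_gt(median(ps), 0.2)
})

test_that("dispersion is near 1 under Poisson counts", {
  set.seed(9)
  q <- data.frame(site = as.character(1:200),
                  group = rep(c("a", "b"), each = 100),
                  count = rpois(200, 20), area_m2 = 0.25, source = "field")
  cmp <- compare_abundance(q)
  expect_equal(cmp$dispersion, 1, tolerance = 0.2)
})

test_that("type-I error of the omnibus test is near nominal", {
  set.seed(10)
  rej <- mean(replicate(200, {
    q <- data.frame(site = as.character(1:40),
                    group = rep(c("a", "b"), each = 20),
                    count = rnbinom(40, size = 4, mu = 20),
                    area_m2 = 0.25, source = "field")
    compare_abundance(q)$omnibus$p < 0.05
  }))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
})
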