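test_that("normality gate branches on Shapiro-Wilk and small groups", {
  set.seed(31)
  # normal data of decent size is parametric most of the time
  # (each group passes at level 0.05 with probability 0.95)
  hits <- replicate(200, {
    g <- list(a = rnorm(30), b = rnorm(30))
    as.character(normality_gate(g)) == "parametric"
  })
  expect_gte(mean(hits), 0.85)
  # strong skew is caught essentially always
  skewed <- list(a = rexp(50)^3, b = rnorm(50))
  expect_equal(as.character(normality_gate(skewed)), "nonparametric")
  # n = 2 group forces the nonparametric branch
  tiny <- list(a = c(1, 2), b = rnorm(30))
  expect_equal(as.character(normality_gate(tiny)), "nonparametric")
})

test_that("compare_groups dispatches by gate and group count", {
  set.seed(32)
  g2 <- list(a = rnorm(25), b = rnorm(25, 1))
  r2 <- compare_groups(g2, gate = "parametric")
  expect_match(r2$test_name, "Welch's t")
  r2n <- compare_groups(g2, gate = "nonparametric")
  expect_match(r2n$test_name, "Mann-Whitney")
  g3 <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  expect_match(compare_groups(g3, gate = "parametric")$test_name, "ANOVA")
  expect_match(compare_groups(g3, gate = "nonparametric")$test_name,
               "Kruskal-Wallis")
  # zero-variance group falls back with a warning
  expect_warning(res <- compare_groups(list(a = rep(1, 10), b = rnorm(10)),
                                       gate = "parametric"),
                 "zero-variance")
  expect_match(res$test_name, "Mann-Whitney")
})

test_that("exact Mann-Whitney reproduces enumeration, including {1,2} vs {3,4}", {
  r <- compare_groups(list(a = c(1, 2), b = c(3, 4)), gate = "nonparametric")
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(oracle_mw_exact(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  # identical groups give p = 1 by symmetry
  same <- compare_groups(list(a = c(5, 6, 7), b = c(5, 6, 7)),
                         gate = "nonparametric")
  expect_equal(same$p_value, 1)
  set.seed(33)
  for (n1 in 2:5) for (n2 in 2:5) {
    vals <- sample(seq(1, 100), n1 + n2) # distinct values, no ties
    g1 <- vals[1:n1]; g2 <- vals[(n1 + 1):(n1 + n2)]
    r <- compare_groups(list(a = g1, b = g2), gate = "nonparametric")
    expect_equal(r$p_value, oracle_mw_exact(g1, g2), tolerance = 1e-10,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
  # relabelling the groups leaves the two-sided p unchanged
  expect_equal(compare_groups(list(a = c(1, 5, 9), b = c(2, 3, 4)),
                              gate = "nonparametric")$p_value,
               compare_groups(list(a = c(2, 3, 4), b = c(1, 5, 9)),
                              gate = "nonparametric")$p_value)
  # monotone transform invariance in the nonparametric branch
  g1 <- c(0.3, 1.2, 2.5); g2 <- c(0.9, 3.3, 4.1, 5.0)
  expect_equal(compare_groups(list(a = g1, b = g2),
                              gate = "nonparametric")$p_value,
               compare_groups(list(a = exp(g1), b = exp(g2)),
                              gate = "nonparametric")$p_value)
})

test_that("Kruskal-Wallis holds its nominal type-I error", {
  set.seed(34)
  rej <- replicate(1000, {
    g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    compare_groups(g, gate = "nonparametric")$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Brown-Forsythe calibrates under the null and detects unequal spread", {
  set.seed(35)
  rej_null <- replicate(500, {
    brown_forsythe(list(a = rnorm(50), b = rnorm(50)))$p_value < 0.05
  })
  expect_gte(mean(rej_null), 0.02)
  expect_lte(mean(rej_null), 0.09)
  rej_alt <- replicate(200, {
    brown_forsythe(list(a = rnorm(50, sd = 1), b = rnorm(50, sd = 5)))$p_value < 0.05
  })
  expect_gt(mean(rej_alt), 0.95)
  # constant groups: statistic 0, p 1
  const <- brown_forsythe(list(a = rep(2, 5), b = rep(9, 5)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
})

test_that("Brown-Forsythe agrees with the median-centred Levene reference", {
  skip_if_not_installed("car")
  set.seed(36)
  g <- list(a = rnorm(30, sd = 1), b = rnorm(25, sd = 2), c = rnorm(35, sd = 1))
  mine <- brown_forsythe(g)
  vals <- unlist(g); fac <- factor(rep(names(g), lengths(g)))
  ref <- car::leveneTest(vals, fac, center = median)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  tab <- matrix(c(5, 0, 19, 15), 2) # captured/not x depleted/control
  res <- fisher_exact(tab)
  expect_equal(res$p_one_sided, choose(24, 5) / choose(39, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value, oracle_fisher_two_sided(tab), tolerance = 1e-10)
  # identical rows carry no association
  expect_equal(fisher_exact(matrix(c(4, 4, 7, 7), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "input error")
  # random tables with total <= 30 against the enumeration oracle
  set.seed(37)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    tab <- matrix(c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2],
                    n - cuts[3]), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_two_sided(tab),
                 tolerance = 1e-9)
  }
})

test_that("significance stars follow the legend convention", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("stats_report assembles one row per test", {
  set.seed(38)
  metrics <- list(m1 = list(a = rnorm(10), b = rnorm(10, 2)),
                  m2 = list(a = rexp(12), b = rexp(12)))
  rep1 <- stats_report(metrics)
  expect_equal(nrow(rep1), 2)
  rep2 <- stats_report(metrics, brown_forsythe_too = TRUE)
  expect_equal(nrow(rep2), 4)
  expect_true(all(rep1$p_value >= 0 & rep1$p_value <= 1))
})
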