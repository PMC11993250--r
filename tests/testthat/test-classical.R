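test_that("the Welch statistic matches the textbook formulas and stats::t.test", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  ref <- stats::t.test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)

  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(sample(4:12, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(4:12, 1), mean = runif(1, -1, 1))
    w <- welch_t_test(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch t is symmetric and degenerates sensibly", {
  x <- c(1.2, 3.4, 2.2, 4.8)
  w <- welch_t_test(x, x)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)

  # equal sample variances and equal n: Satterthwaite df = pooled df 2n-2
  y <- x + 5
  expect_equal(welch_t_test(x, y)$df, 2 * length(x) - 2)

  a <- rnorm(6); b <- rnorm(8, mean = 1)
  ab <- welch_t_test(a, b); ba <- welch_t_test(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$statistic, -ba$statistic)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(2, 2), c(3, 3)), "zero variance")
})

test_that("one-way ANOVA matches the classical decomposition and oracles", {
  g <- list(c(1, 2, 3), c(2, 4, 6), c(5, 5, 7))
  res <- one_way_anova(g)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(seq_along(g), lengths(g))))
  ref <- stats::oneway.test(y ~ grp, data = df, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_identical(c(res$df_between, res$df_within), c(2L, 6L))

  # two groups: F equals the square of the pooled-variance t statistic
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), mean = 0.5)
    f <- one_way_anova(list(x, y))$f_statistic
    t_pooled <- unname(stats::t.test(x, y, var.equal = TRUE)$statistic)
    expect_equal(f, t_pooled^2, tolerance = 1e-10)
  }

  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "undefined")
  expect_error(one_way_anova(list(c(1, 2))), "at least 2 samples")
  expect_error(one_way_anova(list(c(1, 2), 3)), "at least 2 observations")
})

test_that("BCa intervals follow the Efron construction", {
  set.seed(14)
  x <- rnorm(40)
  ours <- bca_bootstrap_ci(x, mean, n_boot = 5000, seed = 99)
  expect_lte(ours$lower, ours$statistic)
  expect_gte(ours$upper, ours$statistic)

  # independent oracle: boot::boot.ci's BCa endpoints on the same sample
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 5000)
  ci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_lt(abs(ours$lower - ci[1]), 0.03)
  expect_lt(abs(ours$upper - ci[2]), 0.03)

  # endpoints are monotone in alpha: the 90% interval nests inside the 95%
  narrow <- bca_bootstrap_ci(x, mean, n_boot = 5000, alpha = 0.10, seed = 99)
  expect_gte(narrow$lower, ours$lower)
  expect_lte(narrow$upper, ours$upper)
})

test_that("degenerate bootstrap distributions collapse with a warning", {
  expect_warning(res <- bca_bootstrap_ci(rep(2, 5), mean, n_boot = 200, seed = 1),
                 "Degenerate")
  expect_equal(res$lower, 2)
  expect_equal(res$upper, 2)
  expect_true(res$degenerate)
})

test_that("the two-group mean-difference BCa interval covers the point estimate", {
  set.seed(3)
  x <- rnorm(20, 5); y <- rnorm(25, 3)
  res <- bca_mean_diff_ci(x, y, n_boot = 2000, seed = 7)
  expect_lte(res$lower, res$statistic)
  expect_gte(res$upper, res$statistic)
  expect_equal(res$statistic, mean(x) - mean(y))
  # interval for a clearly separated difference excludes zero
  expect_gt(res$lower, 0)
})

test_that("region widths are the stated position means", {
  lum <- lumen_fixture(n_embryos = 1, aorta = c(0.6, 0.6, 0.78),
                       heart = c(2.0, 2.4))
  w <- region_lumen_widths(lum)
  expect_equal(w$posterior_aorta_width, 0.66)
  expect_equal(w$heart_proper_width, 2.2)

  all_one <- lumen_fixture(n_embryos = 1, aorta = rep(1, 3), heart = rep(1, 2))
  w1 <- region_lumen_widths(all_one)
  expect_equal(w1$posterior_aorta_width, 1)
  expect_equal(w1$heart_proper_width, 1)

  expect_error(region_lumen_widths(lum[-1, ]), "missing lumen positions")
})

test_that("region widths are scale-equivariant and average replicate planes", {
  lum <- lumen_fixture(n_embryos = 2)
  scaled <- lum
  scaled$diameter <- scaled$diameter * 3
  expect_equal(region_lumen_widths(scaled)$posterior_aorta_width,
               3 * region_lumen_widths(lum)$posterior_aorta_width)

  # two Z-planes at one position average before the region mean
  reps <- rbind(lumen_fixture(n_embryos = 1),
                tibble::tibble(genotype = "wt", embryo_id = "wt_e01",
                               position = "A2", diameter = 0.8))
  w <- region_lumen_widths(reps)
  expect_equal(w$posterior_aorta_width, mean(c(mean(c(0.6, 0.8)), 0.6, 0.78)))
})

test_that("the within-genotype region comparison behaves at both extremes", {
  wt <- generate_embryo_table(preset_configs()$wild_type, seed = 12)
  res <- compare_region_widths(wt$lumen, "wild_type")
  expect_lt(res$p_value, 0.001)
  expect_gt(res$mean_x, res$mean_y)  # heart proper wider than aorta

  expect_error(compare_region_widths(wt$lumen[1:5, ], "wild_type"),
               "At least 2")
  expect_error(compare_region_widths(wt$lumen, "absent"), "not present")
})
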