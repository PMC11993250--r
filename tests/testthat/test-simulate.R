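test_that("regeneration from (config, seed) is bit-identical and prefix-stable", {
  cfg <- phenotype_config(genotype = "g", n_embryos = 6,
                          symmetric_rate = 0.2, asymmetric_rate = 0.1,
                          missingness = 0.05)
  a <- generate_embryo_table(cfg, seed = 101)
  b <- generate_embryo_table(cfg, seed = 101)
  expect_equal(a$table, b$table, ignore_attr = TRUE)
  expect_equal(a$lumen, b$lumen, ignore_attr = TRUE)

  # enlarging the cohort must not perturb earlier embryos
  bigger <- phenotype_config(genotype = "g", n_embryos = 9,
                             symmetric_rate = 0.2, asymmetric_rate = 0.1,
                             missingness = 0.05)
  big <- generate_embryo_table(bigger, seed = 101)
  ids <- unique(a$table$embryo_id)
  expect_equal(big$table[big$table$embryo_id %in% ids, ], a$table,
               ignore_attr = TRUE)
})

test_that("the wild-type preset is blueprint-conformant: 210 records, no defects", {
  wt <- generate_embryo_table(preset_configs()$wild_type, seed = 1)
  expect_identical(nrow(wt$table), 210L)
  cl <- classify_hemisegments(wt$table)
  expect_identical(sum(cl$symmetric_defect), 0L)
  expect_identical(sum(cl$asymmetric_or_earlier_defect), 0L)
})

test_that("the fully penetrant A2 phenotype forces a single Svp CC in all 30 hemisegments", {
  trx <- generate_embryo_table(preset_configs()$trx_like, seed = 2)
  a2 <- trx$table[trx$table$segment == "A2", ]
  expect_identical(nrow(a2), 30L)
  expect_true(all(a2$svp_count == 1L))
})

test_that("generated tables always pass table validation", {
  for (seed in 1:3) {
    cfg <- phenotype_config(genotype = "g", n_embryos = 4,
                            symmetric_rate = 0.4, asymmetric_rate = 0.3,
                            a2_single_svp_penetrance = 0.5,
                            missingness = 0.2)
    bundle <- generate_embryo_table(cfg, seed = seed)
    expect_silent(validate_hemisegment_table(bundle$table))
    expect_silent(validate_lumen_table(bundle$lumen))
  }
})

test_that("marginal defect fractions converge to the configured rate", {
  cfg <- phenotype_config(genotype = "g", n_embryos = 300,
                          symmetric_rate = 0.2, symmetric_rho = 0.3)
  tbl <- generate_embryo_table(cfg, seed = 77)$table
  frac <- cohort_defect_fraction(tbl, "g", "symmetric", "A2_A8")$fraction
  # 3 SEs with the beta-binomial design effect 1 + (14-1)*rho
  se <- sqrt(0.2 * 0.8 * (1 + 13 * 0.3) / nrow(tbl))
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("the intra-embryo correlation of defect indicators matches rho", {
  rho <- 0.3
  cfg <- phenotype_config(genotype = "g", n_embryos = 500,
                          symmetric_rate = 0.3, symmetric_rho = rho)
  tbl <- generate_embryo_table(cfg, seed = 55)$table
  cl <- classify_hemisegments(tbl)
  # one-way ANOVA ICC estimator over embryos (k = 14 hemisegments each)
  y <- as.numeric(cl$symmetric_defect)
  g <- factor(cl$embryo_id)
  k <- 14
  ms <- anova(stats::lm(y ~ g))
  msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  expect_lt(abs(icc - rho), 0.06)
})

test_that("rho = 0 collapses to a shared binomial rate", {
  m <- 0.3
  cfg <- phenotype_config(genotype = "g", n_embryos = 500,
                          symmetric_rate = m, symmetric_rho = 0)
  tbl <- generate_embryo_table(cfg, seed = 91)$table
  props <- embryo_defect_proportions(tbl, "symmetric", "A2_A8")
  expect_lt(abs(var(props$proportion) - m * (1 - m) / 14), 0.004)
})

test_that("lumen generation respects the configured region models", {
  cfg <- phenotype_config(genotype = "g", n_embryos = 4,
                          lumen_aorta_sd = 0, lumen_heart_sd = 0)
  lum <- generate_lumen_table(cfg, seed = 3)
  aorta <- lum$diameter[lum$position %in% c("A2", "A3", "A4")]
  heart <- lum$diameter[lum$position %in% c("A6", "A7")]
  expect_true(all(aorta == 0.66))
  expect_true(all(heart == 2.18))

  again <- generate_lumen_table(cfg, seed = 3)
  expect_equal(lum, again, ignore_attr = TRUE)
})

test_that("null pairs share one generative process under distinct labels", {
  cfg <- phenotype_config(symmetric_rate = 0.15, symmetric_rho = 0.3)
  pair <- generate_null_pair(cfg, n_a = 10, n_b = 12, seed = 8)
  expect_identical(unique(pair$a$table$genotype), "null_a")
  expect_identical(unique(pair$b$table$genotype), "null_b")
  expect_identical(length(unique(pair$a$table$embryo_id)), 10L)
  expect_identical(length(unique(pair$b$table$embryo_id)), 12L)
})

test_that("preset names are a stable contract", {
  expect_named(preset_configs(),
               c("wild_type", "trx_like", "trr_like", "set1_like"))
})

test_that("invalid configurations are rejected", {
  expect_error(phenotype_config(symmetric_rate = 1.2), "probability")
  expect_error(phenotype_config(symmetric_rho = 1), "rho")
  expect_error(phenotype_config(lumen_aorta_mean = 0), "positive")
  expect_error(phenotype_config(magnitude_probs = c("0" = 1)), "zero deviation")
  expect_error(phenotype_config(a8_tin_surplus_probs = c("0" = 0.5)), "sum to 1")
  expect_error(generate_embryo_table(phenotype_config()), "seed")
})
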