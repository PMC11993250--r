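test_that("hemisegments are classified against segment-specific expectations", {
  tbl <- tibble::tibble(
    genotype = "g", embryo_id = "e1", row = "left",
    segment = c("A5", "A8", "A2"),
    svp_count = c(2L, 2L, 1L),
    tin_count = c(4L, 2L, 4L)
  )
  out <- classify_hemisegments(tbl)
  # A5 conformant; A8 expects only 2 Tin CCs so 2/2 is normal
  expect_identical(out$symmetric_defect, c(FALSE, FALSE, FALSE))
  expect_identical(out$asymmetric_or_earlier_defect, c(FALSE, FALSE, TRUE))
  expect_identical(out$svp_delta, c(0L, 0L, -1L))
  expect_identical(out$tin_delta, c(0L, 0L, 0L))
})

test_that("classification is direction-agnostic in every segment", {
  bp <- reference_blueprint()
  for (seg in bp$segments) {
    for (shift in c(-1L, 1L)) {
      tbl <- tibble::tibble(
        genotype = "g", embryo_id = "e1", row = "left", segment = seg,
        svp_count = bp$expected_svp[[seg]] + shift,
        tin_count = bp$expected_tin[[seg]] + shift
      )
      out <- classify_hemisegments(tbl)
      expect_true(out$symmetric_defect)
      expect_true(out$asymmetric_or_earlier_defect)
    }
  }
})

test_that("one hemisegment can carry both defect classes; tallies are independent", {
  tbl <- tibble::tibble(genotype = "g", embryo_id = "e1", row = "left",
                        segment = "A4", svp_count = 1L, tin_count = 5L)
  out <- classify_hemisegments(tbl)
  expect_true(out$symmetric_defect && out$asymmetric_or_earlier_defect)
  both <- cohort_defect_fraction(tbl, "g", "symmetric", "A2_A8")$defective +
    cohort_defect_fraction(tbl, "g", "asymmetric_or_earlier", "A2_A8")$defective
  expect_identical(both, 2L)
})

test_that("a blueprint-conformant table yields zero defects in every class and range", {
  tbl <- blueprint_table("wt", n_embryos = 3)
  for (cls in c("symmetric", "asymmetric_or_earlier", "any")) {
    for (rng in c("A2_A8", "A3_A8")) {
      expect_identical(cohort_defect_fraction(tbl, "wt", cls, rng)$defective, 0L)
    }
  }
})

test_that("embryo proportions count defective over scored hemisegments", {
  tbl <- blueprint_table("g", n_embryos = 1)
  props <- embryo_defect_proportions(tbl, "symmetric", "A2_A8")
  expect_identical(props$proportion, 0)

  # 7 of 14 hemisegments Tin-defective -> 0.5
  half <- tbl
  half$tin_count[1:7] <- half$tin_count[1:7] + 1L
  props <- embryo_defect_proportions(half, "symmetric", "A2_A8")
  expect_identical(props$scored_hemisegments, 14L)
  expect_identical(props$proportion, 0.5)

  # 3 of 12 Svp-defective over A3-A8 -> 0.25
  quart <- tbl
  a3up <- which(quart$segment != "A2")
  quart$svp_count[a3up[1:3]] <- quart$svp_count[a3up[1:3]] - 1L
  props <- embryo_defect_proportions(quart, "asymmetric_or_earlier", "A3_A8")
  expect_identical(props$scored_hemisegments, 12L)
  expect_identical(props$proportion, 0.25)

  expect_error(
    embryo_defect_proportions(tbl, embryo_id = "no_such_embryo"),
    "no scored hemisegments"
  )
})

test_that("cohort fractions pool hemisegments across embryos", {
  wt <- blueprint_table("wt", n_embryos = 15)
  res <- cohort_defect_fraction(wt, "wt", "symmetric", "A2_A8")
  expect_identical(res$scored, 210L)
  expect_identical(res$fraction, 0)

  one <- wt
  one$tin_count[1] <- one$tin_count[1] + 1L
  expect_equal(cohort_defect_fraction(one, "wt", "symmetric")$fraction, 1 / 210)

  # fully penetrant single-Svp A2 phenotype: 30/30 over range {A2}
  pen <- blueprint_table("trx", n_embryos = 15)
  pen$svp_count[pen$segment == "A2"] <- 1L
  res <- cohort_defect_fraction(pen, "trx", "asymmetric_or_earlier", "A2")
  expect_identical(res$defective, 30L)
  expect_identical(res$scored, 30L)
  expect_identical(res$fraction, 1)

  expect_error(cohort_defect_fraction(wt, "absent"), "not present")
})

test_that("pooled fraction equals the weighted mean of embryo proportions", {
  set.seed(11)
  cfg <- phenotype_config(genotype = "g", n_embryos = 8,
                          symmetric_rate = 0.3, symmetric_rho = 0.4)
  tbl <- generate_embryo_table(cfg, seed = 11)$table
  pooled <- cohort_defect_fraction(tbl, "g", "symmetric", "A2_A8")$fraction
  props <- embryo_defect_proportions(tbl, "symmetric", "A2_A8")
  weighted <- sum(props$proportion * props$scored_hemisegments) /
    sum(props$scored_hemisegments)
  expect_equal(pooled, weighted)
  # equal scoring per embryo: pooled = unweighted mean of embryo proportions
  expect_equal(pooled, mean(props$proportion))
})

test_that("segment summaries pool contralateral hemisegments per embryo", {
  wt <- blueprint_table("wt", n_embryos = 15)
  res <- segment_cc_summary(wt, "wt", "A2", "svp")
  expect_identical(res$n_segments, 15L)
  expect_equal(res$mean, 4.0)
  expect_equal(res$sd, 0)

  ones <- wt
  ones$svp_count <- 1L
  expect_equal(segment_cc_summary(ones, "wt", "A6", "svp")$mean, 2.0)

  # unpaired hemisegment: embryo excluded with a warning
  unpaired <- wt[-1, ]
  expect_warning(res <- segment_cc_summary(unpaired, "wt", "A2", "svp"),
                 "unpaired")
  expect_identical(res$n_segments, 14L)
})

test_that("anterior CC summaries work per row across embryos", {
  wt <- blueprint_table("wt", n_embryos = 4, anterior = 12L)
  res <- anterior_cc_summary(wt, "wt", "left")
  expect_equal(res$mean, 12)
  expect_equal(res$sd, 0)
  expect_identical(res$n, 4L)

  two <- blueprint_table("wt", n_embryos = 2)
  two$anterior_cc_count[two$segment == "A2" & two$row == "left"] <- c(12L, 13L)
  expect_equal(anterior_cc_summary(two, "wt", "left")$mean, 12.5)

  noa <- blueprint_table("wt", n_embryos = 2)
  noa$anterior_cc_count <- NA_integer_
  expect_error(anterior_cc_summary(noa, "wt", "left"), "No anterior CC counts")
})
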