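# Fixture builders shared across the suite. All data are generated in code.

# A blueprint-conformant table: every hemisegment carries exactly the
# expected Svp/Tin counts, anterior counts attached to A2 records.
blueprint_table <- function(genotypes = "wt", n_embryos = 2,
                            segments = paste0("A", 2:8), anterior = 12L) {
  bp <- reference_blueprint()
  purrr::map_dfr(genotypes, function(g) {
    grid <- tidyr::expand_grid(
      embryo_id = sprintf("%s_e%02d", g, seq_len(n_embryos)),
      row = c("left", "right"),
      segment = segments
    )
    tibble::tibble(
      genotype = g,
      embryo_id = grid$embryo_id,
      row = grid$row,
      segment = grid$segment,
      svp_count = unname(bp$expected_svp[grid$segment]),
      tin_count = unname(bp$expected_tin[grid$segment]),
      anterior_cc_count = ifelse(grid$segment == "A2", anterior, NA_integer_)
    )
  })
}

# A random valid table (arbitrary non-negative counts, possibly missing
# hemisegments) for round-trip properties.
random_valid_table <- function(seed, n_embryos = 3, missing_rate = 0.15) {
  set.seed(seed)
  tbl <- blueprint_table("geno_x", n_embryos = n_embryos)
  tbl$svp_count <- sample(0:5, nrow(tbl), replace = TRUE)
  tbl$tin_count <- sample(0:7, nrow(tbl), replace = TRUE)
  keep <- runif(nrow(tbl)) >= missing_rate
  tbl[keep, , drop = FALSE]
}

# A lumen table with all five positions per embryo.
lumen_fixture <- function(genotype = "wt", n_embryos = 3,
                          aorta = c(0.6, 0.6, 0.78), heart = c(2.0, 2.4)) {
  purrr::map_dfr(seq_len(n_embryos), function(i) {
    tibble::tibble(
      genotype = genotype,
      embryo_id = sprintf("%s_e%02d", genotype, i),
      position = c("A2", "A3", "A4", "A6", "A7"),
      diameter = c(aorta, heart)
    )
  })
}
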