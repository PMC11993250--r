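#' Phenotype configuration for the synthetic cohort generator
#'
#' Describes one genotype's generative model for per-hemisegment Svp/Tin
#' counts and lumen diameters. Stochastic defects follow a beta-binomial
#' scheme: each embryo draws a per-class defect probability from a Beta
#' distribution with mean `m` and intra-embryo (intra-class) correlation
#' `rho` (shapes `a = m(1-rho)/rho`, `b = (1-m)(1-rho)/rho`; `rho = 0`
#' degenerates to a shared fixed rate), and each hemisegment's defect
#' indicator is Bernoulli at that embryo's rate. Realized defects perturb
#' the blueprint count by a signed magnitude drawn from `magnitude_probs`,
#' clamped at zero (Svp additionally capped at 4 unless
#' `svp_supernumerary_allowed`). Deterministic phenotype flags are applied
#' afterwards, overriding stochastic draws, so penetrance-1 phenotypes are
#' exact: `a2_single_svp_penetrance` forces `svp_count = 1` in A2, and a
#' non-trivial `a8_tin_surplus_probs` sets the A8 Tin count to expectation
#' plus a drawn surplus.
#'
#' @param genotype Genotype label for generated records.
#' @param n_embryos Number of embryos in the cohort.
#' @param segments Segments covered (default A2--A8).
#' @param rows Rows covered (default both).
#' @param symmetric_rate,asymmetric_rate Mean per-hemisegment defect rate
#'   `m` for the Tin (symmetric) and Svp (asymmetric-or-earlier) classes.
#' @param symmetric_rho,asymmetric_rho Intra-embryo correlation `rho` of the
#'   defect indicators, in `[0, 1)`.
#' @param a2_single_svp_penetrance Probability that an A2 hemisegment is
#'   forced to a single Svp CC (1 = fully penetrant).
#' @param a8_tin_surplus_probs Named numeric vector of probabilities over
#'   added A8 Tin CCs (names "0", "1", ...). The default `c("0" = 1)`
#'   disables the flag.
#' @param svp_supernumerary_allowed If `FALSE`, Svp counts are capped at 4.
#' @param magnitude_probs Named probabilities over signed count deviations
#'   applied to defective hemisegments (names like "-2", "-1", "1", "2").
#' @param anterior_mean,anterior_sd Normal model (integer-rounded, floored
#'   at 0) for the per-row anterior-aorta CC count attached to A2 records.
#' @param lumen_aorta_mean,lumen_aorta_sd Posterior-aorta lumen diameter
#'   model (um), truncated at 0.
#' @param lumen_heart_mean,lumen_heart_sd Heart-proper lumen diameter model
#'   (um), truncated at 0.
#' @param missingness Per-hemisegment probability of being unscoreable
#'   (dropped from the table).
#' @param seed Default seed used by the generator when none is supplied.
#' @return Object of class `dv_phenotype_config` (a validated list).
#' @export
phenotype_config <- function(genotype = "wild_type",
                             n_embryos = 15,
                             segments = paste0("A", 2:8),
                             rows = c("left", "right"),
                             symmetric_rate = 0,
                             symmetric_rho = 0.3,
                             asymmetric_rate = 0,
                             asymmetric_rho = 0.3,
                             a2_single_svp_penetrance = 0,
                             a8_tin_surplus_probs = c("0" = 1),
                             svp_supernumerary_allowed = FALSE,
                             magnitude_probs = c("-2" = 0.15, "-1" = 0.35,
                                                 "1" = 0.35, "2" = 0.15),
                             anterior_mean = 12.2,
                             anterior_sd = 0.8,
                             lumen_aorta_mean = 0.66,
                             lumen_aorta_sd = 0.1,
                             lumen_heart_mean = 2.18,
                             lumen_heart_sd = 0.1,
                             missingness = 0,
                             seed = NULL) {
  bp <- reference_blueprint()
  segments <- normalize_segment_labels(segments)
  unknown <- setdiff(segments, bp$segments)
  if (length(unknown)) {
    rlang::abort(paste0("Unknown segment(s): ", paste(unknown, collapse = ", "), "."))
  }
  rows <- normalize_row_labels(rows)
  if (!all(rows %in% bp$rows)) rlang::abort("Rows must be left/right.")
  check_unit <- function(v, name) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      rlang::abort(paste0("`", name, "` must be a probability in [0, 1]."))
    }
  }
  check_unit(symmetric_rate, "symmetric_rate")
  check_unit(asymmetric_rate, "asymmetric_rate")
  check_unit(a2_single_svp_penetrance, "a2_single_svp_penetrance")
  check_unit(missingness, "missingness")
  for (r in c(symmetric_rho, asymmetric_rho)) {
    if (r < 0 || r >= 1) rlang::abort("Correlations `rho` must lie in [0, 1).")
  }
  check_probs <- function(p, name, integer_names = TRUE) {
    if (is.null(names(p)) || any(is.na(suppressWarnings(as.integer(names(p)))))) {
      rlang::abort(paste0("`", name, "` must be named by integer deviations."))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      rlang::abort(paste0("`", name, "` must be non-negative and sum to 1."))
    }
  }
  check_probs(a8_tin_surplus_probs, "a8_tin_surplus_probs")
  check_probs(magnitude_probs, "magnitude_probs")
  if (any(as.integer(names(magnitude_probs)) == 0L & magnitude_probs > 0)) {
    rlang::abort("`magnitude_probs` must not place mass on a zero deviation.")
  }
  if (lumen_aorta_mean <= 0 || lumen_heart_mean <= 0) {
    rlang::abort("Lumen means must be positive.")
  }
  if (anterior_sd < 0 || lumen_aorta_sd < 0 || lumen_heart_sd < 0) {
    rlang::abort("Standard deviations must be non-negative.")
  }
  if (n_embryos < 1) rlang::abort("`n_embryos` must be >= 1.")
  structure(
    list(genotype = as.character(genotype), n_embryos = as.integer(n_embryos),
         segments = segments, rows = rows,
         symmetric_rate = symmetric_rate, symmetric_rho = symmetric_rho,
         asymmetric_rate = asymmetric_rate, asymmetric_rho = asymmetric_rho,
         a2_single_svp_penetrance = a2_single_svp_penetrance,
         a8_tin_surplus_probs = a8_tin_surplus_probs,
         svp_supernumerary_allowed = svp_supernumerary_allowed,
         magnitude_probs = magnitude_probs,
         anterior_mean = anterior_mean, anterior_sd = anterior_sd,
         lumen_aorta_mean = lumen_aorta_mean, lumen_aorta_sd = lumen_aorta_sd,
         lumen_heart_mean = lumen_heart_mean, lumen_heart_sd = lumen_heart_sd,
         missingness = missingness, seed = seed),
    class = "dv_phenotype_config"
  )
}

# Prefix-stable substream seeds: sequential draws with replacement mean the
# first k seeds do not change when more embryos are requested.
derive_substream_seeds <- function(seed, n, salt = 0L) {
  set.seed(as.integer((as.numeric(seed) + as.numeric(salt)) %% 2147483647))
  sample.int(2147483646L, n, replace = TRUE)
}

draw_class_rate <- function(m, rho) {
  if (rho == 0 || m == 0 || m == 1) return(m)
  a <- m * (1 - rho) / rho
  b <- (1 - m) * (1 - rho) / rho
  stats::rbeta(1, a, b)
}

draw_magnitudes <- function(n, probs) {
  if (n == 0) return(integer(0))
  vals <- as.integer(names(probs))
  vals[sample.int(length(vals), n, replace = TRUE, prob = probs)]
}

generate_one_embryo <- function(config, blueprint, embryo_id, embryo_seed) {
  set.seed(embryo_seed)
  segs <- rep(config$segments, times = length(config$rows))
  rws <- rep(config$rows, each = length(config$segments))
  n_h <- length(segs)
  exp_svp <- unname(blueprint$expected_svp[segs])
  exp_tin <- unname(blueprint$expected_tin[segs])

  p_sym <- draw_class_rate(config$symmetric_rate, config$symmetric_rho)
  p_asym <- draw_class_rate(config$asymmetric_rate, config$asymmetric_rho)
  sym_def <- stats::runif(n_h) < p_sym
  asym_def <- stats::runif(n_h) < p_asym

  tin <- exp_tin
  tin[sym_def] <- tin[sym_def] + draw_magnitudes(sum(sym_def),
                                                 config$magnitude_probs)
  tin <- pmax(tin, 0L)
  svp <- exp_svp
  svp[asym_def] <- svp[asym_def] + draw_magnitudes(sum(asym_def),
                                                   config$magnitude_probs)
  svp <- pmax(svp, 0L)
  if (!config$svp_supernumerary_allowed) svp <- pmin(svp, 4L)

  # deterministic phenotype flags override stochastic draws
  if (config$a2_single_svp_penetrance > 0 && any(segs == "A2")) {
    is_a2 <- segs == "A2"
    forced <- stats::runif(sum(is_a2)) < config$a2_single_svp_penetrance
    svp[is_a2][forced] <- 1L
  }
  surplus_probs <- config$a8_tin_surplus_probs
  nontrivial_surplus <- !(length(surplus_probs) == 1 &&
                            names(surplus_probs) == "0")
  if (nontrivial_surplus && any(segs == "A8")) {
    is_a8 <- segs == "A8"
    surplus <- draw_surplus(sum(is_a8), surplus_probs)
    tin[is_a8] <- exp_tin[is_a8] + surplus
  }

  anterior <- rep(NA_integer_, n_h)
  if (any(segs == "A2")) {
    for (r in config$rows) {
      v <- max(0, round(stats::rnorm(1, config$anterior_mean,
                                     config$anterior_sd)))
      anterior[segs == "A2" & rws == r] <- as.integer(v)
    }
  }

  keep <- if (config$missingness > 0) {
    stats::runif(n_h) >= config$missingness
  } else rep(TRUE, n_h)

  tibble::tibble(
    genotype = config$genotype,
    embryo_id = embryo_id,
    row = rws,
    segment = segs,
    svp_count = as.integer(svp),
    tin_count = as.integer(tin),
    anterior_cc_count = anterior
  )[keep, , drop = FALSE]
}

draw_surplus <- function(n, probs) {
  vals <- as.integer(names(probs))
  vals[sample.int(length(vals), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic scored cohort
#'
#' Produces a per-hemisegment count table and matching lumen table for one
#' genotype under a [phenotype_config()]. Each embryo is generated on an
#' independent substream derived from the master seed, so enlarging a
#' cohort does not perturb earlier embryos, and regeneration from
#' (config, seed) is bit-identical. Generated tables always pass
#' [validate_hemisegment_table()].
#'
#' @param config A [phenotype_config()].
#' @param seed Master integer seed (defaults to `config$seed`).
#' @return Object of class `dv_cohort`: list with `table` (hemisegment
#'   tibble), `lumen` (lumen tibble), `config`, `seed`.
#' @examples
#' wt <- generate_embryo_table(preset_configs()$wild_type, seed = 1)
#' nrow(wt$table)  # 15 embryos x 14 hemisegments = 210
#' @export
generate_embryo_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dv_phenotype_config"))
  if (is.null(seed)) {
    rlang::abort("A seed is required (argument `seed` or `config$seed`).")
  }
  bp <- reference_blueprint()
  embryo_seeds <- derive_substream_seeds(seed, config$n_embryos, salt = 0L)
  ids <- sprintf("%s_e%02d", config$genotype, seq_len(config$n_embryos))
  parts <- vector("list", config$n_embryos)
  for (i in seq_len(config$n_embryos)) {
    parts[[i]] <- generate_one_embryo(config, bp, ids[i], embryo_seeds[i])
  }
  table <- validate_hemisegment_table(dplyr::bind_rows(parts), bp)
  attr(table, "provenance") <- paste0("synthetic:", config$genotype,
                                      ":seed=", seed)
  lumen <- generate_lumen_table(config, seed = seed)
  structure(list(table = table, lumen = lumen, config = config,
                 seed = as.integer(seed)),
            class = "dv_cohort")
}

#' @export
print.dv_cohort <- function(x, ...) {
  cat("<synthetic dorsal-vessel cohort>\n")
  cat(sprintf("  genotype: %s, embryos: %d, hemisegment records: %d\n",
              x$config$genotype, x$config$n_embryos, nrow(x$table)))
  cat(sprintf("  lumen measurements: %d, seed: %d\n", nrow(x$lumen), x$seed))
  invisible(x)
}

#' Generate a synthetic lumen diameter table
#'
#' Per embryo, five positive diameters: A2--A4 from the posterior-aorta
#' distribution and A6--A7 from the heart-proper distribution, each a
#' normal truncated at 0 (zero sd yields the mean exactly).
#'
#' @inheritParams generate_embryo_table
#' @return Validated lumen tibble.
#' @export
generate_lumen_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dv_phenotype_config"))
  if (is.null(seed)) {
    rlang::abort("A seed is required (argument `seed` or `config$seed`).")
  }
  rtrunc_pos <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    v <- stats::rnorm(n, mean, sd)
    while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mean, sd)
    v
  }
  embryo_seeds <- derive_substream_seeds(seed, config$n_embryos,
                                         salt = 1000003L)
  ids <- sprintf("%s_e%02d", config$genotype, seq_len(config$n_embryos))
  parts <- vector("list", config$n_embryos)
  for (i in seq_len(config$n_embryos)) {
    set.seed(embryo_seeds[i])
    parts[[i]] <- tibble::tibble(
      genotype = config$genotype,
      embryo_id = ids[i],
      position = lumen_positions(),
      diameter = c(rtrunc_pos(3, config$lumen_aorta_mean,
                              config$lumen_aorta_sd),
                   rtrunc_pos(2, config$lumen_heart_mean,
                              config$lumen_heart_sd))
    )
  }
  validate_lumen_table(dplyr::bind_rows(parts))
}

#' Generate a pair of cohorts under one null configuration
#'
#' Draws two cohorts from the identical generative process, differing only
#' in genotype label and substream seeds -- the harness for type-I-error
#' studies of the genotype comparison.
#'
#' @param config A [phenotype_config()] shared by both cohorts.
#' @param n_a,n_b Cohort sizes.
#' @param seed Master seed.
#' @return List of two `dv_cohort` objects named `a` and `b`.
#' @export
generate_null_pair <- function(config, n_a = 15, n_b = 15, seed) {
  stopifnot(inherits(config, "dv_phenotype_config"))
  seeds <- derive_substream_seeds(seed, 2L, salt = 2000003L)
  cfg_a <- config; cfg_a$genotype <- "null_a"; cfg_a$n_embryos <- as.integer(n_a)
  cfg_b <- config; cfg_b$genotype <- "null_b"; cfg_b$n_embryos <- as.integer(n_b)
  list(a = generate_embryo_table(cfg_a, seed = seeds[1]),
       b = generate_embryo_table(cfg_b, seed = seeds[2]))
}

#' Named preset phenotype configurations
#'
#' Encodes the qualitative phenotype classes of the study as generator
#' presets (phenomenological count distributions, not mechanistic claims):
#'
#' * `wild_type` -- blueprint-conformant: zero defect rates, no deterministic
#'   flags, wild-type lumen regions (0.66 um aorta, 2.18 um heart proper).
#' * `trx_like` -- elevated symmetric (Tin) defect rate only; fully penetrant
#'   single-Svp A2 phenotype; A8 Tin surplus (per-segment A8 Tin mean around
#'   6.8); heart-proper lumen collapsed to the aorta width (homeotic
#'   transformation of the heart proper).
#' * `trr_like`, `set1_like` -- elevated rates in *both* defect classes;
#'   supernumerary Svp counts permitted; wild-type-like lumen.
#'
#' Within-embryo correlation values are framework parameters (no empirical
#' estimate exists for them), set to 0.3 throughout.
#'
#' @return Named list of [phenotype_config()] objects with stable names
#'   `wild_type`, `trx_like`, `trr_like`, `set1_like`.
#' @export
preset_configs <- function() {
  list(
    wild_type = phenotype_config(genotype = "wild_type"),
    trx_like = phenotype_config(
      genotype = "trx_like",
      symmetric_rate = 0.25, symmetric_rho = 0.3,
      asymmetric_rate = 0, asymmetric_rho = 0.3,
      a2_single_svp_penetrance = 1,
      a8_tin_surplus_probs = c("0" = 0.1, "1" = 0.5, "2" = 0.3, "3" = 0.1),
      anterior_mean = 12.6,
      lumen_heart_mean = 0.66, lumen_heart_sd = 0.1
    ),
    trr_like = phenotype_config(
      genotype = "trr_like",
      symmetric_rate = 0.20, symmetric_rho = 0.3,
      asymmetric_rate = 0.13, asymmetric_rho = 0.3,
      svp_supernumerary_allowed = TRUE
    ),
    set1_like = phenotype_config(
      genotype = "set1_like",
      symmetric_rate = 0.20, symmetric_rho = 0.3,
      asymmetric_rate = 0.15, asymmetric_rho = 0.3,
      svp_supernumerary_allowed = TRUE
    )
  )
}
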