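#' Build a pipeline run configuration
#'
#' Bundles the inputs and settings for one end-to-end analysis run: the
#' hemisegment and lumen tables (paths or in-memory tibbles, or preset names
#' for synthetic cohorts), the list of genotype comparisons, and the
#' permutation settings.
#'
#' @param hemisegments Hemisegment table, a path to one, or a character
#'   vector of [preset_configs()] names to simulate.
#' @param lumen Optional lumen table or path; generated alongside presets.
#' @param comparisons Data frame (or tibble) with columns `genotype_a`,
#'   `genotype_b`, `defect_class`, `segment_range`, one row per comparison.
#' @param n_perm Permutations per comparison.
#' @param seed Master seed (presets and per-comparison substreams).
#' @param alternative Sidedness of every permutation test.
#' @param segment_summaries Data frame with columns `genotype`, `segment`,
#'   `lineage` for segment-level CC summaries (`NULL` for none).
#' @return Object of class `dv_run_config`.
#' @export
run_config <- function(hemisegments, lumen = NULL, comparisons,
                       n_perm = 1e4, seed = 1,
                       alternative = "two_sided",
                       segment_summaries = NULL) {
  comparisons <- tibble::as_tibble(comparisons)
  needed <- c("genotype_a", "genotype_b", "defect_class", "segment_range")
  missing <- setdiff(needed, names(comparisons))
  if (length(missing)) {
    rlang::abort(paste0("`comparisons` is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  structure(list(hemisegments = hemisegments, lumen = lumen,
                 comparisons = comparisons, n_perm = n_perm,
                 seed = as.integer(seed), alternative = alternative,
                 segment_summaries = segment_summaries),
            class = "dv_run_config")
}

resolve_inputs <- function(config) {
  hs <- config$hemisegments
  lumen <- config$lumen
  if (is.character(hs) && all(hs %in% names(preset_configs()))) {
    presets <- preset_configs()[hs]
    seeds <- derive_substream_seeds(config$seed, length(presets),
                                    salt = 3000017L)
    bundles <- purrr::map2(presets, seeds, generate_embryo_table)
    hs <- dplyr::bind_rows(purrr::map(bundles, "table"))
    lumen <- dplyr::bind_rows(purrr::map(bundles, "lumen"))
  } else if (is.character(hs)) {
    if (length(hs) != 1 || !file.exists(hs)) {
      rlang::abort(paste0("`hemisegments` must be a table, an existing path, ",
                          "or preset names (",
                          paste(names(preset_configs()), collapse = ", "), ")."))
    }
    hs <- read_hemisegment_table(hs)
    if (is.character(lumen)) lumen <- read_lumen_table(lumen)
  }
  hs <- validate_hemisegment_table(hs)
  if (!is.null(lumen)) lumen <- validate_lumen_table(lumen)
  list(hemisegments = hs, lumen = lumen)
}

#' Run the full dorsal-vessel analysis pipeline
#'
#' Orchestrates every stage on one pair of input tables: (a) pooled cohort
#' defect fractions per genotype, class and range; (b) pairwise permutation
#' tests on embryo-level proportions; (c) optional segment-level CC
#' summaries with Welch/BCa statistics; (d) per-genotype lumen region
#' comparisons. Every comparison runs on its own substream derived from the
#' master seed, recorded in the report, so any single p-value can be
#' regenerated in isolation. The pipeline is a pure function of
#' (inputs, config): identical inputs give identical outputs.
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, each report is written
#'   as a tab-separated file plus a human-readable `summary.txt`.
#' @return Invisibly, a list of tibbles: `defect_fractions`,
#'   `permutation_tests`, `segment_summaries`, `lumen_comparisons`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "dv_run_config"))
  inputs <- resolve_inputs(config)
  hs <- inputs$hemisegments
  genos <- unique(hs$genotype)
  referenced <- unique(c(config$comparisons$genotype_a,
                         config$comparisons$genotype_b))
  absent <- setdiff(referenced, genos)
  if (length(absent)) {
    rlang::abort(paste0("Comparison references absent genotype(s): ",
                        paste(absent, collapse = ", "), "."))
  }

  classes_ranges <- unique(config$comparisons[, c("defect_class",
                                                  "segment_range")])
  fractions <- purrr::pmap_dfr(
    expand.grid(genotype = genos, i = seq_len(nrow(classes_ranges)),
                stringsAsFactors = FALSE),
    function(genotype, i) {
      cohort_defect_fraction(hs, genotype,
                             defect_class = classes_ranges$defect_class[i],
                             segment_range = classes_ranges$segment_range[i])
    })

  comp_seeds <- derive_substream_seeds(config$seed,
                                       nrow(config$comparisons),
                                       salt = 4000037L)
  tests <- purrr::map_dfr(seq_len(nrow(config$comparisons)), function(i) {
    cmp <- config$comparisons[i, ]
    res <- compare_genotypes(hs, cmp$genotype_a, cmp$genotype_b,
                             defect_class = cmp$defect_class,
                             segment_range = cmp$segment_range,
                             n_perm = config$n_perm, seed = comp_seeds[i],
                             alternative = config$alternative)
    tibble::tibble(
      genotype_a = cmp$genotype_a, genotype_b = cmp$genotype_b,
      defect_class = cmp$defect_class, segment_range = cmp$segment_range,
      observed_beta1 = res$observed_beta1, n_perm = res$n_perm,
      n_exceed = res$n_exceed, p_value = res$p_value,
      alternative = res$alternative, seed = res$seed
    )
  })

  seg_summaries <- NULL
  if (!is.null(config$segment_summaries)) {
    ss <- tibble::as_tibble(config$segment_summaries)
    seg_summaries <- purrr::map_dfr(seq_len(nrow(ss)), function(i) {
      segment_cc_summary(hs, ss$genotype[i], ss$segment[i], ss$lineage[i])
    })
  }

  lumen_cmp <- NULL
  if (!is.null(inputs$lumen)) {
    lumen_cmp <- purrr::map_dfr(unique(inputs$lumen$genotype), function(g) {
      res <- compare_region_widths(inputs$lumen, g)
      tibble::tibble(genotype = g, n_embryos = res$n_embryos,
                     heart_proper_mean = res$mean_x,
                     posterior_aorta_mean = res$mean_y,
                     t_statistic = res$statistic, df = res$df,
                     p_value = res$p_value)
    })
  }

  reports <- list(defect_fractions = fractions,
                  permutation_tests = tests,
                  segment_summaries = seg_summaries,
                  lumen_comparisons = lumen_cmp)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(reports)) {
      if (!is.null(reports[[nm]])) {
        readr::write_tsv(reports[[nm]], file.path(output_dir,
                                                  paste0(nm, ".tsv")))
      }
    }
    summary_lines <- c(
      "dorsal-vessel analysis pipeline report",
      sprintf("master seed: %d; permutations per comparison: %d",
              config$seed, as.integer(config$n_perm)),
      sprintf("genotypes: %s", paste(genos, collapse = ", ")),
      "",
      "permutation tests:",
      sprintf("  %s vs %s [%s, %s]: beta1 = %.4f, p = %.6g (seed %d)",
              tests$genotype_a, tests$genotype_b, tests$defect_class,
              tests$segment_range, tests$observed_beta1, tests$p_value,
              tests$seed)
    )
    if (!is.null(lumen_cmp)) {
      summary_lines <- c(summary_lines, "",
        "lumen region comparisons (heart proper vs posterior aorta, um):",
        sprintf("  %s: %.2f vs %.2f, t = %.2f, p = %.4g",
                lumen_cmp$genotype, lumen_cmp$heart_proper_mean,
                lumen_cmp$posterior_aorta_mean, lumen_cmp$t_statistic,
                lumen_cmp$p_value))
    }
    writeLines(summary_lines, file.path(output_dir, "summary.txt"))
  }
  invisible(reports)
}
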