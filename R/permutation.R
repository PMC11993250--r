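#' Fit the two-group indicator linear model
#'
#' The genotype comparison model for embryo-level defect proportions is
#' `Y_j = beta0 + beta1 * I_j + e_j`, where `Y_j` is embryo j's proportion of
#' defective hemisegments and `I_j` indicates membership in the mutant
#' (phenotype) group. Least squares on this design has the closed form
#' `beta0 = mean(Y | I = 0)` and `beta1 = mean(Y | I = 1) - mean(Y | I = 0)`:
#' the genotype effect is the difference of group mean proportions.
#'
#' @param responses Numeric vector of embryo proportions in `[0, 1]`.
#' @param indicators Vector of 0/1 group indicators, same length.
#' @return An object of class `dv_indicator_fit`: list with `beta0`, `beta1`,
#'   `group_sizes` (n0, n1).
#' @examples
#' fit_indicator_glm(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1))  # beta1 = 0.4
#' @export
fit_indicator_glm <- function(responses, indicators) {
  if (length(responses) != length(indicators)) {
    rlang::abort("`responses` and `indicators` must have equal length.")
  }
  indicators <- as.integer(indicators)
  if (!all(indicators %in% c(0L, 1L))) {
    rlang::abort("`indicators` must be 0/1.")
  }
  if (any(is.na(responses)) || any(responses < 0 | responses > 1)) {
    rlang::abort("`responses` must be proportions in [0, 1].")
  }
  n1 <- sum(indicators)
  n0 <- length(indicators) - n1
  if (n0 == 0L || n1 == 0L) {
    rlang::abort("Both indicator groups must be non-empty.")
  }
  beta0 <- mean(responses[indicators == 0L])
  beta1 <- mean(responses[indicators == 1L]) - beta0
  structure(list(beta0 = beta0, beta1 = beta1,
                 group_sizes = c(n0 = n0, n1 = n1)),
            class = "dv_indicator_fit")
}

perm_alternatives <- function() c("two_sided", "greater", "less")

# Exceedance of a permuted effect against the observed one, with ties
# counted as exceedances (conservative, guarantees a valid p-value).
# A tiny absolute tolerance absorbs float noise in reordered sums.
exceeds <- function(perm, obs, alternative, tol = 1e-12) {
  switch(alternative,
         two_sided = abs(perm) >= abs(obs) - tol,
         greater = perm >= obs - tol,
         less = perm <= obs + tol)
}

new_permutation_result <- function(observed_beta1, n_perm, n_exceed, p_value,
                                   alternative, seed, method, extra = list()) {
  structure(
    c(list(observed_beta1 = observed_beta1,
           n_perm = n_perm,
           n_exceed = n_exceed,
           p_value = p_value,
           alternative = alternative,
           seed = seed,
           method = method),
      extra),
    class = "dv_permutation_result"
  )
}

#' @export
print.dv_permutation_result <- function(x, ...) {
  cat("<permutation test on indicator-model genotype effect>\n")
  cat(sprintf("  method: %s   alternative: %s\n", x$method, x$alternative))
  cat(sprintf("  observed beta1 = %.6g\n", x$observed_beta1))
  cat(sprintf("  permutations N = %d, exceedances n = %d\n",
              x$n_perm, x$n_exceed))
  cat(sprintf("  p-value = %.6g\n", x$p_value))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Monte-Carlo permutation p-value for the genotype effect
#'
#' Tests `H0: beta1 = 0` by randomly re-shuffling the genotype labels among
#' the embryos and recomputing the effect estimate. With `n` the number of
#' permuted estimates that meet or exceed the observed one (two-sided on
#' `|beta1|` by default; ties count as exceedances) and `N` the number of
#' random permutations, the p-value is `p = (n + 1) / (N + 1)`, which is
#' valid for clustered (per-embryo) responses because the embryo is the
#' exchangeable unit. The published analyses use `N = 1e6` permutations for
#' highly reproducible p-values; smaller `N` trades resolution for speed.
#'
#' @inheritParams fit_indicator_glm
#' @param n_perm Number of random permutations N (default `1e6`).
#' @param seed Integer seed; recorded in the result.
#' @param alternative `"two_sided"` (default), `"greater"`, or `"less"`
#'   (signed exceedance of beta1).
#' @return A `dv_permutation_result`.
#' @export
sampled_permutation_pvalue <- function(responses, indicators, n_perm = 1e6,
                                       seed = NULL,
                                       alternative = c("two_sided", "greater",
                                                       "less")) {
  alternative <- rlang::arg_match(alternative)
  if (!is.numeric(n_perm) || n_perm < 1) rlang::abort("`n_perm` must be >= 1.")
  n_perm <- as.integer(n_perm)
  fit <- fit_indicator_glm(responses, indicators)
  obs <- fit$beta1
  n <- length(responses)
  n1 <- fit$group_sizes[["n1"]]
  n0 <- fit$group_sizes[["n0"]]
  total <- sum(responses)
  if (!is.null(seed)) set.seed(seed)
  perm_beta1 <- vapply(seq_len(n_perm), function(i) {
    s1 <- sum(responses[sample.int(n, n1)])
    s1 / n1 - (total - s1) / n0
  }, numeric(1))
  n_exceed <- sum(exceeds(perm_beta1, obs, alternative))
  new_permutation_result(
    observed_beta1 = obs, n_perm = n_perm, n_exceed = n_exceed,
    p_value = (n_exceed + 1) / (n_perm + 1),
    alternative = alternative, seed = seed, method = "sampled"
  )
}

#' Exact permutation p-value by enumeration
#'
#' Enumerates every assignment of the group-1 labels to the embryos (all
#' `choose(n, n1)` subsets) instead of sampling, providing an exact reference
#' distribution for small samples and an independent oracle for
#' [sampled_permutation_pvalue()]. The reported `p_value` is the exact
#' fraction `n / N` of assignments (observed included) meeting the
#' exceedance rule; the Monte-Carlo add-one convention `(n + 1) / (N + 1)`
#' is reported alongside as `p_add_one` for comparability.
#'
#' @inheritParams sampled_permutation_pvalue
#' @param max_assignments Enumeration guard on `choose(n, n1)` (default 1e6).
#' @return A `dv_permutation_result` with `method = "exact"` and `p_add_one`.
#' @examples
#' exact_permutation_pvalue(c(1, 1, 0, 0), c(1, 1, 0, 0))$p_value  # 2/6
#' @export
exact_permutation_pvalue <- function(responses, indicators,
                                     alternative = c("two_sided", "greater",
                                                     "less"),
                                     max_assignments = 1e6) {
  alternative <- rlang::arg_match(alternative)
  fit <- fit_indicator_glm(responses, indicators)
  obs <- fit$beta1
  n <- length(responses)
  n1 <- fit$group_sizes[["n1"]]
  n0 <- fit$group_sizes[["n0"]]
  n_assign <- choose(n, n1)
  if (n_assign > max_assignments) {
    rlang::abort(paste0("choose(", n, ", ", n1, ") = ", n_assign,
                        " assignments exceeds the enumeration guard (",
                        format(max_assignments, scientific = FALSE), ")."))
  }
  subsets <- utils::combn(n, n1)
  total <- sum(responses)
  s1 <- colSums(matrix(responses[subsets], nrow = n1))
  perm_beta1 <- s1 / n1 - (total - s1) / n0
  n_exceed <- sum(exceeds(perm_beta1, obs, alternative))
  new_permutation_result(
    observed_beta1 = obs, n_perm = as.integer(n_assign), n_exceed = n_exceed,
    p_value = n_exceed / n_assign,
    alternative = alternative, seed = NULL, method = "exact",
    extra = list(p_add_one = (n_exceed + 1) / (n_assign + 1))
  )
}

#' Permutation comparison of two genotypes
#'
#' End-to-end genotype comparison: computes per-embryo defect proportions
#' for both cohorts ([embryo_defect_proportions()]), codes
#' `genotype_b` as the indicator-1 group, and runs the permutation test.
#' Provenance (defect class, segment range, seed, N) is carried in the
#' result so any single p-value can be regenerated in isolation.
#'
#' @param table Hemisegment table containing both genotypes.
#' @param genotype_a Reference genotype (indicator 0).
#' @param genotype_b Comparison genotype (indicator 1).
#' @inheritParams embryo_defect_proportions
#' @inheritParams sampled_permutation_pvalue
#' @return A `dv_permutation_result` with fields `genotype_a`, `genotype_b`,
#'   `defect_class`, `segment_range`.
#' @export
compare_genotypes <- function(table, genotype_a, genotype_b,
                              defect_class = "symmetric",
                              segment_range = "A2_A8",
                              n_perm = 1e6, seed = NULL,
                              alternative = c("two_sided", "greater", "less"),
                              blueprint = reference_blueprint()) {
  alternative <- rlang::arg_match(alternative)
  present <- unique(table$genotype)
  for (g in c(genotype_a, genotype_b)) {
    if (!g %in% present) {
      rlang::abort(paste0("Genotype `", g, "` not present in the table."))
    }
  }
  props <- embryo_defect_proportions(table, defect_class = defect_class,
                                     segment_range = segment_range,
                                     genotype = c(genotype_a, genotype_b),
                                     blueprint = blueprint)
  y <- props$proportion
  ind <- as.integer(props$genotype == genotype_b)
  res <- sampled_permutation_pvalue(y, ind, n_perm = n_perm, seed = seed,
                                    alternative = alternative)
  res$genotype_a <- genotype_a
  res$genotype_b <- genotype_b
  res$defect_class <- defect_class
  res$segment_range <- if (length(segment_range) == 1) segment_range else
    paste(resolve_segment_range(segment_range, blueprint), collapse = "+")
  res
}
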