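#' Welch two-sample unequal-variance t-test
#'
#' The two-tailed, two-sample unequal-variance t-test used for pairwise
#' cardial-cell count and lumen-width comparisons. The statistic is
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch--Satterthwaite (fractional) degrees of freedom.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return Object of class `dv_t_test`: `statistic`, `df`, `p_value`
#'   (two-tailed), `mean_x`, `mean_y`, `var_x`, `var_y`, `n_x`, `n_y`.
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("Each sample must contain at least 2 observations.")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    rlang::abort("Both samples have zero variance; t is undefined.")
  }
  nx <- length(x); ny <- length(y)
  se2x <- vx / nx; se2y <- vy / ny
  statistic <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(statistic), df)
  structure(list(statistic = statistic, df = df, p_value = p,
                 mean_x = mean(x), mean_y = mean(y),
                 var_x = vx, var_y = vy, n_x = nx, n_y = ny),
            class = "dv_t_test")
}

#' @export
print.dv_t_test <- function(x, ...) {
  cat("<Welch two-sample t-test>\n")
  cat(sprintf("  t = %.4f, df = %.2f, two-tailed p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  means: %.4g vs %.4g (n = %d, %d)\n",
              x$mean_x, x$mean_y, x$n_x, x$n_y))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA across two or more genotype groups
#' (between/within sum-of-squares decomposition; for two groups F equals the
#' square of the pooled-variance t statistic).
#'
#' @param groups List of numeric vectors, one per group, each of size >= 2.
#' @return Object of class `dv_anova`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    rlang::abort("`groups` must be a list of at least 2 samples.")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    rlang::abort("Each group must contain at least 2 observations.")
  }
  all_values <- unlist(groups, use.names = FALSE)
  grand <- mean(all_values)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_between <- length(groups) - 1L
  df_within <- sum(sizes) - length(groups)
  if (ss_within == 0) {
    rlang::abort("Within-group sum of squares is zero; F is undefined.")
  }
  f <- (ss_between / df_between) / (ss_within / df_within)
  structure(list(f_statistic = f, df_between = df_between,
                 df_within = df_within,
                 p_value = stats::pf(f, df_between, df_within,
                                     lower.tail = FALSE),
                 ss_between = ss_between, ss_within = ss_within),
            class = "dv_anova")
}

#' @export
print.dv_anova <- function(x, ...) {
  cat("<one-way ANOVA>\n")
  cat(sprintf("  F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

# Efron BCa machinery shared by the one- and two-sample interfaces.
bca_from_boot <- function(theta_hat, theta_star, theta_jack, alpha) {
  b <- length(theta_star)
  if (all(theta_star == theta_star[1])) {
    return(list(lower = theta_hat, upper = theta_hat, z0 = 0, a = 0,
                degenerate = TRUE))
  }
  # bias correction: bootstrap position of the observed statistic,
  # midpoint convention for ties
  frac <- (sum(theta_star < theta_hat) + 0.5 * sum(theta_star == theta_hat)) / b
  frac <- min(max(frac, 1 / (2 * b)), 1 - 1 / (2 * b))
  z0 <- stats::qnorm(frac)
  # acceleration: jackknife skewness
  d <- mean(theta_jack) - theta_jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  z_lo <- stats::qnorm(alpha / 2)
  z_hi <- stats::qnorm(1 - alpha / 2)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  qs <- stats::quantile(theta_star, probs = c(adj(z_lo), adj(z_hi)),
                        names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], z0 = z0, a = a, degenerate = FALSE)
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated (BCa) bootstrap interval for a statistic
#' of one sample, following the standard Efron construction: the bias
#' correction `z0` comes from the bootstrap distribution's position relative
#' to the observed statistic (midpoint convention for ties), and the
#' acceleration `a` from jackknife skewness. A degenerate bootstrap
#' distribution (all resample statistics equal) collapses the interval to
#' the point value with `degenerate = TRUE`.
#'
#' @param x Numeric sample, size >= 3.
#' @param statistic_fn Function of a numeric vector (default [mean()]).
#' @param n_boot Number of bootstrap resamples (default 5000, the
#'   convention used for between-group cardial-cell comparisons).
#' @param alpha Two-sided miscoverage level (default 0.05 for a 95\% CI).
#' @param seed Integer seed; recorded in the result.
#' @return Object of class `dv_bca`: `statistic`, `lower`, `upper`,
#'   `n_boot`, `alpha`, `z0`, `acceleration`, `seed`, `degenerate`.
#' @export
bca_bootstrap_ci <- function(x, statistic_fn = mean, n_boot = 5000,
                             alpha = 0.05, seed = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) rlang::abort("Sample size must be >= 3 for a BCa interval.")
  if (alpha <= 0 || alpha >= 1) rlang::abort("`alpha` must be in (0, 1).")
  theta_hat <- statistic_fn(x)
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  theta_star <- apply(idx, 2, function(i) statistic_fn(x[i]))
  theta_jack <- vapply(seq_len(n), function(i) statistic_fn(x[-i]), numeric(1))
  parts <- bca_from_boot(theta_hat, theta_star, theta_jack, alpha)
  if (parts$degenerate) {
    rlang::warn("Degenerate bootstrap distribution; interval collapsed to the point value.")
  }
  structure(list(statistic = theta_hat, lower = parts$lower,
                 upper = parts$upper, n_boot = as.integer(n_boot),
                 alpha = alpha, z0 = parts$z0, acceleration = parts$a,
                 seed = seed, degenerate = parts$degenerate),
            class = "dv_bca")
}

#' BCa bootstrap interval for a two-group mean difference
#'
#' BCa interval for `mean(x) - mean(y)`, resampling each group
#' independently; the acceleration uses the combined delete-one jackknife
#' over both samples. This is the default between-group bootstrap
#' comparison for segment-level cardial-cell counts.
#'
#' @param x,y Numeric samples, each of size >= 3.
#' @inheritParams bca_bootstrap_ci
#' @return A `dv_bca` object for the mean difference.
#' @export
bca_mean_diff_ci <- function(x, y, n_boot = 5000, alpha = 0.05, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3 || length(y) < 3) {
    rlang::abort("Each sample must contain at least 3 observations.")
  }
  theta_hat <- mean(x) - mean(y)
  if (!is.null(seed)) set.seed(seed)
  nx <- length(x); ny <- length(y)
  xs <- matrix(sample(x, nx * n_boot, replace = TRUE), nrow = nx)
  ys <- matrix(sample(y, ny * n_boot, replace = TRUE), nrow = ny)
  theta_star <- colMeans(xs) - colMeans(ys)
  jack_x <- vapply(seq_len(nx), function(i) mean(x[-i]) - mean(y), numeric(1))
  jack_y <- vapply(seq_len(ny), function(i) mean(x) - mean(y[-i]), numeric(1))
  parts <- bca_from_boot(theta_hat, theta_star, c(jack_x, jack_y), alpha)
  if (parts$degenerate) {
    rlang::warn("Degenerate bootstrap distribution; interval collapsed to the point value.")
  }
  structure(list(statistic = theta_hat, lower = parts$lower,
                 upper = parts$upper, n_boot = as.integer(n_boot),
                 alpha = alpha, z0 = parts$z0, acceleration = parts$a,
                 seed = seed, degenerate = parts$degenerate),
            class = "dv_bca")
}

#' @export
print.dv_bca <- function(x, ...) {
  cat("<BCa bootstrap interval>\n")
  cat(sprintf("  statistic = %.4g, %g%% CI [%.4g, %.4g] (B = %d)\n",
              x$statistic, 100 * (1 - x$alpha), x$lower, x$upper, x$n_boot))
  if (x$degenerate) cat("  (degenerate bootstrap distribution)\n")
  invisible(x)
}

#' Per-embryo lumen region widths
#'
#' The lumen width of the posterior aorta of an embryo is the mean of the
#' internal lumen diameters measured at the A2, A3 and A4 segments; the
#' heart-proper width is the mean over A6 and A7. If several diameters are
#' recorded at one position they are averaged per position first. Embryos
#' missing any of the five positions are an error (an incomplete embryo
#' cannot yield comparable region means).
#'
#' @param measurements Lumen table (see [validate_lumen_table()]); may hold
#'   one or many embryos.
#' @return Tibble with one row per embryo: `genotype`, `embryo_id`,
#'   `posterior_aorta_width`, `heart_proper_width` (um).
#' @export
region_lumen_widths <- function(measurements) {
  tbl <- tibble::as_tibble(measurements)
  required <- c("genotype", "embryo_id", "position", "diameter")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  tbl$position <- normalize_segment_labels(tbl$position)
  bad <- setdiff(unique(tbl$position), lumen_positions())
  if (length(bad)) {
    rlang::abort(paste0("Unknown lumen position(s): ",
                        paste(bad, collapse = ", "), "."))
  }
  if (any(tbl$diameter <= 0)) rlang::abort("Diameters must be positive.")
  per_pos <- tbl |>
    dplyr::group_by(.data$genotype, .data$embryo_id, .data$position) |>
    dplyr::summarise(diameter = mean(.data$diameter), .groups = "drop")
  counts <- per_pos |>
    dplyr::count(.data$genotype, .data$embryo_id)
  incomplete <- counts$embryo_id[counts$n != length(lumen_positions())]
  if (length(incomplete)) {
    rlang::abort(paste0("Embryo(s) missing lumen positions: ",
                        paste(utils::head(incomplete, 5), collapse = ", "),
                        " (all of ", paste(lumen_positions(), collapse = ", "),
                        " are required)."))
  }
  per_pos |>
    dplyr::group_by(.data$genotype, .data$embryo_id) |>
    dplyr::summarise(
      posterior_aorta_width = mean(.data$diameter[.data$position %in%
                                                    c("A2", "A3", "A4")]),
      heart_proper_width = mean(.data$diameter[.data$position %in%
                                                 c("A6", "A7")]),
      .groups = "drop"
    )
}

#' Compare lumen widths between heart proper and posterior aorta
#'
#' Welch two-tailed t-test of the per-embryo heart-proper width against the
#' per-embryo posterior-aorta width within one genotype. In wild type the
#' heart-proper lumen is markedly dilated relative to the aorta (about
#' 2.18 um vs 0.66 um); genotypes with a homeotically transformed heart
#' proper show no significant difference.
#'
#' @param measurements Lumen table containing the genotype.
#' @param genotype Genotype label.
#' @return A `dv_t_test` (x = heart-proper widths, y = posterior-aorta
#'   widths), with `n_embryos` attached.
#' @export
compare_region_widths <- function(measurements, genotype) {
  tbl <- tibble::as_tibble(measurements)
  if (!genotype %in% tbl$genotype) {
    rlang::abort(paste0("Genotype `", genotype, "` not present."))
  }
  widths <- region_lumen_widths(tbl[tbl$genotype == genotype, , drop = FALSE])
  if (nrow(widths) < 2) {
    rlang::abort("At least 2 complete embryos are required.")
  }
  res <- welch_t_test(widths$heart_proper_width, widths$posterior_aorta_width)
  res$n_embryos <- nrow(widths)
  res$genotype <- genotype
  res
}
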