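#' The wild-type dorsal-vessel blueprint
#'
#' The Drosophila embryonic dorsal vessel is a linear heart tube of exactly
#' 104 contractile cardial cells (CCs). Posterior to the anterior aorta (12
#' CCs per row that express neither Svp nor a hemisegmental pattern), the
#' vessel is organized into repeated cardiac hemisegments A2--A8, one per row
#' (left/right). Each hemisegment carries 2 Svp CCs followed by 4 Tin CCs,
#' except the posterior-most A8 hemisegment which is abbreviated to 2 Svp +
#' 2 Tin CCs.
#'
#' @param anterior_aorta_ccs_per_row CCs per row anterior to the first Svp CC
#'   of A2. Wild type: 12.
#' @param expected_svp Named integer vector, expected Svp CCs per hemisegment.
#' @param expected_tin Named integer vector, expected Tin CCs per hemisegment.
#'
#' @return An object of class `dv_blueprint`: a list with fields
#'   `segments`, `rows`, `anterior_aorta_ccs_per_row`, `expected_svp`,
#'   `expected_tin`.
#'
#' @examples
#' bp <- reference_blueprint()
#' bp$expected_tin[["A8"]]   # 2: the abbreviated posterior hemisegment
#' total_cc_count(bp)        # 104
#' @export
reference_blueprint <- function(anterior_aorta_ccs_per_row = 12L,
                                expected_svp = NULL,
                                expected_tin = NULL) {
  segments <- paste0("A", 2:8)
  if (is.null(expected_svp)) {
    expected_svp <- stats::setNames(rep(2L, 7L), segments)
  }
  if (is.null(expected_tin)) {
    expected_tin <- stats::setNames(c(rep(4L, 6L), 2L), segments)
  }
  segments <- names(expected_svp)
  if (!identical(names(expected_svp), names(expected_tin))) {
    rlang::abort("`expected_svp` and `expected_tin` must cover the same segments.")
  }
  if (any(expected_svp < 0) || any(expected_tin < 0) ||
      anterior_aorta_ccs_per_row < 0) {
    rlang::abort("Blueprint cell counts must be non-negative.")
  }
  structure(
    list(
      segments = segments,
      rows = c("left", "right"),
      anterior_aorta_ccs_per_row = as.integer(anterior_aorta_ccs_per_row),
      expected_svp = expected_svp,
      expected_tin = expected_tin
    ),
    class = "dv_blueprint"
  )
}

#' Total cardial-cell count implied by a blueprint
#'
#' Sums the per-row anterior aorta contribution and the hemisegmental Svp and
#' Tin expectations over both rows. The canonical wild-type blueprint gives
#' 104 = 2 x (12 anterior + 40 hemisegmental) CCs.
#'
#' @param blueprint A [reference_blueprint()] object.
#' @return Integer total CC count over both rows.
#' @examples
#' total_cc_count(reference_blueprint())  # 104
#' @export
total_cc_count <- function(blueprint = reference_blueprint()) {
  stopifnot(inherits(blueprint, "dv_blueprint"))
  as.integer(2L * (blueprint$anterior_aorta_ccs_per_row +
                     sum(blueprint$expected_svp) + sum(blueprint$expected_tin)))
}

#' @export
print.dv_blueprint <- function(x, ...) {
  cat("<dorsal-vessel blueprint>\n")
  cat("  segments:", paste(x$segments, collapse = " "), "\n")
  cat("  anterior aorta CCs/row:", x$anterior_aorta_ccs_per_row, "\n")
  cat("  Svp per hemisegment:", paste(x$expected_svp, collapse = " "), "\n")
  cat("  Tin per hemisegment:", paste(x$expected_tin, collapse = " "), "\n")
  cat("  total CCs (both rows):", total_cc_count(x), "\n")
  invisible(x)
}
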