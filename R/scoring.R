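#' Resolve a segment-range preset
#'
#' Two presets mirror the two comparison designs used for dorsal-vessel
#' defect fractions: `"A2_A8"` (all cardiac hemisegments) and `"A3_A8"`
#' (excluding A2, so that a fully penetrant A2-specific phenotype does not
#' dominate the hemisegment statistics). A character vector of segment
#' labels is also accepted.
#'
#' @param segment_range `"A2_A8"`, `"A3_A8"`, or a character vector of
#'   segment labels.
#' @param blueprint A [reference_blueprint()].
#' @return Character vector of segment labels.
#' @export
resolve_segment_range <- function(segment_range = "A2_A8",
                                  blueprint = reference_blueprint()) {
  if (length(segment_range) == 1 && segment_range %in% c("A2_A8", "A3_A8")) {
    segs <- switch(segment_range,
                   A2_A8 = blueprint$segments,
                   A3_A8 = setdiff(blueprint$segments, "A2"))
    return(segs)
  }
  segs <- normalize_segment_labels(segment_range)
  unknown <- setdiff(segs, blueprint$segments)
  if (length(unknown)) {
    rlang::abort(paste0("Unknown segment(s) in range: ",
                        paste(unknown, collapse = ", "), "."))
  }
  segs
}

defect_classes <- function() c("symmetric", "asymmetric_or_earlier", "any")

#' Classify hemisegments against the blueprint
#'
#' Each scored hemisegment is compared to its blueprint expectation. Any
#' deviation (increase or decrease) of the Tin CC count is a *symmetric*
#' cell-division defect; any deviation of the Svp CC count is an
#' *asymmetric-or-earlier* defect (a failed asymmetric division, or a defect
#' in an earlier symmetric progenitor division). The two classes are
#' evaluated independently, so one hemisegment can carry both. Signed deltas
#' (observed minus expected) are retained for diagnostics.
#'
#' @param table Hemisegment table (validated; see
#'   [validate_hemisegment_table()]).
#' @param blueprint A [reference_blueprint()].
#' @return The table with added columns `svp_delta`, `tin_delta`,
#'   `symmetric_defect`, `asymmetric_or_earlier_defect`.
#' @examples
#' tbl <- tibble::tibble(genotype = "wt", embryo_id = "e1", row = "left",
#'                       segment = c("A5", "A8"), svp_count = c(2, 2),
#'                       tin_count = c(4, 2))
#' classify_hemisegments(tbl)  # no defects: A8 expects only 2 Tin CCs
#' @export
classify_hemisegments <- function(table, blueprint = reference_blueprint()) {
  table <- validate_hemisegment_table(table, blueprint)
  seg <- table$segment
  table$svp_delta <- table$svp_count - unname(blueprint$expected_svp[seg])
  table$tin_delta <- table$tin_count - unname(blueprint$expected_tin[seg])
  table$symmetric_defect <- table$tin_delta != 0L
  table$asymmetric_or_earlier_defect <- table$svp_delta != 0L
  table
}

#' @keywords internal
defect_indicator <- function(classified, defect_class) {
  defect_class <- rlang::arg_match(defect_class, defect_classes())
  switch(defect_class,
         symmetric = classified$symmetric_defect,
         asymmetric_or_earlier = classified$asymmetric_or_earlier_defect,
         any = classified$symmetric_defect | classified$asymmetric_or_earlier_defect)
}

#' Per-embryo defect proportions
#'
#' Aggregates hemisegment defect calls to the embryo level: the proportion of
#' an embryo's scored hemisegments (within a segment range) that are
#' defective for a given class. This per-embryo proportion is the response
#' variable of the indicator-model permutation test, the unit of inference
#' that respects within-embryo correlation of defects.
#'
#' @param table Hemisegment table.
#' @param defect_class One of `"symmetric"`, `"asymmetric_or_earlier"`,
#'   `"any"`.
#' @param segment_range See [resolve_segment_range()].
#' @param genotype Optional genotype filter.
#' @param embryo_id Optional single embryo filter; errors if that embryo has
#'   no scored hemisegments in range.
#' @param blueprint A [reference_blueprint()].
#' @return Tibble with one row per embryo: `genotype`, `embryo_id`,
#'   `defect_class`, `segment_range`, `scored_hemisegments`,
#'   `defective_hemisegments`, `proportion`.
#' @export
embryo_defect_proportions <- function(table,
                                      defect_class = "symmetric",
                                      segment_range = "A2_A8",
                                      genotype = NULL,
                                      embryo_id = NULL,
                                      blueprint = reference_blueprint()) {
  segs <- resolve_segment_range(segment_range, blueprint)
  range_label <- if (length(segment_range) == 1) segment_range else
    paste(segs, collapse = "+")
  classified <- classify_hemisegments(table, blueprint)
  classified <- classified[classified$segment %in% segs, , drop = FALSE]
  if (!is.null(genotype)) {
    classified <- classified[classified$genotype %in% genotype, , drop = FALSE]
  }
  if (!is.null(embryo_id)) {
    classified <- classified[classified$embryo_id %in% embryo_id, , drop = FALSE]
    if (nrow(classified) == 0) {
      rlang::abort(paste0("Embryo `", embryo_id,
                          "` has no scored hemisegments in the requested range."))
    }
  }
  classified$defective <- defect_indicator(classified, defect_class)
  out <- classified |>
    dplyr::group_by(.data$genotype, .data$embryo_id) |>
    dplyr::summarise(
      scored_hemisegments = dplyr::n(),
      defective_hemisegments = sum(.data$defective),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      defect_class = defect_class,
      segment_range = range_label,
      proportion = .data$defective_hemisegments / .data$scored_hemisegments
    ) |>
    dplyr::select("genotype", "embryo_id", "defect_class", "segment_range",
                  "scored_hemisegments", "defective_hemisegments", "proportion")
  out
}

#' Pooled cohort defect fraction
#'
#' The fraction of all scored hemisegments of one genotype (within a segment
#' range) that are defective for a class -- the quantity plotted in
#' cohort-level defect-fraction summaries. Pooling is over hemisegments, so
#' the denominator counts present records only (missing hemisegments are
#' absent rows).
#'
#' @inheritParams embryo_defect_proportions
#' @param genotype Genotype label (must be present in the table).
#' @return One-row tibble: `genotype`, `defect_class`, `segment_range`,
#'   `defective`, `scored`, `fraction`.
#' @export
cohort_defect_fraction <- function(table, genotype,
                                   defect_class = "symmetric",
                                   segment_range = "A2_A8",
                                   blueprint = reference_blueprint()) {
  segs <- resolve_segment_range(segment_range, blueprint)
  range_label <- if (length(segment_range) == 1) segment_range else
    paste(segs, collapse = "+")
  classified <- classify_hemisegments(table, blueprint)
  if (!genotype %in% classified$genotype) {
    rlang::abort(paste0("Genotype `", genotype, "` not present in the table."))
  }
  classified <- classified[classified$genotype == genotype &
                             classified$segment %in% segs, , drop = FALSE]
  defective <- sum(defect_indicator(classified, defect_class))
  scored <- nrow(classified)
  tibble::tibble(
    genotype = genotype,
    defect_class = defect_class,
    segment_range = range_label,
    defective = defective,
    scored = scored,
    fraction = defective / scored
  )
}

#' Segment-level cardial-cell count summary
#'
#' Summarises per-*segment* CC counts for one genotype and lineage, where a
#' segment pools the two contralateral hemisegments (left + right). Embryos
#' with an unpaired hemisegment (one row missing) are excluded with a
#' warning. Means are reported at full precision; presentation layers round
#' to one decimal.
#'
#' @param table Hemisegment table.
#' @param genotype Genotype label.
#' @param segment Segment label, e.g. `"A2"` or `"A8"`.
#' @param lineage `"svp"` or `"tin"`.
#' @param blueprint A [reference_blueprint()].
#' @return One-row tibble: `genotype`, `segment`, `lineage`, `n_segments`,
#'   `mean`, `sd`.
#' @export
segment_cc_summary <- function(table, genotype, segment,
                               lineage = c("svp", "tin"),
                               blueprint = reference_blueprint()) {
  lineage <- rlang::arg_match(lineage)
  segment <- normalize_segment_labels(segment)
  table <- validate_hemisegment_table(table, blueprint)
  if (!genotype %in% table$genotype) {
    rlang::abort(paste0("Genotype `", genotype, "` not present in the table."))
  }
  sub <- table[table$genotype == genotype & table$segment == segment, ,
               drop = FALSE]
  if (nrow(sub) == 0) {
    rlang::abort(paste0("No `", segment, "` records for genotype `",
                        genotype, "`."))
  }
  col <- paste0(lineage, "_count")
  wide <- sub |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(n_rows = dplyr::n(),
                     segment_count = sum(.data[[col]]),
                     .groups = "drop")
  unpaired <- wide$embryo_id[wide$n_rows != 2L]
  if (length(unpaired)) {
    rlang::warn(paste0("Excluding ", length(unpaired),
                       " embryo(s) with an unpaired ", segment,
                       " hemisegment: ",
                       paste(utils::head(unpaired, 5), collapse = ", "), "."))
    wide <- wide[wide$n_rows == 2L, , drop = FALSE]
  }
  if (nrow(wide) == 0) {
    rlang::abort("No complete (bilateral) segments to summarise.")
  }
  tibble::tibble(
    genotype = genotype,
    segment = segment,
    lineage = lineage,
    n_segments = nrow(wide),
    mean = mean(wide$segment_count),
    sd = stats::sd(wide$segment_count)
  )
}

#' Anterior-aorta cardial-cell count summary
#'
#' Summarises, per row (left or right), the number of CCs immediately
#' anterior to the first Svp CC of the A2 hemisegment -- the anterior aorta
#' CCs, 12 per row in wild type. These counts attach to A2 records (one
#' value per row per embryo).
#'
#' @param table Hemisegment table with `anterior_cc_count` populated on A2
#'   records.
#' @param genotype Genotype label.
#' @param row `"left"` or `"right"`.
#' @return One-row tibble: `genotype`, `row`, `n`, `mean`, `sd`.
#' @export
anterior_cc_summary <- function(table, genotype, row = c("left", "right")) {
  row <- rlang::arg_match(row)
  table <- validate_hemisegment_table(table)
  sub <- table[table$genotype == genotype & table$row == row &
                 table$segment == "A2" & !is.na(table$anterior_cc_count), ,
               drop = FALSE]
  if (nrow(sub) == 0) {
    rlang::abort(paste0("No anterior CC counts for genotype `", genotype,
                        "`, row `", row, "`."))
  }
  tibble::tibble(
    genotype = genotype,
    row = row,
    n = nrow(sub),
    mean = mean(sub$anterior_cc_count),
    sd = stats::sd(sub$anterior_cc_count)
  )
}
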