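#' @keywords internal
hemisegment_columns <- function() {
  c("genotype", "embryo_id", "row", "segment", "svp_count", "tin_count",
    "anterior_cc_count")
}

lumen_positions <- function() c("A2", "A3", "A4", "A6", "A7")

#' @keywords internal
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

normalize_row_labels <- function(row) {
  out <- tolower(trimws(as.character(row)))
  out[out %in% c("l")] <- "left"
  out[out %in% c("r")] <- "right"
  out
}

normalize_segment_labels <- function(segment) {
  toupper(trimws(as.character(segment)))
}

#' Validate a hemisegment count table
#'
#' Checks the schema used for per-hemisegment Svp/Tin cardial-cell counts:
#' required columns, segment labels drawn from the blueprint, row labels in
#' left/right, non-negative integer counts, and uniqueness of the
#' (genotype, embryo_id, row, segment) key. Missing hemisegments are simply
#' absent rows; `anterior_cc_count` is optional and only meaningful on A2
#' records.
#'
#' @param table A data frame of hemisegment records.
#' @param blueprint A [reference_blueprint()].
#' @return The validated table as a tibble (normalized labels), invisibly
#'   usable downstream. Errors name offending rows.
#' @export
validate_hemisegment_table <- function(table, blueprint = reference_blueprint()) {
  table <- tibble::as_tibble(table)
  required <- c("genotype", "embryo_id", "row", "segment", "svp_count", "tin_count")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"anterior_cc_count" %in% names(table)) {
    table$anterior_cc_count <- NA_integer_
  }
  table <- table[, hemisegment_columns()]
  table$genotype <- as.character(table$genotype)
  table$embryo_id <- as.character(table$embryo_id)
  table$row <- normalize_row_labels(table$row)
  table$segment <- normalize_segment_labels(table$segment)

  bad_row <- which(!table$row %in% blueprint$rows)
  if (length(bad_row)) {
    rlang::abort(paste0("Unknown row label(s) at row(s) ",
                        paste(utils::head(bad_row, 5), collapse = ", "),
                        ": expected left/right."))
  }
  bad_seg <- which(!table$segment %in% blueprint$segments)
  if (length(bad_seg)) {
    rlang::abort(paste0(
      "Unknown segment label(s) at row(s) ",
      paste(utils::head(bad_seg, 5), collapse = ", "), ": ",
      paste(unique(table$segment[bad_seg]), collapse = ", "),
      " (expected ", paste(blueprint$segments, collapse = ", "), ")."))
  }
  for (col in c("svp_count", "tin_count")) {
    v <- suppressWarnings(as.numeric(table[[col]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      rlang::abort(paste0("Column `", col, "` must hold non-negative integers; ",
                          "offending row(s): ",
                          paste(utils::head(bad, 5), collapse = ", "), "."))
    }
    table[[col]] <- as.integer(v)
  }
  a <- suppressWarnings(as.numeric(table$anterior_cc_count))
  bad <- which(!is.na(a) & (a < 0 | a != round(a)))
  if (length(bad)) {
    rlang::abort(paste0("`anterior_cc_count` must be a non-negative integer or NA; ",
                        "offending row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  table$anterior_cc_count <- as.integer(a)

  key <- paste(table$genotype, table$embryo_id, table$row, table$segment, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    first <- dup[1]
    rlang::abort(paste0(
      "Duplicate hemisegment key at row ", first, ": (",
      table$genotype[first], ", ", table$embryo_id[first], ", ",
      table$row[first], ", ", table$segment[first], ")."))
  }
  table
}

#' Read a per-hemisegment cardial-cell count table
#'
#' Reads a UTF-8 delimited text file (comma or tab, auto-detected from the
#' header line) with columns `genotype`, `embryo_id`, `row`, `segment`,
#' `svp_count`, `tin_count` and optionally `anterior_cc_count`, then
#' validates it with [validate_hemisegment_table()].
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter; `NULL` (default) auto-detects from the header.
#' @param blueprint A [reference_blueprint()] used for validation.
#' @return A validated tibble of hemisegment records with a `provenance`
#'   attribute recording the source path.
#' @export
read_hemisegment_table <- function(path, delim = NULL,
                                   blueprint = reference_blueprint()) {
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  out <- validate_hemisegment_table(raw, blueprint)
  attr(out, "provenance") <- normalizePath(path)
  out
}

#' Write a hemisegment count table
#'
#' Round-trips through [read_hemisegment_table()] to an equal table.
#'
#' @param table Validated hemisegment table.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @export
write_hemisegment_table <- function(table, path, delim = ",") {
  table <- validate_hemisegment_table(table)
  readr::write_delim(table, path, delim = delim, na = "")
  invisible(path)
}

#' Convert a deltas table to absolute counts
#'
#' Supplementary tabulations in this field often record the *change* (if any)
#' in Svp and Tin CC numbers per hemisegment rather than absolute counts.
#' This converter turns signed deltas (`svp_delta`, `tin_delta`, 0 = no
#' change) into absolute counts against the blueprint expectation:
#' `count = expected + delta`.
#'
#' @param table Data frame with `genotype`, `embryo_id`, `row`, `segment`,
#'   `svp_delta`, `tin_delta` and optionally `anterior_cc_count`.
#' @param blueprint A [reference_blueprint()].
#' @return A validated absolute-count hemisegment tibble.
#' @export
deltas_to_counts <- function(table, blueprint = reference_blueprint()) {
  table <- tibble::as_tibble(table)
  required <- c("genotype", "embryo_id", "row", "segment", "svp_delta", "tin_delta")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  seg <- normalize_segment_labels(table$segment)
  bad <- which(!seg %in% blueprint$segments)
  if (length(bad)) {
    rlang::abort(paste0("Unknown segment label(s) at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  table$svp_count <- unname(blueprint$expected_svp[seg]) + table$svp_delta
  table$tin_count <- unname(blueprint$expected_tin[seg]) + table$tin_delta
  table$svp_delta <- NULL
  table$tin_delta <- NULL
  validate_hemisegment_table(table, blueprint)
}

#' Validate a lumen diameter table
#'
#' Internal lumen diameters (um) are measured at five positions along the
#' dorsal vessel: A2, A3, A4 (posterior aorta) and A6, A7 (heart proper).
#' Multiple diameters per (embryo, position) -- e.g. from several Z planes --
#' are averaged per position by downstream summaries; duplicates are
#' rejected here so that a table row is one measurement.
#'
#' @param table Data frame with `genotype`, `embryo_id`, `position`,
#'   `diameter`.
#' @return Validated tibble.
#' @export
validate_lumen_table <- function(table) {
  table <- tibble::as_tibble(table)
  required <- c("genotype", "embryo_id", "position", "diameter")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  table <- table[, required]
  table$genotype <- as.character(table$genotype)
  table$embryo_id <- as.character(table$embryo_id)
  table$position <- normalize_segment_labels(table$position)
  bad <- which(!table$position %in% lumen_positions())
  if (length(bad)) {
    rlang::abort(paste0(
      "Unknown lumen position at row(s) ",
      paste(utils::head(bad, 5), collapse = ", "), ": ",
      paste(unique(table$position[bad]), collapse = ", "),
      " (measured positions are ", paste(lumen_positions(), collapse = ", "), ")."))
  }
  bad <- which(is.na(table$diameter) | table$diameter <= 0)
  if (length(bad)) {
    rlang::abort(paste0("Diameters must be positive; offending row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  key <- paste(table$genotype, table$embryo_id, table$position, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    first <- dup[1]
    rlang::abort(paste0("Duplicate lumen measurement at row ", first, ": (",
                        table$embryo_id[first], ", ", table$position[first], ")."))
  }
  table
}

#' Read a lumen diameter table
#'
#' @inheritParams read_hemisegment_table
#' @return Validated tibble of lumen measurements (um).
#' @export
read_lumen_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  out <- validate_lumen_table(raw)
  attr(out, "provenance") <- normalizePath(path)
  out
}

#' Write a lumen diameter table
#'
#' @param table Validated lumen table.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @export
write_lumen_table <- function(table, path, delim = ",") {
  table <- validate_lumen_table(table)
  readr::write_delim(table, path, delim = delim, na = "")
  invisible(path)
}
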