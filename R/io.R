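condition_vocabulary <- c("light", "dark", "darkW", "lightW")

validate_organ_table <- function(df) {
  assert_columns(df, c("genotype_id", "ecotype_ref", "plate_id", "replicate_id",
                       "condition", "hypocotyl_length_mm", "root_length_mm"),
                 "organ table")
  bad_cond <- which(!df$condition %in% condition_vocabulary)
  if (length(bad_cond)) {
    stop_input("unknown condition '%s' in row %d (expected one of %s)",
               df$condition[bad_cond[1]], bad_cond[1],
               paste(condition_vocabulary, collapse = ", "))
  }
  for (col in intersect(c("hypocotyl_length_mm", "root_length_mm",
                          "hypocotyl_width_mm"), names(df))) {
    vals <- df[[col]]
    bad <- which(!is.na(vals) & (!is.finite(vals) | vals <= 0))
    if (length(bad)) {
      stop_input("non-positive or non-finite %s in row %d (value %s)",
                 col, bad[1], format(vals[bad[1]]))
    }
    if (col != "hypocotyl_width_mm" && anyNA(vals)) {
      stop_input("missing %s in row %d", col, which(is.na(vals))[1])
    }
  }
  as_tibble(df)
}

validate_cellfile_table <- function(df) {
  assert_columns(df, c("root_id", "condition", "genotype_id", "cell_index",
                       "length_um", "width_um"),
                 "cell-file table")
  if (anyNA(df$cell_index) || any(df$cell_index != round(df$cell_index)) ||
      any(df$cell_index < 1)) {
    bad <- which(is.na(df$cell_index) | df$cell_index != round(df$cell_index) |
                   df$cell_index < 1)[1]
    stop_input("cell_index must be a 1-based integer (row %d)", bad)
  }
  key <- paste(df$root_id, df$cell_index)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_input("duplicated cell index %d for root '%s' (row %d)",
               df$cell_index[dup[1]], df$root_id[dup[1]], dup[1])
  }
  for (root in unique(df$root_id)) {
    if (min(df$cell_index[df$root_id == root]) != 1L) {
      stop_input("cell indexing for root '%s' must start at 1", root)
    }
  }
  for (col in c("length_um", "width_um")) {
    bad <- which(is.na(df[[col]]) | !is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop_input("non-positive or missing %s in row %d", col, bad[1])
    }
  }
  as_tibble(df)
}

validate_mitotic_table <- function(df) {
  assert_columns(df, c("root_id", "condition", "count"), "mitotic table")
  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad)) {
    stop_input("count must be a non-negative integer (row %d)", bad[1])
  }
  as_tibble(df)
}

#' Read and validate a measurement table
#'
#' Reads a UTF-8 CSV and validates it against one of the pipeline's three
#' schemas: `"organ"` (per-seedling organ measurements), `"cellfile"`
#' (per-cell root-file measurements, 1-based `cell_index` from the
#' quiescent centre, duplicate indices rejected) or `"mitotic"` (marker
#' counts per root tip). Errors name the offending column and row.
#'
#' @param path CSV file path.
#' @param schema One of `"organ"`, `"cellfile"`, `"mitotic"`.
#' @return Validated tibble.
#' @export
read_measurements <- function(path, schema = c("organ", "cellfile", "mitotic")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  switch(schema,
         organ = validate_organ_table(df),
         cellfile = validate_cellfile_table(df),
         mitotic = validate_mitotic_table(df))
}

#' Read an externally shaped table through a column mapping
#'
#' Ingests tables whose column names differ from the pipeline's schemas —
#' e.g. sheets exported from a supplementary workbook — by applying a
#' user-supplied mapping from canonical to source column names, then
#' validating against the chosen schema. Reads CSV/TSV directly and `.xlsx`
#' through the readxl package when installed.
#'
#' @param path Table path (`.csv`, `.tsv` or `.xlsx`).
#' @param mapping Named character vector: names are the canonical schema
#'   columns, values the source columns (e.g.
#'   `c(hypocotyl_length_mm = "Hypocotyl (mm)")`). Unmapped canonical
#'   columns must already be present under their own names.
#' @param schema One of `"organ"`, `"cellfile"`, `"mitotic"`.
#' @param sheet Sheet name or index for workbook input.
#' @return Validated tibble in canonical form.
#' @export
read_mapped_table <- function(path, mapping,
                              schema = c("organ", "cellfile", "mitotic"),
                              sheet = 1L) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (length(mapping) && (is.null(names(mapping)) || any(!nzchar(names(mapping))))) {
    stop_input("`mapping` must be a named character vector (canonical = source)")
  }
  ext <- tolower(tools::file_ext(path))
  df <- switch(
    ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          check.names = FALSE),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                            check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop_input("reading .xlsx requires the readxl package")
      }
      as.data.frame(readxl::read_excel(path, sheet = sheet))
    },
    stop_input("unsupported table format '.%s'", ext)
  )
  for (canonical in names(mapping)) {
    src <- mapping[[canonical]]
    if (!src %in% names(df)) {
      stop_input("mapped source column '%s' (for %s) not found", src, canonical)
    }
    df[[canonical]] <- df[[src]]
  }
  df <- df[, !duplicated(names(df)), drop = FALSE]
  switch(schema,
         organ = validate_organ_table(df),
         cellfile = validate_cellfile_table(df),
         mitotic = validate_mitotic_table(df))
}
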