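#' Construct and validate a cohort table
#'
#' A cohort table is a long-format data frame with one row per scan:
#' identifier columns `subject_id`, `visit_index` (0 = baseline),
#' `time_from_baseline` (years), `group` (`"control"` or `"patient"`),
#' and one numeric column per region. Region column order is preserved.
#'
#' @param df data frame with the columns above
#' @param regions character vector naming the region columns; defaults to
#'   every column that is not an identifier column
#' @return validated data frame of class `cohort_table` with a `regions`
#'   attribute
#' @export
cohort_table <- function(df, regions = NULL) {
  id_cols <- c("subject_id", "visit_index", "time_from_baseline", "group")
  missing_cols <- setdiff(id_cols, names(df))
  if (length(missing_cols))
    stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  regions <- regions %||% setdiff(names(df), id_cols)
  if (length(regions) < 1L) stopf("no region columns found")
  df <- as.data.frame(df)[, c(id_cols, regions)]
  df$subject_id <- as.character(df$subject_id)
  df$visit_index <- as.integer(df$visit_index)
  df$time_from_baseline <- as.numeric(df$time_from_baseline)
  df$group <- as.character(df$group)

  bad_group <- which(!df$group %in% c("control", "patient"))
  if (length(bad_group))
    stopf("row %d: unknown group label '%s'", bad_group[1], df$group[bad_group[1]])
  if (any(df$visit_index < 0L, na.rm = TRUE)) stopf("visit_index must be >= 0")
  key <- paste(df$subject_id, df$visit_index)
  if (anyDuplicated(key))
    stopf("duplicate (subject_id, visit_index): %s",
          key[anyDuplicated(key)[1] > 0][duplicated(key)][1])
  bad_t0 <- which(df$visit_index == 0L & df$time_from_baseline != 0)
  if (length(bad_t0))
    stopf("row %d: baseline visit must have time_from_baseline = 0", bad_t0[1])
  if (any(df$time_from_baseline < 0, na.rm = TRUE))
    stopf("time_from_baseline must be >= 0")
  for (r in regions) {
    v <- df[[r]]
    if (!is.numeric(v)) stopf("region column '%s' is not numeric", r)
    if (anyNA(v))
      stopf("missing value in region '%s', row %d (subject %s)",
            r, which(is.na(v))[1], df$subject_id[which(is.na(v))[1]])
    df[[r]] <- as.numeric(v)
  }
  structure(df, regions = regions, class = c("cohort_table", "data.frame"))
}

#' Read a cohort table from CSV
#'
#' @param path CSV file with header columns `subject_id`, `visit_index`,
#'   `time_from_baseline`, `group`, plus one column per region.
#' @return a [cohort_table()]; region order follows the header.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_cols <- c("subject_id", "visit_index", "time_from_baseline", "group")
  regions <- setdiff(names(df), id_cols)
  for (r in regions) {
    v <- df[[r]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stopf("%s: non-numeric value '%s' in column '%s', row %d",
              basename(path), v[bad[1]], r, bad[1])
      df[[r]] <- vn
    }
  }
  cohort_table(df, regions)
}

#' Write a cohort table to CSV
#' @param table a `cohort_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Region names of a cohort table
#' @param table a `cohort_table`
#' @return character vector
#' @export
cohort_regions <- function(table) attr(table, "regions")

# Extract the scan x region value matrix (rows named subject|visit).
cohort_values <- function(table, regions = cohort_regions(table)) {
  m <- as.matrix(as.data.frame(table)[, regions, drop = FALSE])
  rownames(m) <- paste(table$subject_id, table$visit_index, sep = "|")
  m
}

baseline_rows <- function(table) table$visit_index == 0L
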