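#' Construct a cohort table
#'
#' A cohort table is the package's central container: a patient-by-indicator
#' numeric matrix with an explicit missingness mask and a variable registry.
#' Missing cells hold `NA` in `values` and `TRUE` in `missing_mask`; sentinel
#' numeric codes are never used.
#'
#' @param values Numeric matrix (n patients x p indicators). `NA` entries are
#'   taken as missing.
#' @param registry Registry data.frame restricted to the columns present;
#'   column order of `values` must match `registry$name`.
#' @param ids Optional record identifiers (default `"p1"..."pn"`).
#' @param missing_mask Optional logical matrix; defaults to `is.na(values)`.
#' @return An object of class `hd_cohort` with fields `ids`, `registry`,
#'   `values`, `missing_mask`.
#' @export
cohort_table <- function(values, registry, ids = NULL, missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != nrow(registry))
    stop("values has ", ncol(values), " columns but registry lists ",
         nrow(registry), " variables")
  colnames(values) <- registry$name
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  stopifnot(identical(dim(missing_mask), dim(values)))
  values[missing_mask] <- NA_real_
  if (is.null(ids)) ids <- if (nrow(values) > 0) paste0("p", seq_len(nrow(values))) else character(0)
  stopifnot(length(ids) == nrow(values))
  structure(
    list(ids = as.character(ids), registry = registry,
         values = values, missing_mask = missing_mask),
    class = "hd_cohort"
  )
}

#' @export
print.hd_cohort <- function(x, ...) {
  cat("<hd_cohort> ", nrow(x$values), " records x ", ncol(x$values),
      " indicators; ", sum(x$missing_mask), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.hd_cohort <- function(x) dim(x$values)

#' Subset rows of a cohort table
#' @param table An `hd_cohort`.
#' @param i Row index vector.
#' @return The subsetted `hd_cohort`.
#' @export
cohort_subset <- function(table, i) {
  cohort_table(table$values[i, , drop = FALSE], table$registry,
               ids = table$ids[i],
               missing_mask = table$missing_mask[i, , drop = FALSE])
}

#' Read a cohort table from CSV
#'
#' Expects an RFC-4180 UTF-8 CSV with a header row whose names resolve
#' (case-insensitively) to registry variable names, plus an optional leading
#' `id` column. Blank cells and the literal `NA` are treated as missing;
#' every other cell must parse as a decimal number.
#'
#' @param path CSV file path.
#' @param registry Variable registry; defaults to the rows of
#'   [default_registry()] matching the file header.
#' @return An `hd_cohort`.
#' @export
read_cohort <- function(path, registry = default_registry()) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8", strip.white = TRUE)
  nms <- names(raw)
  lower <- tolower(nms)
  id_col <- which(lower == "id")
  ids <- if (length(id_col) == 1) raw[[id_col]] else NULL
  data_cols <- setdiff(seq_along(nms), id_col)
  if (anyDuplicated(lower[data_cols]))
    stop("duplicate columns in ", path, ": ",
         paste(unique(nms[data_cols][duplicated(lower[data_cols])]), collapse = ", "))
  match_idx <- match(lower[data_cols], tolower(registry$name))
  if (anyNA(match_idx))
    stop("unknown columns in ", path, ": ",
         paste(nms[data_cols][is.na(match_idx)], collapse = ", "))
  reg <- registry[match_idx, , drop = FALSE]
  rownames(reg) <- NULL
  n <- nrow(raw)
  vals <- matrix(NA_real_, n, length(data_cols),
                 dimnames = list(NULL, reg$name))
  for (j in seq_along(data_cols)) {
    cell <- raw[[data_cols[j]]]
    blank <- is.na(cell) | cell == "" | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !blank & is.na(num)
    if (any(bad))
      stop("non-numeric value ", dQuote(cell[which(bad)[1]]), " at row ",
           which(bad)[1], ", column ", reg$name[j])
    num[blank] <- NA_real_
    vals[, j] <- num
  }
  cohort_table(vals, reg, ids = ids)
}

#' Write a cohort table to CSV
#'
#' Missing cells are written as blank fields so that
#' `read_cohort(write_cohort(t))` round-trips values, mask and ids exactly.
#'
#' @param table An `hd_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  df <- as.data.frame(table$values)
  df <- cbind(id = table$ids, df)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a cohort table
#'
#' Reporting-only checks: per-column missing fractions, rows whose missing
#' fraction exceeds `row_missing_threshold` (the "excessive missing data"
#' exclusion criterion), and negative values in variables declared
#' non-negative in the registry.
#'
#' @param table An `hd_cohort`.
#' @param row_missing_threshold Fraction above which a row is flagged
#'   (default 0.30).
#' @return A list with `overall_missing_fraction`, `column_missing`
#'   (named vector), `flagged_rows` (indices), and `negative_violations`
#'   (data.frame row/column).
#' @export
validate_cohort <- function(table, row_missing_threshold = 0.30) {
  m <- table$missing_mask
  n_cells <- length(m)
  col_miss <- colMeans(m)
  row_miss <- rowMeans(m)
  neg <- which(!is.na(table$values) & table$values < 0 &
                 rep(table$registry$nonneg, each = nrow(table$values)),
               arr.ind = TRUE)
  list(
    overall_missing_fraction = if (n_cells > 0) sum(m) / n_cells else 0,
    column_missing = col_miss,
    flagged_rows = which(row_miss > row_missing_threshold),
    negative_violations = data.frame(
      row = if (length(neg)) neg[, 1] else integer(0),
      column = if (length(neg)) colnames(table$values)[neg[, 2]] else character(0)
    )
  )
}
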