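#' Clinical table: feature matrix with missingness mask and labels
#'
#' The central data container: an `n_rows x n_features` numeric matrix
#' (boolean features coded 0/1), a logical missingness mask of the same
#' shape (`TRUE` = missing), a label per row, and the [feature_schema()]
#' describing the columns. Missing cells carry `NA` in `values` and `TRUE`
#' in `missing_mask`; every observed boolean cell must be 0 or 1.
#'
#' @param values Numeric matrix, rows = patients, columns = features in
#'   schema order. Cells may be `NA` where missing.
#' @param labels Vector of class labels (character or factor); every label
#'   must appear in `schema$class_labels`.
#' @param schema A [feature_schema()].
#' @param missing_mask Logical matrix matching `values`; defaults to
#'   `is.na(values)`.
#'
#' @return An object of class `clinical_table`.
#' @seealso [read_clinical_csv()], [filter_rows_by_missingness()],
#'   [stratified_split()], [impute_table()]
#' @export
clinical_table <- function(values, labels, schema, missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!is.logical(missing_mask)) {
    stop_negdrop("missing_mask must be logical", class = "negdrop_validation_error")
  }
  if (!identical(dim(values), dim(missing_mask))) {
    stop_negdrop("values and missing_mask must have identical dimensions",
                 class = "negdrop_validation_error")
  }
  if (ncol(values) != n_features(schema)) {
    stop_negdrop("values has ", ncol(values), " columns but schema describes ",
                 n_features(schema), " features",
                 class = "negdrop_validation_error")
  }
  if (length(labels) != nrow(values)) {
    stop_negdrop("labels length must equal number of rows",
                 class = "negdrop_validation_error")
  }
  labels <- as.character(labels)
  bad_lab <- setdiff(unique(labels), schema$class_labels)
  if (length(bad_lab)) {
    stop_negdrop("labels not in schema class_labels: ",
                 paste(bad_lab, collapse = ", "),
                 class = "negdrop_validation_error")
  }
  values[missing_mask] <- NA_real_
  if (any(is.na(values) & !missing_mask)) {
    stop_negdrop("NA values present in cells not flagged missing",
                 class = "negdrop_validation_error")
  }
  colnames(values) <- schema$feature_names
  colnames(missing_mask) <- schema$feature_names
  bi <- boolean_idx(schema)
  if (length(bi)) {
    bv <- values[, bi, drop = FALSE]
    obs <- !missing_mask[, bi, drop = FALSE]
    bad <- obs & !is.na(bv) & !(bv == 0 | bv == 1)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop_negdrop("non-binary value in boolean column '",
                   schema$feature_names[bi[w["col"]]], "' at data row ",
                   w["row"], class = "negdrop_validation_error")
    }
  }
  structure(
    list(values = values, missing_mask = missing_mask,
         labels = labels, schema = schema),
    class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat("<clinical_table> ", nrow(x$values), " rows x ", ncol(x$values),
      " features; ", sum(x$missing_mask), " missing cells; ",
      length(unique(x$labels)), " observed classes\n", sep = "")
  invisible(x)
}

#' @export
dim.clinical_table <- function(x) dim(x$values)

#' Subset rows of a clinical table
#' @param x A `clinical_table`.
#' @param i Row indices (integer or logical).
#' @param ... Ignored.
#' @export
`[.clinical_table` <- function(x, i, ...) {
  clinical_table(x$values[i, , drop = FALSE], x$labels[i], x$schema,
                 x$missing_mask[i, , drop = FALSE])
}

#' Integer-coded labels (1-based, in schema class order)
#' @param table A `clinical_table`.
#' @return Integer vector of class indices.
#' @export
class_index <- function(table) {
  match(table$labels, table$schema$class_labels)
}

#' Read a clinical table from CSV
#'
#' The file must have a header row containing every schema feature name plus
#' one label column; no other columns are allowed. Cells equal to one of
#' `missing_markers` (case-insensitive; empty string included by default)
#' are flagged missing. Boolean columns must otherwise contain only 0/1.
#' Error messages report 1-based file row numbers (header = row 1).
#'
#' @param path CSV file path.
#' @param schema A [feature_schema()].
#' @param label_col Name of the label column (default `"label"`).
#' @param missing_markers Character vector of cell values treated as
#'   missing; matched case-insensitively.
#' @return A [clinical_table()].
#' @export
read_clinical_csv <- function(path, schema, label_col = "label",
                              missing_markers = c("", "NA", "NaN")) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0))
  expected <- c(schema$feature_names, label_col)
  unknown <- setdiff(names(raw), expected)
  if (length(unknown)) {
    stop_negdrop("unknown column(s) in CSV: ", paste(unknown, collapse = ", "),
                 class = "negdrop_schema_error")
  }
  absent <- setdiff(expected, names(raw))
  if (length(absent)) {
    stop_negdrop("CSV is missing column(s): ", paste(absent, collapse = ", "),
                 class = "negdrop_schema_error")
  }
  markers <- tolower(missing_markers)
  n <- nrow(raw)
  p <- n_features(schema)
  values <- matrix(NA_real_, n, p, dimnames = list(NULL, schema$feature_names))
  mask <- matrix(FALSE, n, p, dimnames = list(NULL, schema$feature_names))
  for (j in seq_len(p)) {
    nm <- schema$feature_names[j]
    cells <- raw[[nm]]
    miss <- tolower(trimws(cells)) %in% markers
    mask[, j] <- miss
    num <- suppressWarnings(as.numeric(cells[!miss]))
    if (anyNA(num)) {
      bad_row <- which(!miss)[which(is.na(num))[1L]]
      stop_negdrop("non-numeric value '", cells[!miss][which(is.na(num))[1L]],
                   "' in column '", nm, "' at file row ", bad_row + 1L,
                   class = "negdrop_validation_error")
    }
    if (schema$feature_types[j] == "boolean" && any(!(num == 0 | num == 1))) {
      k <- which(!(num == 0 | num == 1))[1L]
      bad_row <- which(!miss)[k]
      stop_negdrop("non-binary value '", num[k], "' in boolean column '", nm,
                   "' at file row ", bad_row + 1L,
                   class = "negdrop_validation_error")
    }
    values[!miss, j] <- num
  }
  labs <- trimws(raw[[label_col]])
  clinical_table(values, labs, schema, mask)
}

#' Write a clinical table to CSV
#'
#' Missing cells are emitted as empty strings; column order follows the
#' schema with the label column last. `read_clinical_csv()` of the result
#' round-trips the table exactly.
#'
#' @param table A [clinical_table()].
#' @param path Output file path.
#' @param label_col Name for the label column.
#' @return Invisibly, `path`.
#' @export
write_clinical_csv <- function(table, path, label_col = "label") {
  df <- as.data.frame(table$values)
  df[[label_col]] <- table$labels
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Drop rows with too many missing cells
#'
#' Retains rows whose per-row count of missing cells is at most
#' `max_missing` (boundary inclusive), preserving row order. The default of
#' 3 reflects the convention of excluding records with more than three
#' missing values from analysis.
#'
#' @param table A [clinical_table()].
#' @param max_missing Non-negative integer threshold.
#' @return The filtered `clinical_table`.
#' @export
filter_rows_by_missingness <- function(table, max_missing = 3L) {
  if (!is_count(max_missing)) {
    stop_negdrop("max_missing must be a non-negative integer")
  }
  keep <- rowSums(table$missing_mask) <= max_missing
  table[keep]
}

#' Stratified train/test split
#'
#' Splits rows into train and test sets so that the total training size is
#' exactly `floor(train_fraction * n_rows)`, allocated across classes by
#' largest-remainder rounding of the per-class quotas. Membership within
#' each class is randomized by `seed`; the same seed reproduces the split
#' bit-exactly. For 683-, 768- and 1,920-row tables at fraction 0.7 this
#' yields 478/205, 537/231 and 1,344/576 train/test rows.
#'
#' @param table A [clinical_table()].
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#' @param seed Integer seed controlling within-class assignment.
#' @return A `data_split`: list with integer `train_indices` and
#'   `test_indices` (1-based row indices, disjoint, jointly exhaustive).
#' @export
stratified_split <- function(table, train_fraction = 0.7, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_negdrop("train_fraction must lie in (0, 1)")
  }
  y <- class_index(table)
  n <- length(y)
  classes <- sort(unique(y))
  counts <- vapply(classes, function(c) sum(y == c), integer(1))
  if (any(counts == 0L)) stop_negdrop("every class must have at least one row")
  total_train <- floor(train_fraction * n)
  quota <- train_fraction * counts
  base <- floor(quota)
  rem <- total_train - sum(base)
  frac <- quota - base
  # largest-remainder: hand the leftover seats to the classes with the
  # biggest fractional quotas; ties broken by class order (deterministic)
  extra <- integer(length(classes))
  if (rem > 0) {
    ord <- order(-frac, seq_along(classes))
    extra[ord[seq_len(rem)]] <- 1L
  }
  take <- base + extra
  train_idx <- integer(0)
  with_rng_seed(derive_seed(seed, "stratified_split"), {
    for (k in seq_along(classes)) {
      rows <- which(y == classes[k])
      pick <- if (length(rows) == 1L) {
        if (take[k] >= 1L) rows else integer(0)
      } else {
        sample(rows, take[k])
      }
      train_idx <- c(train_idx, pick)
    }
  })
  train_idx <- sort(train_idx)
  structure(list(train_indices = train_idx,
                 test_indices = setdiff(seq_len(n), train_idx)),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("<data_split> ", length(x$train_indices), " train / ",
      length(x$test_indices), " test rows\n", sep = "")
  invisible(x)
}
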