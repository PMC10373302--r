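#' Feature schema for a clinical table
#'
#' Describes the columns of a tabular clinical dataset: which features are
#' boolean symptom indicators (coded 0/1), which are continuous measurements
#' (e.g. age, course of treatment), the valid range of each continuous
#' feature, and the ordered set of diagnostic class labels.
#'
#' @param feature_names Character vector of unique feature (column) names.
#' @param feature_types Character vector, one of `"boolean"` or
#'   `"continuous"` per feature.
#' @param class_labels Character vector of at least two class labels, in a
#'   fixed order that defines the integer coding used internally.
#' @param continuous_ranges Named list mapping each continuous feature name
#'   to a `c(min, max)` pair in feature units. Features omitted here get an
#'   unbounded range; bounded ranges are required only by operations that
#'   sample values (random negative generation).
#'
#' @return An object of class `feature_schema`.
#' @examples
#' sch <- feature_schema(
#'   feature_names = c("dizziness", "thirst", "age"),
#'   feature_types = c("boolean", "boolean", "continuous"),
#'   class_labels = c("syndrome_a", "syndrome_b"),
#'   continuous_ranges = list(age = c(18, 95))
#' )
#' @export
feature_schema <- function(feature_names, feature_types, class_labels,
                           continuous_ranges = NULL) {
  feature_names <- as.character(feature_names)
  feature_types <- as.character(feature_types)
  class_labels <- as.character(class_labels)
  if (anyDuplicated(feature_names)) {
    stop_negdrop("feature_names must be unique", class = "negdrop_schema_error")
  }
  if (length(feature_types) != length(feature_names)) {
    stop_negdrop("feature_types must have one entry per feature name",
                 class = "negdrop_schema_error")
  }
  if (!all(feature_types %in% c("boolean", "continuous"))) {
    stop_negdrop("feature_types must be 'boolean' or 'continuous'",
                 class = "negdrop_schema_error")
  }
  if (length(unique(class_labels)) < 2L) {
    stop_negdrop("class_labels needs at least 2 distinct entries",
                 class = "negdrop_schema_error")
  }
  cont <- feature_names[feature_types == "continuous"]
  ranges <- stats::setNames(
    rep(list(c(-Inf, Inf)), length(cont)), cont)
  if (!is.null(continuous_ranges)) {
    bad <- setdiff(names(continuous_ranges), cont)
    if (length(bad)) {
      stop_negdrop("continuous_ranges given for non-continuous feature(s): ",
                   paste(bad, collapse = ", "), class = "negdrop_schema_error")
    }
    for (nm in names(continuous_ranges)) {
      r <- as.numeric(continuous_ranges[[nm]])
      if (length(r) != 2L || r[1] > r[2]) {
        stop_negdrop("range for '", nm, "' must be c(min, max) with min <= max",
                     class = "negdrop_schema_error")
      }
      ranges[[nm]] <- r
    }
  }
  structure(
    list(feature_names = feature_names,
         feature_types = feature_types,
         continuous_ranges = ranges,
         class_labels = class_labels),
    class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  nb <- sum(x$feature_types == "boolean")
  nc <- sum(x$feature_types == "continuous")
  cat("<feature_schema> ", length(x$feature_names), " features (",
      nb, " boolean, ", nc, " continuous), ",
      length(x$class_labels), " classes\n", sep = "")
  invisible(x)
}

n_features <- function(schema) length(schema$feature_names)
n_classes_of <- function(schema) length(schema$class_labels)
boolean_idx <- function(schema) which(schema$feature_types == "boolean")
continuous_idx <- function(schema) which(schema$feature_types == "continuous")
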