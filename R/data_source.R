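#' Construct a data source matrix
#'
#' A data source is one named block of the multi-view dataset: a non-negative
#' samples-by-features matrix together with one text label per feature column.
#' Rows index genomic positions (samples) and must agree across all sources of
#' one dataset; columns index source-specific features such as positional
#' k-mers, region-type channels or co-binding indicators.
#'
#' Positional feature labels use the form `"<feature>@<offset>"` (for example
#' `"UGUA@-3"`, `"exon@0"`); non-positional features (such as annotation
#' terms) use the bare feature name.  [parse_feature_labels()] inverts the
#' mapping.
#'
#' @param values Numeric matrix with non-negative, finite entries.
#' @param name Single character label for the source (e.g. `"KMER"`).
#' @param feature_labels Character vector of column labels; defaults to
#'   `colnames(values)`.
#' @return An object of class `"data_source"`: a list with elements `name`,
#'   `values` and `feature_labels`.  `values` carries the labels as column
#'   names.
#' @examples
#' x <- data_source(matrix(runif(20), 5, 4), "RNA",
#'                  paste0("pairprob@", -2:1))
#' x
#' @export
data_source <- function(values, name, feature_labels = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("data source '%s': 'values' must be a numeric matrix", name)
  if (anyNA(values) || any(!is.finite(values)))
    stop_input("data source '%s': entries must be finite", name)
  if (any(values < 0))
    stop_input("data source '%s': entries must be non-negative", name)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_input("'name' must be a single non-empty string")
  if (is.null(feature_labels))
    feature_labels <- paste0("f", seq_len(ncol(values)))
  if (length(feature_labels) != ncol(values))
    stop_input("data source '%s': %d feature labels for %d columns",
               name, length(feature_labels), ncol(values))
  colnames(values) <- feature_labels
  structure(list(name = name, values = values,
                 feature_labels = as.character(feature_labels)),
            class = "data_source")
}

#' @export
print.data_source <- function(x, ...) {
  cat(sprintf("<data_source '%s'> %d samples x %d features\n",
              x$name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.data_source <- function(x) dim(x$values)

# Coerce a list of matrices / data_source objects into a named list of
# data_source with a common row count.
as_data_sources <- function(sources) {
  if (inherits(sources, "data_source")) sources <- list(sources)
  if (!is.list(sources) || length(sources) == 0L)
    stop_input("'sources' must be a non-empty list of data sources")
  nms <- names(sources)
  out <- vector("list", length(sources))
  for (i in seq_along(sources)) {
    s <- sources[[i]]
    if (inherits(s, "data_source")) {
      out[[i]] <- s
    } else {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else paste0("X", i)
      out[[i]] <- data_source(as.matrix(s), nm)
    }
  }
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out)))
    stop_input("source names must be unique (got: %s)",
               paste(names(out), collapse = ", "))
  m <- vapply(out, function(s) nrow(s$values), 0L)
  if (length(unique(m)) != 1L)
    stop_input("all sources must have the same number of rows (got %s)",
               paste(sprintf("%s=%d", names(out), m), collapse = ", "))
  out
}

#' Split positional feature labels into feature and offset
#'
#' Inverts the `"<feature>@<offset>"` labelling convention used by the
#' encoders.  Labels without an `"@"` (e.g. annotation terms) get offset `NA`.
#'
#' @param labels Character vector of feature labels.
#' @return A data frame with columns `label`, `feature` and `offset`.
#' @examples
#' parse_feature_labels(c("UGUA@-3", "exon@0", "GO:0003729"))
#' @export
parse_feature_labels <- function(labels) {
  labels <- as.character(labels)
  has_at <- grepl("@", labels, fixed = TRUE)
  feature <- labels
  offset <- rep(NA_integer_, length(labels))
  if (any(has_at)) {
    feature[has_at] <- sub("@[^@]*$", "", labels[has_at])
    offset[has_at] <- as.integer(sub("^.*@", "", labels[has_at]))
  }
  data.frame(label = labels, feature = feature, offset = offset,
             stringsAsFactors = FALSE)
}

make_positional_labels <- function(feature, offsets) {
  as.vector(t(outer(feature, offsets, function(f, o) paste0(f, "@", o))))
}
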