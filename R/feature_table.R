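#' Lipid feature table
#'
#' A lightweight container for a lipid x sample intensity matrix together
#' with a view tag recording which transformation the values are in:
#' \code{"raw"} (arbitrary intensity units, >= 0), \code{"relative"}
#' (per-sample proportions of total annotated intensity, columns sum to 1)
#' or \code{"clr"} (centered log-ratio values, columns sum to 0).
#'
#' Rows are lipid features, columns are samples. Row and column names are
#' mandatory and act as the feature/sample identifiers throughout the
#' package.
#'
#' @param x numeric matrix (lipids x samples) with dimnames.
#' @param view one of \code{"raw"}, \code{"relative"}, \code{"clr"}.
#' @return An object of class \code{feature_table} (a matrix with a
#'   \code{view} attribute).
#' @export
feature_table <- function(x, view = c("raw", "relative", "clr")) {
  view <- match.arg(view)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("feature table must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("feature table requires row (lipid) and column (sample) names")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("feature table row/column names must be unique")
  }
  if (view %in% c("raw", "relative") && any(x < 0, na.rm = TRUE)) {
    stop("raw and relative views must be non-negative")
  }
  structure(x, view = view, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table [%s]> %d lipids x %d samples\n",
              ft_view(x), nrow(x), ncol(x)))
  invisible(x)
}

#' View tag of a feature table
#' @param x a \code{feature_table}.
#' @return character scalar: \code{"raw"}, \code{"relative"} or \code{"clr"}.
#' @export
ft_view <- function(x) {
  v <- attr(x, "view")
  if (is.null(v)) "raw" else v
}

# internal: coerce plain matrices, keep attributes through subsetting helpers
as_ft_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "view") <- NULL
  y
}

stopifnot_view <- function(x, view) {
  if (!identical(ft_view(x), view)) {
    stop(sprintf("expected a '%s' view feature table, got '%s'",
                 view, ft_view(x)))
  }
  invisible(TRUE)
}

#' Write / read a feature table as TSV
#'
#' Plain tab-separated text with lipid ids in the first column
#' (\code{lipid_id}) and one column per sample.
#'
#' @param x a \code{feature_table}.
#' @param path file path.
#' @return \code{read_feature_table} returns a \code{feature_table};
#'   \code{write_feature_table} returns \code{path} invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(lipid_id = rownames(x), as_ft_matrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param view view tag to stamp on the table read from disk.
#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, view = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  feature_table(m, view = view)
}
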