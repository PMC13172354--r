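#' Construct an expression matrix
#'
#' A light wrapper around a cells-by-genes numeric matrix (dense or sparse
#' [Matrix::dgCMatrix-class]) that records whether the values are raw UMI
#' counts or log-normalized expression, and enforces unique identifiers and
#' finite nonnegative values.
#'
#' @param values Numeric matrix (or sparse `Matrix`) with cells as rows and
#'   genes as columns. Row names are cell barcodes, column names gene ids;
#'   both must be present and unique.
#' @param layer One of `"raw_counts"` or `"log_normalized"`.
#'
#' @return An `expression_matrix`: the input matrix carrying a `layer`
#'   attribute and class.
#' @export
#'
#' @examples
#' m <- matrix(rpois(20, 5), 4, 5,
#'             dimnames = list(paste0("c", 1:4), paste0("g", 1:5)))
#' expression_matrix(m, layer = "raw_counts")
expression_matrix <- function(values, layer = c("log_normalized", "raw_counts")) {
  layer <- match.arg(layer)
  if (!(is.matrix(values) || inherits(values, "Matrix"))) {
    td_abort("`values` must be a matrix or a sparse Matrix", "trajdyn_input_error")
  }
  if (ncol(values) == 0L) {
    td_abort("expression matrix must have at least one gene",
             "trajdyn_input_error")
  }
  cn <- colnames(values); rn <- rownames(values)
  if ((nrow(values) > 0L && is.null(rn)) || is.null(cn)) {
    td_abort("expression matrix needs cell row names and gene column names",
             "trajdyn_input_error")
  }
  if (anyDuplicated(rn)) td_abort("duplicate cell ids", "trajdyn_input_error")
  if (anyDuplicated(cn)) td_abort("duplicate gene ids", "trajdyn_input_error")
  v <- if (inherits(values, "Matrix")) values@x else values
  if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
    td_abort("expression values must be finite and >= 0", "trajdyn_input_error")
  }
  structure(values, layer = layer,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes, layer = %s\n",
              nrow(x), ncol(x), expr_layer(x)))
  invisible(x)
}

#' Layer tag of an expression matrix
#' @param x An `expression_matrix`.
#' @return `"raw_counts"` or `"log_normalized"`.
#' @export
expr_layer <- function(x) attr(x, "layer") %||% "log_normalized"

`%||%` <- function(a, b) if (is.null(a)) b else a

cell_ids <- function(x) rownames(x)
gene_ids <- function(x) colnames(x)

# strip class/attr back to the underlying matrix for arithmetic
expr_values <- function(x) {
  cls <- class(x)
  class(x) <- setdiff(cls, "expression_matrix")
  attr(x, "layer") <- NULL
  x
}

assert_layer <- function(x, layer) {
  if (!inherits(x, "expression_matrix")) {
    td_abort("expected an `expression_matrix`", "trajdyn_input_error")
  }
  if (expr_layer(x) != layer) {
    td_abort(sprintf("expected layer '%s' but got '%s'", layer, expr_layer(x)),
             "trajdyn_input_error")
  }
  invisible(x)
}
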