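#' Quality-control thresholds for cell filtering
#'
#' Bundles the per-cell filtering rules: a detected-feature range and a
#' mitochondrial-fraction ceiling. Feature bounds are inclusive; the
#' mitochondrial bound is strict (a cell exactly at `max_mito_fraction`
#' fails). Two presets mirror the common use cases: `"invitro"` keeps cells
#' with 1000--8000 detected features and mitochondrial content below 7%;
#' `"invivo"` keeps cells with fewer than 7500 features and mitochondrial
#' content below 5%.
#'
#' @param min_features Minimum detected genes per cell (inclusive).
#' @param max_features Maximum detected genes per cell (inclusive); `Inf`
#'   for unbounded.
#' @param max_mito_fraction Strict upper bound on the mitochondrial read
#'   fraction, in \[0, 1\].
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#'
#' @return A `qc_thresholds` list.
#' @export
#'
#' @examples
#' qc_thresholds()
#' qc_preset("invivo")
qc_thresholds <- function(min_features = 1000, max_features = 8000,
                          max_mito_fraction = 0.07, mito_prefix = "MT-") {
  td_assert_scalar_number(min_features, "min_features", lower = 0)
  if (!identical(max_features, Inf)) {
    td_assert_scalar_number(max_features, "max_features", lower = 0)
  }
  if (min_features > max_features) {
    td_abort("`min_features` must be <= `max_features`", "trajdyn_config_error")
  }
  td_assert_scalar_number(max_mito_fraction, "max_mito_fraction", 0, 1)
  stopifnot(is.character(mito_prefix), length(mito_prefix) == 1L)
  structure(list(min_features = min_features, max_features = max_features,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @param preset `"invitro"` or `"invivo"`.
#' @export
qc_preset <- function(preset = c("invitro", "invivo")) {
  preset <- match.arg(preset)
  switch(preset,
    invitro = qc_thresholds(1000, 8000, 0.07),
    # "fewer than 7500 features": counts are integers, so <= 7499
    invivo  = qc_thresholds(0, 7499, 0.05)
  )
}

#' Filter cells on detected features and mitochondrial content
#'
#' Retains cells whose detected-gene count lies within
#' `[min_features, max_features]` (inclusive) and whose mitochondrial read
#' fraction is strictly below `max_mito_fraction`. A gene counts as detected
#' in a cell when its count is greater than zero; the mitochondrial fraction
#' is the count sum over genes matching `mito_prefix` divided by the cell's
#' total count (0 for a zero-total cell).
#'
#' @param matrix An `expression_matrix` of raw counts.
#' @param thresholds A [qc_thresholds()] object.
#'
#' @return A `qc_result` list with elements `matrix` (the filtered
#'   `expression_matrix`) and `report`, a tibble with one row per input cell:
#'   `cell_id`, `n_features`, `mito_fraction`, `pass`, and `fail_reason`
#'   (`NA` for passing cells; otherwise which rule failed first:
#'   `"low_features"`, `"high_features"` or `"high_mito"`).
#' @export
#'
#' @examples
#' m <- matrix(rpois(300, 2), 10, 30,
#'             dimnames = list(paste0("c", 1:10), paste0("g", 1:30)))
#' res <- qc_filter_cells(expression_matrix(m, "raw_counts"),
#'                        qc_thresholds(min_features = 5, max_features = Inf,
#'                                      max_mito_fraction = 1))
#' res$report
qc_filter_cells <- function(matrix, thresholds = qc_preset("invitro")) {
  assert_layer(matrix, "raw_counts")
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (nrow(matrix) == 0L) {
    td_abort("expression matrix has no cells", "trajdyn_input_error")
  }
  v <- expr_values(matrix)
  n_features <- as.numeric(Matrix::rowSums(v > 0))
  totals <- as.numeric(Matrix::rowSums(v))
  mito_genes <- startsWith(gene_ids(matrix), thresholds$mito_prefix)
  if (!any(mito_genes)) {
    warn(sprintf("no gene ids start with '%s'; mitochondrial fraction treated as 0",
                 thresholds$mito_prefix))
    mito_fraction <- rep(0, nrow(v))
  } else {
    mito_counts <- as.numeric(Matrix::rowSums(v[, mito_genes, drop = FALSE]))
    mito_fraction <- ifelse(totals > 0, mito_counts / totals, 0)
  }
  fail_reason <- dplyr::case_when(
    n_features < thresholds$min_features ~ "low_features",
    n_features > thresholds$max_features ~ "high_features",
    mito_fraction >= thresholds$max_mito_fraction ~ "high_mito",
    TRUE ~ NA_character_
  )
  report <- tibble(
    cell_id = cell_ids(matrix),
    n_features = n_features,
    mito_fraction = mito_fraction,
    pass = is.na(fail_reason),
    fail_reason = fail_reason
  )
  keep <- which(report$pass)
  if (length(keep) == 0L) {
    warn("no cells pass QC")
  }
  filtered <- expression_matrix(v[keep, , drop = FALSE], layer = "raw_counts")
  structure(list(matrix = filtered, report = report, thresholds = thresholds),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d / %d cells retained\n",
              sum(x$report$pass), nrow(x$report)))
  invisible(x)
}

#' Total-count log-normalization
#'
#' Scales each cell's counts to a common total and applies `log(1 + x)`:
#' `value(c, g) = log1p(count(c, g) * scale_total / total(c))` with the
#' natural logarithm.
#'
#' @param matrix An `expression_matrix` of raw counts.
#' @param scale_total Target per-cell total after scaling (default `1e4`).
#'
#' @return An `expression_matrix` with `layer = "log_normalized"`.
#' @export
#'
#' @examples
#' m <- matrix(c(5, 5, 0, 10), 2, 2,
#'             dimnames = list(c("a", "b"), c("g1", "g2")))
#' lognormalize(expression_matrix(m, "raw_counts"))
lognormalize <- function(matrix, scale_total = 1e4) {
  assert_layer(matrix, "raw_counts")
  td_assert_scalar_number(scale_total, "scale_total", lower = 0, strict_lower = TRUE)
  v <- expr_values(matrix)
  totals <- as.numeric(Matrix::rowSums(v))
  if (any(totals == 0)) {
    bad <- cell_ids(matrix)[totals == 0]
    td_abort(sprintf("cells with zero total count cannot be normalized: %s",
                     paste(utils::head(bad, 5), collapse = ", ")),
             "trajdyn_input_error")
  }
  out <- log1p(as.matrix(v) * (scale_total / totals))
  dimnames(out) <- dimnames(v)
  expression_matrix(out, layer = "log_normalized")
}
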