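#' Read and write pipeline inputs and outputs
#'
#' Plain-text readers and writers for every artifact the pipeline consumes
#' or produces: Matrix-Market expression triplets with barcode/feature
#' sidecars, embedding and pseudotime CSVs, principal-graph node/edge TSVs,
#' grayscale PNG images, and suction-curve CSVs with a phase sidecar.
#'
#' @param matrix An `expression_matrix`.
#' @param dir Directory holding (or to hold) `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @param layer Layer tag to stamp on a matrix being read.
#'
#' @return `read_expression_mtx()` returns an `expression_matrix` (cells x
#'   genes, sparse); the writers return their input invisibly.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
write_expression_mtx <- function(matrix, dir) {
  stopifnot(inherits(matrix, "expression_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- expr_values(matrix)
  # features x cells on disk, the 10x convention
  Matrix::writeMM(methods::as(Matrix::Matrix(t(as.matrix(v)), sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(v), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(v), file.path(dir, "features.tsv"))
  invisible(matrix)
}

#' @rdname expression_io
#' @export
read_expression_mtx <- function(dir, layer = c("log_normalized", "raw_counts")) {
  layer <- match.arg(layer)
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  m <- Matrix::t(m)
  dimnames(m) <- list(barcodes, features)
  expression_matrix(methods::as(m, "CsparseMatrix"), layer = layer)
}

#' Write a full synthetic trajectory dataset to a directory
#'
#' Lays out every component as plain text: the expression matrix as
#' Matrix-Market triplets plus `barcodes.tsv` / `features.tsv`, the
#' embedding, pseudotime and truth labels as headered CSVs, and the graph
#' as `nodes.tsv` / `edges.tsv`.
#'
#' @param dataset A `trajectory_dataset`.
#' @param dir Output directory (created if needed).
#' @return The dataset, invisibly.
#' @export
write_trajectory_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_mtx(dataset$expression, dir)
  readr::write_csv(dataset$embedding, file.path(dir, "embedding.csv"))
  readr::write_csv(dataset$pseudotime, file.path(dir, "pseudotime.csv"))
  readr::write_csv(dataset$truth, file.path(dir, "truth.csv"))
  write_principal_graph(dataset$graph, dir)
  invisible(dataset)
}

#' @rdname principal_graph_io
#' @export
write_principal_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "principal_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(graph$nodes, file.path(dir, "nodes.tsv"))
  readr::write_tsv(graph$edges, file.path(dir, "edges.tsv"))
  invisible(graph)
}

#' Read or write a principal graph as node/edge TSVs
#'
#' `nodes.tsv` has columns `node_id`, `x`, `y`; `edges.tsv` has `from`,
#' `to`.
#'
#' @param graph A [principal_graph()].
#' @param dir Directory holding (or to hold) the two TSVs.
#' @return `read_principal_graph()` returns a `principal_graph`; the writer
#'   returns its input invisibly.
#' @name principal_graph_io
#' @export
read_principal_graph <- function(dir) {
  principal_graph(
    readr::read_tsv(file.path(dir, "nodes.tsv"), show_col_types = FALSE),
    readr::read_tsv(file.path(dir, "edges.tsv"), show_col_types = FALSE))
}

#' Read per-cell embedding or pseudotime CSVs
#'
#' @param path CSV file with columns `cell_id`, `x`, `y` (embedding) or
#'   `cell_id`, `pseudotime`.
#' @return A tibble.
#' @name cell_csv_io
#' @export
read_embedding_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("cell_id", "x", "y") %in% names(out)))
  out
}

#' @rdname cell_csv_io
#' @export
read_pseudotime_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("cell_id", "pseudotime") %in% names(out)))
  out
}

#' Read or write a grayscale image as PNG
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param path PNG file path.
#' @return `read_gray_png()` returns a numeric matrix; the writer returns
#'   its input invisibly.
#' @name image_io
#' @export
write_gray_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(image)
}

#' @rdname image_io
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Read or write a suction curve as CSV plus a phase sidecar
#'
#' The curve goes to `<stem>.csv` (columns `time_s`, `displacement_mm`) and
#' the phase boundaries to `<stem>_phases.csv` (columns `phase`, `time_s`).
#'
#' @param curve A `suction_curve`.
#' @param stem File-path stem (no extension).
#' @return `read_suction_curve()` returns a `suction_curve`; the writer
#'   returns its input invisibly.
#' @name suction_io
#' @export
write_suction_curve <- function(curve, stem) {
  stopifnot(inherits(curve, "suction_curve"))
  readr::write_csv(curve$samples, paste0(stem, ".csv"))
  readr::write_csv(tibble(phase = c("suction_start", "release", "end"),
                          time_s = c(curve$suction_start_s, curve$release_s,
                                     curve$end_s)),
                   paste0(stem, "_phases.csv"))
  invisible(curve)
}

#' @rdname suction_io
#' @export
read_suction_curve <- function(stem) {
  samples <- readr::read_csv(paste0(stem, ".csv"), show_col_types = FALSE)
  phases <- readr::read_csv(paste0(stem, "_phases.csv"), show_col_types = FALSE)
  pick <- function(p) phases$time_s[phases$phase == p]
  suction_curve(samples$time_s, samples$displacement_mm,
                suction_start_s = pick("suction_start"),
                release_s = pick("release"), end_s = pick("end"))
}

#' Write gene-dynamics results as TSVs
#'
#' Writes the full per-gene record table to `<stem>_records.tsv` and the
#' per-direction fate-gene lists to `<stem>_fate_up.tsv` /
#' `<stem>_fate_down.tsv`.
#'
#' @param result A `gene_dynamics` object.
#' @param stem File-path stem.
#' @return The result, invisibly.
#' @export
write_dynamics_tsv <- function(result, stem) {
  stopifnot(inherits(result, "gene_dynamics"))
  readr::write_tsv(tidy(result), paste0(stem, "_records.tsv"))
  readr::write_tsv(result$fate_up, paste0(stem, "_fate_up.tsv"))
  readr::write_tsv(result$fate_down, paste0(stem, "_fate_down.tsv"))
  invisible(result)
}
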