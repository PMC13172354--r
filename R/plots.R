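#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects for each result type:
#' the embedding with graph and selection for a `cell_selection`, expression
#' against pseudotime with the LOESS trend for a `gene_dynamics` gene, the
#' angular alignment profile for a `radial_profile`, and the displacement
#' trace with phase boundaries for a `suction_curve`.
#'
#' @param object A trajdyn result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name trajdyn-autoplot
NULL

#' @rdname trajdyn-autoplot
#' @export
autoplot.cell_selection <- function(object, ...) {
  poly <- tibble(x = object$path$polyline[, 1], y = object$path$polyline[, 2])
  ggplot2::ggplot(object$cells) +
    ggplot2::aes(colour = .data$selected) +
    ggplot2::geom_point(ggplot2::aes(x = .data$distance,
                                     y = seq_along(.data$distance)),
                        size = 0.6, show.legend = TRUE) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "distance to path", y = "cell (arbitrary order)",
                  colour = "selected",
                  title = sprintf("threshold %.3g at the %.0fth percentile",
                                  object$threshold, 100 * object$percentile)) +
    ggplot2::theme_minimal()
}

#' Plot cells, principal graph and selection in embedding space
#'
#' @param embedding Tibble with `cell_id`, `x`, `y`.
#' @param selection A `cell_selection`.
#' @return A ggplot object.
#' @export
plot_selection_embedding <- function(embedding, selection) {
  emb <- normalize_embedding(embedding)
  emb <- dplyr::left_join(emb, selection$cells, by = "cell_id")
  poly <- tibble(x = selection$path$polyline[, 1],
                 y = selection$path$polyline[, 2])
  ggplot2::ggplot(emb, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 0.6) +
    ggplot2::geom_path(data = poly, linewidth = 0.8, colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "selected") +
    ggplot2::theme_minimal()
}

#' @rdname trajdyn-autoplot
#' @param gene Gene id to display (default: the top-ranked up gene).
#' @export
autoplot.gene_dynamics <- function(object, gene = NULL, ...) {
  if (is.null(gene)) {
    gene <- if (nrow(object$fate_up)) object$fate_up$gene_id[1] else
      object$records$gene_id[which(object$records$passed_prefilter)[1]]
  }
  rec <- object$records[object$records$gene_id == gene, ]
  if (nrow(rec) == 0L || is.null(rec$y[[1]])) {
    td_abort(sprintf("gene '%s' has no fitted values", gene),
             "trajdyn_input_error")
  }
  df <- tibble(pseudotime = unname(object$pseudotime),
               y = rec$y[[1]],
               y_hat = if (is.null(rec$y_hat[[1]])) NA_real_ else rec$y_hat[[1]])
  ggplot2::ggplot(df, ggplot2::aes(.data$pseudotime, .data$y)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_hat), colour = "firebrick",
                       linewidth = 0.9, na.rm = TRUE) +
    ggplot2::labs(y = "log-normalized expression", title = gene,
                  subtitle = sprintf("dynamics range %.3g, rho %.3g",
                                     rec$dynamics_range, rec$rho)) +
    ggplot2::theme_minimal()
}

#' @rdname trajdyn-autoplot
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(.data$angle_deg, .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = (object$peak_angle - 90) %% 180,
                        linetype = 3) +
    ggplot2::labs(x = "spectral angle (deg)", y = "normalized radial sum",
                  title = sprintf("fiber axis %.1f deg, alignment index %.3g",
                                  object$peak_angle, object$alignment_index)) +
    ggplot2::theme_minimal()
}

#' @rdname trajdyn-autoplot
#' @export
autoplot.suction_curve <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(.data$time_s, .data$displacement_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(object$release_s, object$end_s),
                        linetype = 3) +
    ggplot2::labs(x = "time (s)", y = "displacement (mm)") +
    ggplot2::theme_minimal()
}
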