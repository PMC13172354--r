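#' Configuration for gene-dynamics scoring along pseudotime
#'
#' Bundles every tunable of the dynamics pipeline. The two `branch` presets
#' differ only in the static cutoff applied to the dynamics-range score:
#' 0.05 for the pericyte-directed branch and 0.1 for the fibroblast-directed
#' branch.
#'
#' @param branch `"pericyte"` (static cutoff 0.05) or `"fibroblast"` (0.1);
#'   ignored when `static_cutoff` is given explicitly.
#' @param detection_min_fraction Minimum fraction of selected cells in which
#'   a gene must be detected to enter the analysis (default 0.10, inclusive).
#' @param detection_threshold Expression value strictly above which a gene
#'   counts as detected (default 0).
#' @param loess_span LOESS span (default 0.3).
#' @param loess_degree Local polynomial degree, 1 or 2 (default 2).
#' @param static_cutoff Dynamics-range score strictly below which a gene is
#'   classified static.
#' @param top_k Number of fate genes reported per direction (default 20).
#' @param rho_cutoff Strict absolute-Spearman cutoff for the
#'   high-correlation gene set (default 0.7).
#' @param high_rho_from `"dynamic"` (default) applies the |rho| cutoff after
#'   static-gene exclusion; `"all"` applies it to every gene passing the
#'   detection prefilter.
#'
#' @return A `dynamics_config` list.
#' @export
dynamics_config <- function(branch = c("pericyte", "fibroblast"),
                            detection_min_fraction = 0.10,
                            detection_threshold = 0,
                            loess_span = 0.3,
                            loess_degree = 2,
                            static_cutoff = NULL,
                            top_k = 20,
                            rho_cutoff = 0.7,
                            high_rho_from = c("dynamic", "all")) {
  branch <- match.arg(branch)
  high_rho_from <- match.arg(high_rho_from)
  if (is.null(static_cutoff)) {
    static_cutoff <- if (branch == "pericyte") 0.05 else 0.1
  }
  td_assert_scalar_number(detection_min_fraction, "detection_min_fraction", 0, 1)
  td_assert_scalar_number(loess_span, "loess_span", 0, 1, strict_lower = TRUE)
  if (!loess_degree %in% c(1, 2)) {
    td_abort("`loess_degree` must be 1 or 2", "trajdyn_config_error")
  }
  td_assert_scalar_number(static_cutoff, "static_cutoff", 0, 1)
  td_assert_scalar_number(top_k, "top_k", lower = 0)
  td_assert_scalar_number(rho_cutoff, "rho_cutoff", 0, 1)
  structure(list(branch = branch,
                 detection_min_fraction = detection_min_fraction,
                 detection_threshold = detection_threshold,
                 loess_span = loess_span, loess_degree = loess_degree,
                 static_cutoff = static_cutoff, top_k = top_k,
                 rho_cutoff = rho_cutoff, adjust_method = "bonferroni",
                 high_rho_from = high_rho_from),
            class = "dynamics_config")
}

#' Detection-rate prefilter over the selected cell population
#'
#' A gene is retained when it is detected (expression strictly above
#' `detection_threshold`, default 0) in at least `detection_min_fraction`
#' (default 10%) of the selected cells.
#'
#' @param matrix A log-normalized `expression_matrix`.
#' @param selection A `cell_selection` from [select_cells_near_path()], or a
#'   character vector of cell ids.
#' @param config A [dynamics_config()].
#'
#' @return Tibble with `gene_id`, `detection_rate`, `passed_prefilter`.
#' @export
prefilter_genes <- function(matrix, selection, config = dynamics_config()) {
  assert_layer(matrix, "log_normalized")
  ids <- if (inherits(selection, "cell_selection")) selected_ids(selection)
         else as.character(selection)
  if (length(ids) == 0L) {
    td_abort("cell selection is empty", "trajdyn_input_error")
  }
  missing <- setdiff(ids, cell_ids(matrix))
  if (length(missing)) {
    td_abort(sprintf("selected cells absent from matrix: %s",
                     paste(utils::head(missing, 5), collapse = ", ")),
             "trajdyn_input_error")
  }
  v <- expr_values(matrix)[ids, , drop = FALSE]
  rate <- as.numeric(Matrix::colSums(v > config$detection_threshold)) / length(ids)
  tibble(gene_id = gene_ids(matrix), detection_rate = rate,
         passed_prefilter = rate >= config$detection_min_fraction)
}

#' LOESS fit of expression against pseudotime
#'
#' Tricube-weighted local polynomial regression (single pass, Gaussian
#' family) of expression on pseudotime, evaluated at the observed
#' pseudotime points. Ties in pseudotime are permitted.
#'
#' @param pseudotime Numeric vector of finite pseudotime values.
#' @param y Expression values, same length.
#' @param span Neighborhood fraction in (0, 1\] (default 0.3).
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#'
#' @return Fitted values at the input pseudotime points (same length and
#'   order as the input).
#' @export
fit_loess <- function(pseudotime, y, span = 0.3, degree = 2) {
  n <- length(pseudotime)
  if (length(y) != n) td_abort("length mismatch", "trajdyn_input_error")
  if (!all(is.finite(pseudotime))) {
    td_abort("pseudotime must be finite", "trajdyn_input_error")
  }
  if (n < max(10L, degree + 2L)) {
    td_abort(sprintf("need at least %d points for a degree-%d local fit",
                     max(10L, degree + 2L), degree), "trajdyn_input_error")
  }
  if (diff(range(pseudotime)) == 0) {
    td_abort("all pseudotime values are equal; no axis to fit along",
             "trajdyn_input_error")
  }
  fit <- loess(y ~ t, data = data.frame(t = pseudotime, y = y),
               span = span, degree = degree, family = "gaussian",
               control = loess.control(surface = "direct", statistics = "exact"))
  unname(predict(fit, newdata = data.frame(t = pseudotime)))
}

#' Dynamics-range score
#'
#' The ratio of the fitted-value spread to the observed-value spread,
#' `(max(y_hat) - min(y_hat)) / (max(y) - min(y))`. Values near 0 indicate
#' pseudotime-independent ("static") expression; values near 1 indicate that
#' the smooth trend spans the full observed range. A local fit can overshoot
#' the observed extrema, so scores slightly above 1 are possible and are
#' reported as computed, not clipped.
#'
#' @param y Observed expression values (length >= 2).
#' @param y_hat Fitted values at the same points.
#'
#' @return The ratio, or `NA_real_` when `max(y) == min(y)` (degenerate:
#'   no observed spread).
#' @export
#'
#' @examples
#' dynamics_range(0:4, c(0.5, 1, 2, 3, 3.5))  # 0.75
dynamics_range <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    td_abort("`y` and `y_hat` must have the same length", "trajdyn_input_error")
  }
  if (length(y) < 2L) td_abort("need at least 2 points", "trajdyn_input_error")
  denom <- max(y) - min(y)
  if (denom == 0) return(NA_real_)
  (max(y_hat) - min(y_hat)) / denom
}

#' Classify genes as static or dynamic
#'
#' A gene is static when its dynamics-range score is strictly below
#' `static_cutoff`, dynamic when the score is greater than or equal to the
#' cutoff, and degenerate when the score is undefined (no observed spread).
#'
#' @param records Tibble containing a `dynamics_range` column.
#' @param static_cutoff Cutoff fraction (0.05 pericyte preset, 0.1
#'   fibroblast preset).
#'
#' @return The records with a `dynamics_class` column added
#'   (`"static"`, `"dynamic"` or `"degenerate"`).
#' @export
classify_dynamics <- function(records, static_cutoff = 0.05) {
  stopifnot("dynamics_range" %in% names(records))
  dplyr::mutate(records, dynamics_class = dplyr::case_when(
    is.na(.data$dynamics_range) ~ "degenerate",
    .data$dynamics_range < static_cutoff ~ "static",
    TRUE ~ "dynamic"
  ))
}

#' Spearman rank correlation with a large-sample p value
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks (average
#' ranks for ties), with a two-sided p value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' When all `y` values are tied, rho is defined as 0 with p = 1.
#'
#' @param pseudotime Numeric vector (not all tied).
#' @param y Numeric vector, same length (>= 3).
#'
#' @return A list with `rho` and `p_value`.
#' @export
spearman_rank <- function(pseudotime, y) {
  n <- length(pseudotime)
  if (length(y) != n) td_abort("length mismatch", "trajdyn_input_error")
  if (n < 3L) td_abort("need at least 3 pairs", "trajdyn_input_error")
  if (diff(range(pseudotime)) == 0) {
    td_abort("all pseudotime values tied", "trajdyn_input_error")
  }
  if (diff(range(y)) == 0) {
    return(list(rho = 0, p_value = 1))
  }
  rx <- rank(pseudotime); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Rank fate-determining genes by correlation strength
#'
#' Applies Bonferroni correction over the dynamic-class genes tested, flags
#' the strict `|rho| > rho_cutoff` high-correlation set, and ranks the
#' top `top_k` genes per direction (up: rho > 0; down: rho < 0) by
#' descending `|rho|`, ties broken by smaller p value then gene id. Static
#' and degenerate genes never appear in the rankings.
#'
#' @param records Tibble with `gene_id`, `dynamics_class`, `rho`, `p_value`.
#' @param config A [dynamics_config()].
#'
#' @return The records with `p_adjusted`, `direction`, `rank_in_direction`
#'   and `high_rho` columns added.
#' @export
rank_fate_genes <- function(records, config = dynamics_config()) {
  stopifnot(all(c("gene_id", "dynamics_class", "rho", "p_value") %in% names(records)))
  is_dyn <- records$dynamics_class == "dynamic" & !is.na(records$rho)
  m <- sum(is_dyn)
  records$p_adjusted <- NA_real_
  records$p_adjusted[is_dyn] <- pmin(1, records$p_value[is_dyn] * m)
  records$direction <- ifelse(is_dyn & records$rho > 0, "up",
                       ifelse(is_dyn & records$rho < 0, "down", NA))
  records$high_rho <- is_dyn & abs(records$rho) > config$rho_cutoff
  records$rank_in_direction <- NA_integer_
  for (dir in c("up", "down")) {
    idx <- which(!is.na(records$direction) & records$direction == dir)
    if (!length(idx)) next
    ord <- idx[order(-abs(records$rho[idx]), records$p_value[idx],
                     records$gene_id[idx])]
    ranks <- seq_along(ord)
    keep <- ranks <= config$top_k
    records$rank_in_direction[ord[keep]] <- ranks[keep]
  }
  records
}

#' Run the full gene-dynamics pipeline along a trajectory
#'
#' Executes, over the selected cells ordered by pseudotime: the detection
#' prefilter, a LOESS fit per gene, the dynamics-range score, static/dynamic
#' classification, Spearman correlation with pseudotime on the dynamic
#' genes, Bonferroni correction over the dynamic family, and fate-gene
#' ranking. Every input gene receives a record with its pass/fail provenance
#' at each stage.
#'
#' @param matrix A log-normalized `expression_matrix`.
#' @param selection A `cell_selection` (or character vector of cell ids).
#' @param pseudotime Named numeric vector of per-cell pseudotime, or a data
#'   frame with columns `cell_id` and `pseudotime`; must cover the selected
#'   cells.
#' @param config A [dynamics_config()].
#'
#' @return A `gene_dynamics` object: `records` (one tibble row per input
#'   gene with `y`/`y_hat` list columns for fitted genes), `fate_up` and
#'   `fate_down` (per-direction top-k tibbles), `high_rho` (the strict
#'   |rho| > cutoff set), `cells` (selected ids in pseudotime order), and
#'   the `config`.
#' @export
run_dynamics_pipeline <- function(matrix, selection, pseudotime,
                                  config = dynamics_config()) {
  assert_layer(matrix, "log_normalized")
  pt <- normalize_pseudotime(pseudotime)
  ids <- if (inherits(selection, "cell_selection")) selected_ids(selection)
         else as.character(selection)
  missing_pt <- setdiff(ids, names(pt))
  if (length(missing_pt)) {
    td_abort(sprintf("no pseudotime for selected cells: %s",
                     paste(utils::head(missing_pt, 5), collapse = ", ")),
             "trajdyn_input_error")
  }
  pre <- prefilter_genes(matrix, ids, config)
  ids <- ids[order(pt[ids])]
  t_ord <- unname(pt[ids])
  v <- as.matrix(expr_values(matrix)[ids, , drop = FALSE])

  fit_one <- function(gene, passed) {
    y <- v[, gene]
    if (!passed) {
      return(list(y = NULL, y_hat = NULL, dynamics_range = NA_real_))
    }
    if (max(y) == min(y)) {
      return(list(y = y, y_hat = NULL, dynamics_range = NA_real_))
    }
    y_hat <- fit_loess(t_ord, y, span = config$loess_span,
                       degree = config$loess_degree)
    list(y = y, y_hat = y_hat, dynamics_range = dynamics_range(y, y_hat))
  }
  fits <- purrr::map2(pre$gene_id, pre$passed_prefilter, fit_one)

  records <- pre
  records$y <- purrr::map(fits, "y")
  records$y_hat <- purrr::map(fits, "y_hat")
  records$dynamics_range <- purrr::map_dbl(fits, "dynamics_range")
  records$dynamics_range[!records$passed_prefilter] <- NA_real_
  records <- classify_dynamics(records, config$static_cutoff)
  records$dynamics_class[!records$passed_prefilter] <- NA_character_

  cors <- purrr::pmap(
    list(records$y, records$dynamics_class),
    function(y, cls) {
      if (is.null(y) || is.na(cls) || cls != "dynamic") {
        return(list(rho = NA_real_, p_value = NA_real_))
      }
      spearman_rank(t_ord, y)
    })
  records$rho <- purrr::map_dbl(cors, "rho")
  records$p_value <- purrr::map_dbl(cors, "p_value")
  records <- rank_fate_genes(records, config)

  cols <- c("gene_id", "detection_rate", "passed_prefilter", "dynamics_range",
            "dynamics_class", "rho", "p_value", "p_adjusted", "direction",
            "rank_in_direction", "high_rho", "y", "y_hat")
  records <- records[, cols]
  top <- function(dir) {
    out <- records[!is.na(records$rank_in_direction) &
                     !is.na(records$direction) & records$direction == dir, ]
    out <- out[order(out$rank_in_direction), ]
    out[, setdiff(cols, c("y", "y_hat"))]
  }
  structure(list(records = records,
                 fate_up = top("up"), fate_down = top("down"),
                 high_rho = records$gene_id[records$high_rho],
                 cells = ids, pseudotime = setNames(t_ord, ids),
                 config = config),
            class = "gene_dynamics")
}

normalize_pseudotime <- function(pseudotime) {
  if (is.data.frame(pseudotime)) {
    stopifnot(all(c("cell_id", "pseudotime") %in% names(pseudotime)))
    return(setNames(pseudotime$pseudotime, as.character(pseudotime$cell_id)))
  }
  if (is.null(names(pseudotime))) {
    td_abort("pseudotime vector must be named by cell id", "trajdyn_input_error")
  }
  pseudotime
}

#' @export
print.gene_dynamics <- function(x, ...) {
  n_cls <- function(cl) sum(x$records$dynamics_class == cl, na.rm = TRUE)
  cat(sprintf(paste0("<gene_dynamics> %d genes over %d cells: ",
                     "%d dynamic, %d static, %d degenerate; ",
                     "%d with |rho| > %.2g\n"),
              nrow(x$records), length(x$cells),
              n_cls("dynamic"), n_cls("static"), n_cls("degenerate"),
              length(x$high_rho), x$config$rho_cutoff))
  invisible(x)
}
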