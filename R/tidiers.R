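#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per gene, per cell, per angle bin, per curve) and `glance()` a one-row
#' summary.
#'
#' @param x A trajdyn result object.
#' @param ... Unused.
#' @return A tibble.
#' @name trajdyn-tidiers
NULL

#' @rdname trajdyn-tidiers
#' @export
tidy.gene_dynamics <- function(x, ...) {
  dplyr::select(x$records, -dplyr::any_of(c("y", "y_hat")))
}

#' @rdname trajdyn-tidiers
#' @export
glance.gene_dynamics <- function(x, ...) {
  r <- x$records
  tibble(n_genes = nrow(r),
         n_cells = length(x$cells),
         n_prefiltered = sum(r$passed_prefilter),
         n_dynamic = sum(r$dynamics_class == "dynamic", na.rm = TRUE),
         n_static = sum(r$dynamics_class == "static", na.rm = TRUE),
         n_degenerate = sum(r$dynamics_class == "degenerate", na.rm = TRUE),
         n_high_rho = length(x$high_rho),
         static_cutoff = x$config$static_cutoff,
         rho_cutoff = x$config$rho_cutoff)
}

#' @rdname trajdyn-tidiers
#' @export
tidy.qc_result <- function(x, ...) x$report

#' @rdname trajdyn-tidiers
#' @export
glance.qc_result <- function(x, ...) {
  tibble(n_cells = nrow(x$report),
         n_retained = sum(x$report$pass),
         retention_rate = mean(x$report$pass))
}

#' @rdname trajdyn-tidiers
#' @export
tidy.cell_selection <- function(x, ...) x$cells

#' @rdname trajdyn-tidiers
#' @export
glance.cell_selection <- function(x, ...) {
  tibble(n_cells = nrow(x$cells), n_selected = sum(x$cells$selected),
         threshold = x$threshold, percentile = x$percentile)
}

#' @rdname trajdyn-tidiers
#' @export
tidy.radial_profile <- function(x, ...) x$profile

#' @rdname trajdyn-tidiers
#' @export
glance.radial_profile <- function(x, ...) {
  tibble(peak_angle = x$peak_angle, alignment_index = x$alignment_index,
         n_bins = x$n_bins, r_min = x$r_min, r_max = x$r_max)
}

#' @rdname trajdyn-tidiers
#' @export
tidy.r_parameters <- function(x, ...) {
  tibble(parameter = c("Uf", "Ur", "Ua", "R2", "R7"),
         value = c(x$Uf, x$Ur, x$Ua, x$R2, x$R7))
}

#' @rdname trajdyn-tidiers
#' @export
glance.r_parameters <- function(x, ...) {
  tibble(Uf = x$Uf, Ur = x$Ur, Ua = x$Ua, R2 = x$R2, R7 = x$R7,
         degenerate = x$degenerate)
}

#' @rdname trajdyn-tidiers
#' @export
tidy.suction_curve <- function(x, ...) x$samples
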