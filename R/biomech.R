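#' Viscoelasticity R parameters from a suction curve
#'
#' Computes the suction-deformation parameters from a displacement trace
#' with known phase boundaries:
#' * `Uf` — final distension: the maximum displacement during suction;
#' * `Ur` — immediate retraction: `Uf` minus the displacement read a short
#'   window after pressure release (linear interpolation between samples);
#' * `Ua` — total recovery: `Uf` minus the displacement at the end of the
#'   relaxation phase;
#' * `R2 = Ua / Uf` and `R7 = Ur / Uf`, the gross elasticity and immediate
#'   elastic recovery ratios. Higher R7 means more elastic, less viscous
#'   behavior.
#'
#' @param curve A `suction_curve` (from [generate_suction_curve()] or
#'   [suction_curve()]).
#' @param immediate_window_s Seconds after release at which the "immediate"
#'   displacement is read (default 0.1).
#'
#' @return An `r_parameters` list: `Uf`, `Ur`, `Ua`, `R2`, `R7`,
#'   `degenerate` (TRUE when `Uf == 0`, in which case the ratios are `NA`).
#' @export
#'
#' @examples
#' crv <- generate_suction_curve(uf = 0.3, elastic_fraction = 0.5,
#'                               recovery_fraction = 0.8)
#' compute_r_parameters(crv)
compute_r_parameters <- function(curve, immediate_window_s = 0.1) {
  stopifnot(inherits(curve, "suction_curve"))
  td_assert_scalar_number(immediate_window_s, "immediate_window_s", lower = 0)
  s <- curve$samples
  in_suction <- s$time_s >= curve$suction_start_s & s$time_s <= curve$release_s
  in_relax <- s$time_s >= curve$release_s & s$time_s <= curve$end_s
  if (sum(in_suction) < 2L || sum(in_relax) < 2L) {
    td_abort("each phase needs at least 2 samples", "trajdyn_input_error")
  }
  read_at <- function(t) {
    t <- min(max(t, min(s$time_s)), max(s$time_s))
    approx(s$time_s, s$displacement_mm, xout = t, ties = "ordered")$y
  }
  Uf <- max(s$displacement_mm[in_suction])
  t_imm <- min(curve$release_s + immediate_window_s, curve$end_s)
  Ur <- Uf - read_at(t_imm)
  Ua <- Uf - read_at(curve$end_s)
  Ur <- max(Ur, 0); Ua <- max(Ua, 0)
  degenerate <- Uf == 0
  structure(list(Uf = Uf, Ur = Ur, Ua = Ua,
                 R2 = if (degenerate) NA_real_ else Ua / Uf,
                 R7 = if (degenerate) NA_real_ else Ur / Uf,
                 degenerate = degenerate,
                 immediate_window_s = immediate_window_s),
            class = "r_parameters")
}

#' @export
print.r_parameters <- function(x, ...) {
  if (x$degenerate) {
    cat("<r_parameters> degenerate curve (Uf = 0); ratios undefined\n")
  } else {
    cat(sprintf(
      "<r_parameters> Uf %.4g mm, Ur %.4g mm, Ua %.4g mm, R2 %.4g, R7 %.4g\n",
      x$Uf, x$Ur, x$Ua, x$R2, x$R7))
  }
  invisible(x)
}

#' Average R parameters over repeated suction cycles
#'
#' Computes [compute_r_parameters()] per cycle and averages, the convention
#' for multi-cycle suction protocols.
#'
#' @param curves List of `suction_curve` objects (one per cycle).
#' @param immediate_window_s Passed to [compute_r_parameters()].
#'
#' @return A tibble with one row of mean `Uf`, `Ur`, `Ua`, `R2`, `R7` and
#'   the cycle count `n_cycles`.
#' @export
summarize_cycles <- function(curves, immediate_window_s = 0.1) {
  stopifnot(length(curves) >= 1L)
  per <- purrr::map(curves, compute_r_parameters,
                    immediate_window_s = immediate_window_s)
  tb <- purrr::map_dfr(per, ~ tibble(Uf = .x$Uf, Ur = .x$Ur, Ua = .x$Ua,
                                     R2 = .x$R2, R7 = .x$R7))
  dplyr::summarise(tb, dplyr::across(dplyr::everything(),
                                     ~ mean(.x, na.rm = TRUE)),
                   n_cycles = nrow(tb))
}
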