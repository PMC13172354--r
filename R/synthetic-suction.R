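#' Generate a parametric viscoelastic suction curve
#'
#' Simulates the displacement trace of a suction elasticity measurement:
#' during suction the skin surface rises along a saturating exponential to
#' its final distension `uf`; at pressure release it retracts immediately by
#' `elastic_fraction * uf`, holds that level briefly (the generator's model
#' of the device's "immediate retraction" reading window), then creeps back
#' so that the total recovery at the end of relaxation equals
#' `recovery_fraction * uf`. Phase boundaries are recorded on the object so
#' downstream analysis needs no sidecar.
#'
#' @param uf Final distension in mm (maximum displacement during suction).
#' @param elastic_fraction Immediate elastic recovery as a fraction of `uf`,
#'   in \[0, 1\]; the constructed curve's R7 equals this value.
#' @param recovery_fraction Total recovery at the end of relaxation as a
#'   fraction of `uf`; must be >= `elastic_fraction`; the constructed
#'   curve's R2 equals this value.
#' @param dt Sampling interval in seconds.
#' @param suction_s,relax_s Phase durations in seconds (defaults 2 s each).
#' @param immediate_hold_s Post-release plateau duration in seconds
#'   (default 0.1, matching the default analysis window).
#'
#' @return A `suction_curve` list: `samples` (tibble `time_s`,
#'   `displacement_mm`) plus `suction_start_s`, `release_s`, `end_s`.
#' @export
#'
#' @examples
#' crv <- generate_suction_curve(uf = 0.3, elastic_fraction = 0.5,
#'                               recovery_fraction = 0.8)
#' compute_r_parameters(crv)
generate_suction_curve <- function(uf = 0.3, elastic_fraction = 0.5,
                                   recovery_fraction = 0.8, dt = 0.01,
                                   suction_s = 2, relax_s = 2,
                                   immediate_hold_s = 0.1) {
  td_assert_scalar_number(uf, "uf", lower = 0)
  td_assert_scalar_number(elastic_fraction, "elastic_fraction", 0, 1)
  td_assert_scalar_number(recovery_fraction, "recovery_fraction", 0, 1)
  td_assert_scalar_number(dt, "dt", lower = 0, strict_lower = TRUE)
  td_assert_scalar_number(suction_s, "suction_s", lower = 0, strict_lower = TRUE)
  td_assert_scalar_number(relax_s, "relax_s", lower = 0, strict_lower = TRUE)
  if (recovery_fraction < elastic_fraction) {
    td_abort("`recovery_fraction` must be >= `elastic_fraction`",
             "trajdyn_input_error")
  }
  if (immediate_hold_s < 0 || immediate_hold_s >= relax_s) {
    td_abort("`immediate_hold_s` must lie in [0, relax_s)", "trajdyn_input_error")
  }
  end_s <- suction_s + relax_s
  time_s <- seq(0, end_s, by = dt)
  if (utils::tail(time_s, 1) < end_s) time_s <- c(time_s, end_s)

  tau_up <- suction_s / 3
  # normalized so displacement hits uf exactly at release
  rise <- function(t) uf * (1 - exp(-t / tau_up)) / (1 - exp(-suction_s / tau_up))
  plateau <- (1 - elastic_fraction) * uf
  floor_d <- (1 - recovery_fraction) * uf
  hold_end <- suction_s + immediate_hold_s
  tau_dn <- (relax_s - immediate_hold_s) / 3
  creep <- function(t) {
    # 1 at the end of the hold, 0 at end_s
    u <- t - hold_end
    span <- end_s - hold_end
    g <- (exp(-u / tau_dn) - exp(-span / tau_dn)) / (1 - exp(-span / tau_dn))
    floor_d + (plateau - floor_d) * g
  }
  displacement <- ifelse(time_s <= suction_s, rise(time_s),
                  ifelse(time_s <= hold_end, plateau, creep(time_s)))
  structure(list(samples = tibble(time_s = time_s,
                                  displacement_mm = displacement),
                 suction_start_s = 0, release_s = suction_s, end_s = end_s),
            class = "suction_curve")
}

#' @export
print.suction_curve <- function(x, ...) {
  cat(sprintf(paste0("<suction_curve> %d samples over %.3g s ",
                     "(release at %.3g s), max displacement %.4g mm\n"),
              nrow(x$samples), x$end_s, x$release_s,
              max(x$samples$displacement_mm)))
  invisible(x)
}

#' Construct a suction curve from raw samples
#'
#' Wraps an externally measured displacement time series with its phase
#' boundaries so it can be analyzed by [compute_r_parameters()].
#'
#' @param time_s Strictly increasing times in seconds.
#' @param displacement_mm Nonnegative displacements in mm, same length.
#' @param suction_start_s,release_s,end_s Phase timestamps with
#'   `suction_start_s < release_s < end_s`, all within the sampled range.
#'
#' @return A `suction_curve`.
#' @export
suction_curve <- function(time_s, displacement_mm, suction_start_s,
                          release_s, end_s) {
  if (length(time_s) != length(displacement_mm)) {
    td_abort("time and displacement must have the same length",
             "trajdyn_input_error")
  }
  if (any(diff(time_s) <= 0)) {
    td_abort("`time_s` must be strictly increasing", "trajdyn_input_error")
  }
  if (any(!is.finite(displacement_mm)) || any(displacement_mm < 0)) {
    td_abort("displacement must be finite and >= 0", "trajdyn_input_error")
  }
  if (!(suction_start_s < release_s && release_s < end_s)) {
    td_abort("phases must satisfy suction_start < release < end",
             "trajdyn_input_error")
  }
  if (suction_start_s < min(time_s) || end_s > max(time_s)) {
    td_abort("phase timestamps must lie within the sampled time range",
             "trajdyn_input_error")
  }
  structure(list(samples = tibble(time_s = time_s,
                                  displacement_mm = displacement_mm),
                 suction_start_s = suction_start_s, release_s = release_s,
                 end_s = end_s),
            class = "suction_curve")
}
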