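#' Pulsatility index from Doppler velocities
#'
#' `PI = (Vps - Ved) / Vm`: the systolic-diastolic velocity excursion of the
#' waveform normalised by the time-averaged mean velocity. Dimensionless; 0
#' for pulseless flow.
#'
#' @param vps Peak systolic velocity, cm/s (vectorised).
#' @param ved End-diastolic velocity, cm/s.
#' @param vm Mean velocity, cm/s. Requires `vps >= ved` and `vm > 0`.
#' @return Pulsatility index.
#' @export
#' @examples
#' pulsatility_index(100, 40, 60)
pulsatility_index <- function(vps, ved, vm) {
  if (any(!is.finite(c(vps, ved, vm)))) stop("velocities must be finite", call. = FALSE)
  if (any(vm <= 0)) stop("mean velocity must be positive", call. = FALSE)
  if (any(vps < ved)) stop("peak systolic velocity below end-diastolic velocity", call. = FALSE)
  (vps - ved) / vm
}

#' Volume flow rate from mean velocity and trunk cross-section
#'
#' `VFR = Vm * p0`, with the cross-sectional area supplied in mm^2 and
#' converted to cm^2 internally (`p0 / 100`) so that cm/s times cm^2 gives
#' cm^3/s. This is the single place in the package where a mm-to-cm unit
#' conversion occurs.
#'
#' @param vm Mean velocity, cm/s (vectorised).
#' @param p0 Trunk cross-sectional area, mm^2.
#' @return Volume flow rate, cm^3/s.
#' @export
#' @examples
#' volume_flow_rate(70.6, 6.1)
volume_flow_rate <- function(vm, p0) {
  if (any(!is.finite(c(vm, p0)))) stop("inputs must be finite", call. = FALSE)
  if (any(vm <= 0) || any(p0 <= 0)) {
    stop("mean velocity and cross-sectional area must be positive", call. = FALSE)
  }
  vm * (p0 / 100)
}
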