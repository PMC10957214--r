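#' Plane-wave acquisition parameters
#'
#' Tilt-angle sweep and compound frame rate of the ultrafast Doppler
#' acquisition; only simple arithmetic on these values is supported (the
#' pipeline itself starts from ROI signals).
#'
#' @param angle_min_deg,angle_max_deg inclusive tilt range in degrees.
#' @param angle_step_deg step between successive angles (> 0).
#' @param compound_frame_rate_hz compound frame rate in Hz.
#' @return object of class `acq_params`.
#' @export
acq_params <- function(angle_min_deg, angle_max_deg, angle_step_deg,
                       compound_frame_rate_hz = NA_real_) {
  stopifnot(angle_step_deg > 0, angle_max_deg >= angle_min_deg)
  structure(list(angle_min_deg = angle_min_deg,
                 angle_max_deg = angle_max_deg,
                 angle_step_deg = angle_step_deg,
                 compound_frame_rate_hz = compound_frame_rate_hz),
            class = "acq_params")
}

#' Number of tilted plane waves in the sweep
#'
#' Count of the inclusive arithmetic sequence from `angle_min_deg` to
#' `angle_max_deg` by `angle_step_deg`; e.g. -10 to +10 by 2 gives 11.
#'
#' @param params an `acq_params`.
#' @return integer count.
#' @export
plane_wave_count <- function(params) {
  span <- params$angle_max_deg - params$angle_min_deg
  n <- span / params$angle_step_deg
  if (abs(n - round(n)) > 1e-9) {
    stop("angle span ", span, " is not a multiple of step ",
         params$angle_step_deg)
  }
  as.integer(round(n)) + 1L
}

#' Pulse repetition frequency of the compound acquisition
#'
#' Plane-wave count times the compound frame rate; e.g. 11 angles at a
#' 500 Hz frame rate give a 5.5 kHz PRF.
#'
#' @param params an `acq_params` with `compound_frame_rate_hz` set.
#' @return PRF in Hz.
#' @export
pulse_repetition_frequency <- function(params) {
  if (is.na(params$compound_frame_rate_hz)) {
    stop("compound_frame_rate_hz is not set")
  }
  plane_wave_count(params) * params$compound_frame_rate_hz
}
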