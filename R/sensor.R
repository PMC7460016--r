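#' Depth-sensor error model
#'
#' Parameters of the markerless depth camera emulated by the simulator.
#' The default per-axis noise standard deviations are the published mean
#' joint-position errors of the sensor against a marker-based reference
#' (x: 6.5 mm, y: 10.9 mm, z: 5.7 mm); noise is i.i.d. Gaussian per joint,
#' frame and axis. The operating range and field of view describe where a
#' subject is reliably captured.
#'
#' @param sigma_x,sigma_y,sigma_z per-axis noise SD in meters.
#' @param rate sampling rate in Hz.
#' @param operating_range numeric length-2, min/max camera distance in m.
#' @param fov_h,fov_v horizontal/vertical field of view in degrees.
#' @return object of class `motorkin_sensor`.
#' @export
sensor_model <- function(sigma_x = 0.0065, sigma_y = 0.0109,
                         sigma_z = 0.0057, rate = 30,
                         operating_range = c(1.0, 3.0),
                         fov_h = 54.0, fov_v = 39.1) {
  stopifnot(sigma_x >= 0, sigma_y >= 0, sigma_z >= 0, rate > 0,
            length(operating_range) == 2,
            operating_range[1] < operating_range[2],
            fov_h > 0, fov_v > 0)
  structure(list(sigma = c(x = sigma_x, y = sigma_y, z = sigma_z),
                 rate = rate, operating_range = operating_range,
                 fov_h = fov_h, fov_v = fov_v),
            class = "motorkin_sensor")
}

#' Noise-free sensor
#'
#' Convenience constructor: the same sensor geometry with all noise
#' sigmas set to zero, used for ground-truth recovery checks.
#'
#' @param ... passed to [sensor_model()].
#' @return a `motorkin_sensor` with zero noise.
#' @export
noiseless_sensor <- function(...) {
  sensor_model(sigma_x = 0, sigma_y = 0, sigma_z = 0, ...)
}
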