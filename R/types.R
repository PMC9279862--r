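#' Blood-analog fluid properties
#'
#' Dynamic viscosity and density of the working fluid. The defaults are those
#' of a 60:40 water--glycerol blood analog: viscosity 4.5 cP and density
#' 1.04 g/cm^3, matching normal blood.
#'
#' @param viscosity_cp Dynamic viscosity in centipoise (cP). Must be > 0.
#' @param density_g_cm3 Density in g/cm^3. Must be > 0.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()
#' fluid_properties(viscosity_cp = 3.5)
#' @export
fluid_properties <- function(viscosity_cp = 4.5, density_g_cm3 = 1.04) {
  stopifnot(is.numeric(viscosity_cp), length(viscosity_cp) == 1L,
            is.numeric(density_g_cm3), length(density_g_cm3) == 1L)
  if (!is.finite(viscosity_cp) || viscosity_cp <= 0)
    stop("`viscosity_cp` must be a positive finite number", call. = FALSE)
  if (!is.finite(density_g_cm3) || density_g_cm3 <= 0)
    stop("`density_g_cm3` must be a positive finite number", call. = FALSE)
  structure(list(viscosity_cp = viscosity_cp, density_g_cm3 = density_g_cm3),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: viscosity %.3g cP, density %.4g g/cm^3\n",
              x$viscosity_cp, x$density_g_cm3))
  invisible(x)
}

#' Stenosed vessel geometry
#'
#' Reference (healthy) lumen diameter, percent diameter stenosis and stenosis
#' length. The minimal lumen diameter is
#' `d_s = reference_diameter_mm * (1 - percent_stenosis/100)` and must stay
#' positive.
#'
#' @param reference_diameter_mm Healthy lumen diameter in mm, > 0.
#' @param percent_stenosis Diameter stenosis in percent, in `[0, 100)`.
#' @param stenosis_length_mm Length of the stenosed segment in mm, >= 0.
#' @return An object of class `vessel_geometry` with a computed
#'   `minimal_lumen_diameter_mm` field.
#' @examples
#' vessel_geometry(3, 50, 20)
#' @export
vessel_geometry <- function(reference_diameter_mm, percent_stenosis,
                            stenosis_length_mm) {
  stopifnot(is.numeric(reference_diameter_mm), is.numeric(percent_stenosis),
            is.numeric(stenosis_length_mm))
  if (!is.finite(reference_diameter_mm) || reference_diameter_mm <= 0)
    stop("`reference_diameter_mm` must be positive", call. = FALSE)
  if (!is.finite(percent_stenosis) || percent_stenosis < 0 ||
      percent_stenosis >= 100)
    stop("`percent_stenosis` must lie in [0, 100)", call. = FALSE)
  if (!is.finite(stenosis_length_mm) || stenosis_length_mm < 0)
    stop("`stenosis_length_mm` must be >= 0", call. = FALSE)
  d_s <- reference_diameter_mm * (1 - percent_stenosis / 100)
  if (d_s <= 0)
    stop("invalid geometry: minimal lumen diameter is not positive",
         call. = FALSE)
  structure(list(reference_diameter_mm = reference_diameter_mm,
                 percent_stenosis = percent_stenosis,
                 stenosis_length_mm = stenosis_length_mm,
                 minimal_lumen_diameter_mm = d_s),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("Vessel geometry: d0 = %.3g mm, DS = %.1f%%, L = %.3g mm (ds = %.3g mm)\n",
              x$reference_diameter_mm, x$percent_stenosis,
              x$stenosis_length_mm, x$minimal_lumen_diameter_mm))
  invisible(x)
}

#' Pressure-drop/flow coefficients of a stenosis
#'
#' Coefficients of the two-term stenosis law
#' `dP = A*Q + B*Q^2` with `dP` in mmHg and `Q` in mL/min: `A` is the viscous
#' (Poiseuille-type) coefficient in mmHg.min/mL, `B` the expansion-loss
#' coefficient in mmHg.min^2/mL^2. The flow-dependent stenosis resistance is
#' `R_p(Q) = A + B*Q`.
#'
#' @param a Linear coefficient, mmHg.min/mL, >= 0.
#' @param b Quadratic coefficient, mmHg.min^2/mL^2, >= 0.
#' @return An object of class `pq_coefficients`.
#' @examples
#' pq_coefficients(0.05, 0.002)
#' @export
pq_coefficients <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (!is.finite(a) || a < 0) stop("`a` must be finite and >= 0", call. = FALSE)
  if (!is.finite(b) || b < 0) stop("`b` must be finite and >= 0", call. = FALSE)
  structure(list(a = a, b = b), class = "pq_coefficients")
}

#' @export
print.pq_coefficients <- function(x, ...) {
  cat(sprintf("dP-Q coefficients: A = %.4g mmHg.min/mL, B = %.4g mmHg.min^2/mL^2\n",
              x$a, x$b))
  invisible(x)
}

#' Multiplicative sensor-noise model
#'
#' Relative (multiplicative, zero-mean Gaussian) measurement errors applied
#' independently to the flow reading and to each pressure reading. The
#' defaults (0.5% each) propagate into a relative uncertainty of about 0.7%
#' on the pressure ratio P_d/P_a and 0.5% on the flow ratio, i.e. within the
#' 1% bound typical of a well-calibrated pressure-wire/flow-probe setup.
#'
#' @param flow_relative_sd Relative standard deviation of the flow sensor
#'   (unitless fraction), >= 0.
#' @param pressure_relative_sd Relative standard deviation of each pressure
#'   sensor (unitless fraction), >= 0.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model()            # defaults: 0.5% / 0.5%
#' noise_model(0, 0)        # noise-free
#' @export
noise_model <- function(flow_relative_sd = 0.005, pressure_relative_sd = 0.005) {
  stopifnot(is.numeric(flow_relative_sd), is.numeric(pressure_relative_sd))
  if (!is.finite(flow_relative_sd) || flow_relative_sd < 0)
    stop("`flow_relative_sd` must be >= 0", call. = FALSE)
  if (!is.finite(pressure_relative_sd) || pressure_relative_sd < 0)
    stop("`pressure_relative_sd` must be >= 0", call. = FALSE)
  structure(list(flow_relative_sd = flow_relative_sd,
                 pressure_relative_sd = pressure_relative_sd),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Sensor noise: flow %.3g%%, pressure %.3g%% (relative sd)\n",
              100 * x$flow_relative_sd, 100 * x$pressure_relative_sd))
  invisible(x)
}
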