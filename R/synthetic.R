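# Synthetic hemodynamics generator: stenosis dP-Q coefficients from geometry,
# noisy bench-style measurement sweeps, and cohort sampling with known
# ground-truth FFR.

# Unit conversions. Internal hydraulics are SI; the user-facing units are the
# clinical ones (mmHg, mL/min, cP, g/cm^3, mm).
PA_PER_MMHG <- 133.322
M3S_PER_MLMIN <- 1e-6 / 60

#' Stenosis pressure-drop coefficients from geometry
#'
#' Maps a vessel geometry and fluid to the two-term stenosis law
#' `dP = A*Q + B*Q^2` (dP in mmHg, Q in mL/min):
#' \describe{
#'   \item{A (viscous)}{Excess Poiseuille loss of the stenosed segment over a
#'     same-length healthy segment,
#'     `A = (128 mu L / pi) * (1/d_s^4 - 1/d_0^4)` in SI, so a vessel with no
#'     lumen reduction contributes nothing beyond its reference-vessel
#'     baseline and `A = 0` exactly at 0% stenosis.}
#'   \item{B (expansion loss)}{Young-type sudden-expansion loss downstream of
#'     the throat, `B = (K_e * rho / 2) * (A_0/A_s - 1)^2 / A_0^2` in SI,
#'     with `A_0`, `A_s` the reference and minimal lumen areas and `K_e` an
#'     empirical loss coefficient (default 1.52).}
#' }
#' Both terms are converted to mmHg per (mL/min) powers before return.
#'
#' @param geometry A [vessel_geometry()].
#' @param fluid A [fluid_properties()].
#' @param k_expansion Empirical expansion-loss coefficient, dimensionless.
#' @return A [pq_coefficients()] object.
#' @examples
#' g <- vessel_geometry(3, 50, 20)
#' stenosis_coefficients(g, fluid_properties())
#' @export
stenosis_coefficients <- function(geometry, fluid = fluid_properties(),
                                  k_expansion = 1.52) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(fluid, "fluid_properties"))
  if (!is.finite(k_expansion) || k_expansion <= 0)
    stop("`k_expansion` must be > 0", call. = FALSE)
  mu <- fluid$viscosity_cp * 1e-3              # cP -> Pa.s
  rho <- fluid$density_g_cm3 * 1e3             # g/cm^3 -> kg/m^3
  L <- geometry$stenosis_length_mm * 1e-3      # mm -> m
  d0 <- geometry$reference_diameter_mm * 1e-3
  ds <- geometry$minimal_lumen_diameter_mm * 1e-3
  if (ds <= 0) stop("invalid geometry: minimal lumen diameter <= 0",
                    call. = FALSE)

  a_si <- (128 * mu * L / pi) * (1 / ds^4 - 1 / d0^4)   # Pa / (m^3/s)
  area0 <- pi / 4 * d0^2
  areas <- pi / 4 * ds^2
  b_si <- (k_expansion * rho / 2) * (area0 / areas - 1)^2 / area0^2

  pq_coefficients(a = a_si * M3S_PER_MLMIN / PA_PER_MMHG,
                  b = b_si * M3S_PER_MLMIN^2 / PA_PER_MMHG)
}

#' Pressure drop across the stenosis at a given flow
#'
#' @param coeffs A [pq_coefficients()] object (or list with `a`, `b`).
#' @param q Flow(s) in mL/min, >= 0.
#' @return `a*q + b*q^2` in mmHg.
#' @examples
#' pressure_drop(pq_coefficients(0.05, 0.002), 100)  # 25 mmHg
#' @export
pressure_drop <- function(coeffs, q) {
  stopifnot(is.numeric(q))
  if (any(!is.finite(q)) || any(q < 0))
    stop("`q` must be finite and >= 0", call. = FALSE)
  coeffs$a * q + coeffs$b * q^2
}

#' Per-vessel physiological flow setpoints
#'
#' The bench sweep spans "a range of physiological flow rates"; the default
#' grid is 7 points over 20--220 mL/min. For severe stenoses the upper end
#' would drive the distal pressure to zero, so the grid is rescaled: the
#' maximum setpoint is capped at the flow where the pressure drop consumes
#' `max_dp_fraction` of the aortic pressure, and the minimum is kept at
#' one-tenth of the (possibly reduced) maximum or `q_min`, whichever is
#' smaller.
#'
#' @param coeffs A [pq_coefficients()] object.
#' @param p_a Aortic pressure in mmHg.
#' @param n Number of setpoints (default 7).
#' @param q_min,q_max Nominal sweep range in mL/min (defaults 20, 220).
#' @param max_dp_fraction Largest tolerated `dP/P_a` at the top setpoint
#'   (default 0.8).
#' @return Ascending numeric vector of `n` setpoints in mL/min.
#' @export
physiological_setpoints <- function(coeffs, p_a, n = 7, q_min = 20,
                                    q_max = 220, max_dp_fraction = 0.8) {
  stopifnot(n >= 3, q_min > 0, q_max > q_min, p_a > 0,
            max_dp_fraction > 0, max_dp_fraction < 1)
  a <- coeffs$a
  b <- coeffs$b
  hi <- q_max
  if (a > 0 || b > 0) {
    dp_cap <- max_dp_fraction * p_a
    # largest q with a*q + b*q^2 <= dp_cap
    q_cap <- if (b == 0) dp_cap / a else
      2 * dp_cap / (a + sqrt(a^2 + 4 * b * dp_cap))
    hi <- min(q_max, q_cap)
  }
  lo <- min(q_min, hi / 10)
  seq(lo, hi, length.out = n)
}

#' Synthetic vessel with known ground truth
#'
#' Bundles the geometry, its dP-Q coefficients, the constant aortic pressure
#' held on the bench, and the vessel's own ("true") maximal-vasodilation
#' line. The ground-truth FFR is computed with exactly the same intersection
#' solver the pipeline uses, so downstream recovery can be checked to
#' numerical precision.
#'
#' @param id Vessel label.
#' @param geometry A [vessel_geometry()].
#' @param p_a Aortic pressure in mmHg; must exceed the line's `p_zf`.
#' @param true_cfr_line A [cfr_line()]; default is the standard line.
#' @param fluid A [fluid_properties()].
#' @param k_expansion Expansion-loss coefficient, passed to
#'   [stenosis_coefficients()].
#' @return An object of class `synthetic_vessel` with fields `id`,
#'   `geometry`, `coefficients`, `p_a`, `true_cfr_line`, `true_ffr`.
#' @export
synthetic_vessel <- function(id, geometry, p_a, true_cfr_line = cfr_line(),
                             fluid = fluid_properties(), k_expansion = 1.52) {
  stopifnot(inherits(true_cfr_line, "cfr_line"))
  if (!is.finite(p_a) || p_a <= true_cfr_line$p_zf)
    stop("`p_a` must exceed the zero-flow pressure", call. = FALSE)
  coeffs <- stenosis_coefficients(geometry, fluid, k_expansion)
  sol <- solve_hyperemia(coeffs, p_a = p_a, line = true_cfr_line)
  structure(list(id = as.character(id), geometry = geometry,
                 coefficients = coeffs, p_a = p_a,
                 true_cfr_line = true_cfr_line,
                 true_ffr = sol$ffr3d, true_q_h = sol$q_h),
            class = "synthetic_vessel")
}

#' @export
print.synthetic_vessel <- function(x, ...) {
  cat(sprintf("Synthetic vessel '%s': DS = %.1f%%, Pa = %.3g mmHg, true FFR = %.3f\n",
              x$id, x$geometry$percent_stenosis, x$p_a, x$true_ffr))
  invisible(x)
}

#' Simulate a bench measurement sweep for one vessel
#'
#' Emulates the flow-loop protocol: for each flow setpoint and each of
#' `n_replicates` passes, records flow, aortic pressure and distal pressure
#' with independent zero-mean Gaussian relative errors,
#' `(Q*(1+e_Q), P_a*(1+e_P), (P_a - dP(Q))*(1+e_P'))`. The aortic pressure
#' setpoint is held constant across flows (on the bench the needle valve
#' absorbs the difference). Deterministic given `seed`.
#'
#' @param vessel A [synthetic_vessel()].
#' @param flow_setpoints Ascending non-negative setpoints in mL/min; `NULL`
#'   (default) uses [physiological_setpoints()] for this vessel.
#' @param noise A [noise_model()].
#' @param n_replicates Replicate sweeps (default 3).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A [pf_dataset()] with `n_replicates * length(flow_setpoints)`
#'   rows, ordered replicate-major, each replicate in setpoint order.
#' @examples
#' v <- synthetic_vessel("v1", vessel_geometry(3, 50, 20), p_a = 90)
#' d <- simulate_measurements(v, seed = 1)
#' head(d)
#' @export
simulate_measurements <- function(vessel, flow_setpoints = NULL,
                                  noise = noise_model(), n_replicates = 3,
                                  seed = NULL) {
  stopifnot(inherits(vessel, "synthetic_vessel"),
            inherits(noise, "noise_model"), n_replicates >= 1)
  if (is.null(flow_setpoints))
    flow_setpoints <- physiological_setpoints(vessel$coefficients, vessel$p_a)
  if (length(flow_setpoints) == 0 || any(!is.finite(flow_setpoints)) ||
      any(flow_setpoints < 0) || is.unsorted(flow_setpoints))
    stop("`flow_setpoints` must be non-empty, non-negative and ascending",
         call. = FALSE)
  dp <- pressure_drop(vessel$coefficients, flow_setpoints)
  pd_true <- vessel$p_a - dp
  if (any(pd_true <= 0))
    stop(sprintf(
      "unphysical operating point: setpoint %.3g mL/min drives Pd to %.3g mmHg",
      flow_setpoints[which(pd_true <= 0)[1]], min(pd_true)), call. = FALSE)

  n_sp <- length(flow_setpoints)
  with_local_seed(seed, {
    rows <- lapply(seq_len(n_replicates), function(rep) {
      e_q <- stats::rnorm(n_sp, 0, noise$flow_relative_sd)
      e_pa <- stats::rnorm(n_sp, 0, noise$pressure_relative_sd)
      e_pd <- stats::rnorm(n_sp, 0, noise$pressure_relative_sd)
      data.frame(vessel_id = vessel$id, replicate = rep,
                 q = flow_setpoints * (1 + e_q),
                 p_a = vessel$p_a * (1 + e_pa),
                 p_d = pd_true * (1 + e_pd))
    })
    pf_dataset(do.call(rbind, rows))
  })
}

#' Generate a synthetic stenosis cohort
#'
#' Samples vessels mirroring an intermediate-stenosis clinical cohort:
#' percent diameter stenosis from a truncated normal (default mean 53.7, sd
#' 17.1, truncated to `[0, 95]`), reference diameter, lesion length and
#' aortic pressure from truncated normals with typical clinical values, and
#' a per-vessel "true" maximal-vasodilation line whose slope and zero-flow
#' pressure are jittered around the standard line to emulate patient-specific
#' microvasculature. Each vessel's ground-truth FFR is computed from its own
#' line with the pipeline's intersection solver.
#'
#' @param n_vessels Number of vessels, >= 1.
#' @param seed Integer seed, or `NULL`.
#' @param ds_mean,ds_sd,ds_range Percent-stenosis distribution (truncated
#'   normal).
#' @param diameter_mean,diameter_sd,diameter_range Reference diameter (mm).
#' @param length_mean,length_sd,length_range Stenosis length (mm).
#' @param pa_mean,pa_sd,pa_range Aortic pressure (mmHg).
#' @param slope_jitter_sd Lognormal sd of the per-vessel multiplicative
#'   jitter on the CFR-line slope (0 disables).
#' @param pzf_jitter_sd Gaussian sd (mmHg) of the per-vessel jitter on the
#'   zero-flow pressure, truncated to `[5, 35]` (0 disables).
#' @param base_line The population-level [cfr_line()] the jitter is applied
#'   around.
#' @param fluid A [fluid_properties()].
#' @return A list of [synthetic_vessel()] objects, length `n_vessels`.
#' @examples
#' cohort <- generate_cohort(5, seed = 1)
#' sapply(cohort, function(v) v$true_ffr)
#' @export
generate_cohort <- function(n_vessels, seed = NULL,
                            ds_mean = 53.7, ds_sd = 17.1, ds_range = c(0, 95),
                            diameter_mean = 3, diameter_sd = 0.4,
                            diameter_range = c(2, 4.5),
                            length_mean = 20, length_sd = 5,
                            length_range = c(5, 40),
                            pa_mean = 90, pa_sd = 10, pa_range = c(60, 120),
                            slope_jitter_sd = 0.15, pzf_jitter_sd = 2,
                            base_line = cfr_line(),
                            fluid = fluid_properties()) {
  if (!is.numeric(n_vessels) || n_vessels < 1)
    stop("`n_vessels` must be >= 1", call. = FALSE)
  for (nm in c("ds_sd", "diameter_sd", "length_sd", "pa_sd",
               "slope_jitter_sd", "pzf_jitter_sd")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0)
      stop(sprintf("configuration error: `%s` must be >= 0", nm),
           call. = FALSE)
  }
  if (ds_range[1] < 0 || ds_range[2] >= 100 || ds_range[1] >= ds_range[2])
    stop("configuration error: `ds_range` must be inside [0, 100)",
         call. = FALSE)
  with_local_seed(seed, {
    ds <- rtruncnorm_(n_vessels, ds_mean, ds_sd, ds_range[1], ds_range[2])
    d0 <- rtruncnorm_(n_vessels, diameter_mean, diameter_sd,
                      diameter_range[1], diameter_range[2])
    len <- rtruncnorm_(n_vessels, length_mean, length_sd,
                       length_range[1], length_range[2])
    pa <- rtruncnorm_(n_vessels, pa_mean, pa_sd, pa_range[1], pa_range[2])
    slope_f <- if (slope_jitter_sd > 0)
      stats::rlnorm(n_vessels, 0, slope_jitter_sd) else rep(1, n_vessels)
    pzf <- if (pzf_jitter_sd > 0)
      rtruncnorm_(n_vessels, base_line$p_zf, pzf_jitter_sd, 5, 35)
    else rep(base_line$p_zf, n_vessels)
    lapply(seq_len(n_vessels), function(i) {
      line <- cfr_line_from_slope(slope = base_line$slope * slope_f[i],
                                  p_zf = pzf[i], q_rest = base_line$q_rest)
      synthetic_vessel(id = sprintf("V%03d", i),
                       geometry = vessel_geometry(d0[i], ds[i], len[i]),
                       p_a = pa[i], true_cfr_line = line, fluid = fluid)
    })
  })
}
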