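# Hyperemia model: maximal-vasodilation CFR-Pd line, intersection with the
# fitted dP-Q curve, FFR and distal microvascular resistance.

#' Maximal-vasodilation CFR--P_d line
#'
#' Under maximal vasodilation, hyperemic coronary flow is linear in distal
#' perfusion pressure: `Q(P_d) = m * (P_d - p_zf)`, where `p_zf` is the
#' zero-flow mean pressure (the residual distal pressure at which flow
#' ceases; 20 mmHg is the physiologically realistic default). The slope is
#' parameterized through interpretable quantities: a resting flow `q_rest`
#' (50 mL/min for a 3 mm native vessel), a normal coronary flow reserve
#' `cfr_normal` and the distal pressure `p_normal` of a healthy vessel at
#' which that reserve is attained, giving
#' `m = cfr_normal * q_rest / (p_normal - p_zf)`.
#'
#' @param q_rest Resting flow in mL/min, > 0. Default 50.
#' @param cfr_normal Coronary flow reserve of a normal vessel (hyperemic over
#'   resting flow), >= 1. Default 3.5.
#' @param p_normal Distal pressure (mmHg) of a healthy vessel at maximal
#'   vasodilation; must exceed `p_zf`. Default 90.
#' @param p_zf Zero-flow mean pressure in mmHg, >= 0. Default 20.
#' @return An object of class `cfr_line` with fields `p_zf`, `slope`
#'   (mL/min/mmHg) and `q_rest`.
#' @examples
#' line <- cfr_line()           # slope 3.5*50/70 = 2.5 mL/min/mmHg
#' cfr_flow(line, p_d = 60)     # 2.5 * (60 - 20) = 100 mL/min
#' @export
cfr_line <- function(q_rest = 50, cfr_normal = 3.5, p_normal = 90, p_zf = 20) {
  stopifnot(is.numeric(q_rest), is.numeric(cfr_normal),
            is.numeric(p_normal), is.numeric(p_zf))
  if (!is.finite(p_zf) || p_zf < 0) stop("`p_zf` must be >= 0", call. = FALSE)
  if (!is.finite(q_rest) || q_rest <= 0)
    stop("`q_rest` must be > 0", call. = FALSE)
  if (!is.finite(cfr_normal) || cfr_normal < 1)
    stop("`cfr_normal` must be >= 1", call. = FALSE)
  if (!is.finite(p_normal) || p_normal <= p_zf)
    stop("`p_normal` must exceed `p_zf`", call. = FALSE)
  m <- cfr_normal * q_rest / (p_normal - p_zf)
  structure(list(p_zf = p_zf, slope = m, q_rest = q_rest,
                 cfr_normal = cfr_normal, p_normal = p_normal),
            class = "cfr_line")
}

#' Construct a CFR line directly from slope and intercept
#'
#' Lower-level companion to [cfr_line()] for when the slope itself is known
#' (e.g. a per-patient jittered line in the synthetic cohort).
#'
#' @param slope Slope m in mL/min per mmHg, > 0.
#' @param p_zf Zero-flow mean pressure in mmHg, >= 0.
#' @param q_rest Resting flow in mL/min, > 0.
#' @return An object of class `cfr_line`.
#' @export
cfr_line_from_slope <- function(slope, p_zf = 20, q_rest = 50) {
  if (!is.finite(slope) || slope <= 0) stop("`slope` must be > 0", call. = FALSE)
  if (!is.finite(p_zf) || p_zf < 0) stop("`p_zf` must be >= 0", call. = FALSE)
  if (!is.finite(q_rest) || q_rest <= 0)
    stop("`q_rest` must be > 0", call. = FALSE)
  structure(list(p_zf = p_zf, slope = slope, q_rest = q_rest,
                 cfr_normal = NA_real_, p_normal = NA_real_),
            class = "cfr_line")
}

#' Evaluate a CFR line
#'
#' @param line A `cfr_line`.
#' @param p_d Distal pressure(s) in mmHg.
#' @return Maximal-vasodilation flow `m * (p_d - p_zf)` in mL/min (zero at
#'   `p_d = p_zf`, negative values are not clamped).
#' @export
cfr_flow <- function(line, p_d) {
  stopifnot(inherits(line, "cfr_line"), is.numeric(p_d))
  line$slope * (p_d - line$p_zf)
}

#' @export
print.cfr_line <- function(x, ...) {
  cat(sprintf("CFR-Pd line: Q = %.4g * (Pd - %.3g)  [mL/min; mmHg], q_rest = %.3g mL/min\n",
              x$slope, x$p_zf, x$q_rest))
  invisible(x)
}

#' Distal microvascular resistance
#'
#' The resistance offered by the distal bed at hyperemia,
#' `R_d = (P_d - P_zf) / Q_h`.
#'
#' @param p_d_h Hyperemic distal pressure, mmHg; must exceed `p_zf`.
#' @param p_zf Zero-flow mean pressure, mmHg.
#' @param q_h Hyperemic flow, mL/min, > 0.
#' @return Resistance in mmHg.min/mL.
#' @examples
#' compute_rd(70, 20, 100)  # 0.5
#' @export
compute_rd <- function(p_d_h, p_zf, q_h) {
  stopifnot(is.numeric(p_d_h), is.numeric(p_zf), is.numeric(q_h))
  if (any(!is.finite(q_h)) || any(q_h <= 0))
    stop("`q_h` must be > 0", call. = FALSE)
  if (any(!is.finite(p_d_h)) || any(p_d_h <= p_zf))
    stop("unphysical state: `p_d_h` must exceed `p_zf`", call. = FALSE)
  (p_d_h - p_zf) / q_h
}

#' Solve for the hyperemic operating point
#'
#' Intersects the stenosis pressure-drop curve `dP(Q) = a*Q + b*Q^2` (at a
#' fixed aortic pressure `p_a`) with the maximal-vasodilation line
#' `Q = m * (P_d - p_zf)`. Substituting `P_d = p_a - dP(Q)` gives
#' `m*b*Q^2 + (1 + m*a)*Q - m*(p_a - p_zf) = 0`, whose unique positive root
#' is taken in the cancellation-free form
#' `Q = 2*m*(p_a - p_zf) / ((1 + m*a) + sqrt((1 + m*a)^2 + 4*m*b*m*(p_a - p_zf)))`,
#' which degrades gracefully to the linear solution as `b -> 0`.
#'
#' @param fit A `pq_curve_fit` (see [fit_pq_curve()]), a `pq_coefficients`
#'   object, or any list with numeric fields `a` and `b`.
#' @param p_a Aortic pressure in mmHg; must exceed `line$p_zf`.
#' @param line A `cfr_line`.
#' @return An object of class `hyperemia_solution` with fields `q_h`
#'   (hyperemic flow, mL/min), `p_d_h` (hyperemic distal pressure, mmHg),
#'   `ffr3d` (`p_d_h / p_a`), `r_d` (distal resistance, mmHg.min/mL) and
#'   `p_a`.
#' @examples
#' line <- cfr_line()
#' solve_hyperemia(pq_coefficients(0.05, 0.002), p_a = 90, line = line)
#' @export
solve_hyperemia <- function(fit, p_a, line) {
  stopifnot(inherits(line, "cfr_line"), is.numeric(p_a), length(p_a) == 1L)
  a <- fit$a
  b <- fit$b
  if (!is.finite(a) || !is.finite(b) || a < 0 || b < 0)
    stop("fit error: coefficients must be finite and non-negative",
         call. = FALSE)
  if (!is.finite(p_a) || p_a <= line$p_zf)
    stop("no perfusion pressure: `p_a` must exceed the zero-flow pressure",
         call. = FALSE)
  m <- line$slope
  dp_avail <- p_a - line$p_zf
  lin <- 1 + m * a
  if (b == 0) {
    q_h <- m * dp_avail / lin
  } else {
    disc <- lin^2 + 4 * (m * b) * (m * dp_avail)
    q_h <- 2 * m * dp_avail / (lin + sqrt(disc))
  }
  p_d_h <- p_a - (a * q_h + b * q_h^2)
  structure(list(q_h = q_h,
                 p_d_h = p_d_h,
                 ffr3d = p_d_h / p_a,
                 r_d = compute_rd(p_d_h, line$p_zf, q_h),
                 p_a = p_a,
                 p_zf = line$p_zf),
            class = "hyperemia_solution")
}

#' @export
print.hyperemia_solution <- function(x, ...) {
  cat(sprintf("Hyperemic solution: Q_h = %.4g mL/min, Pd = %.4g mmHg (Pa = %.4g)\n",
              x$q_h, x$p_d_h, x$p_a))
  cat(sprintf("  FFR = %.3f, R_d = %.4g mmHg.min/mL\n", x$ffr3d, x$r_d))
  invisible(x)
}

#' Full per-vessel pipeline: measurements to FFR
#'
#' Composes [average_replicates()], [fit_pq_curve()] and [solve_hyperemia()]
#' for one vessel's pressure-flow dataset. `p_a` defaults to the mean
#' measured aortic pressure (the bench holds it constant, so the mean is the
#' setpoint).
#'
#' @param dataset A `pf_dataset` (see [pf_dataset()] / [read_measurements()]).
#' @param line A `cfr_line`.
#' @param p_a Aortic pressure in mmHg; `NULL` (default) uses the mean of the
#'   measured `p_a` column.
#' @return A `hyperemia_solution` with the intermediate `pq_curve_fit`
#'   attached as field `fit`.
#' @export
ffr3d_pipeline <- function(dataset, line, p_a = NULL) {
  avg <- average_replicates(dataset)
  fit <- fit_pq_curve(avg)
  if (is.null(p_a)) p_a <- mean(dataset$p_a)
  sol <- solve_hyperemia(fit, p_a = p_a, line = line)
  sol$fit <- fit
  sol
}
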