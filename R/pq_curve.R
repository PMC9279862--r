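# dP-Q curve construction: replicate averaging, constrained quadratic fit,
# and first-order propagation of sensor uncertainty into the clinical ratios.

#' Pressure-flow measurement dataset
#'
#' A data.frame of replicate bench records with columns `vessel_id`,
#' `replicate` (integer >= 1), `q` (mL/min), `p_a` (mmHg), `p_d` (mmHg).
#' Each replicate is a sweep through the same flow setpoints in the same
#' (ascending) order, so records are matched across replicates by position
#' within the sweep; all replicates must therefore have the same number of
#' rows. A `p_d` slightly above `p_a` (sensor noise at near-zero pressure
#' drop) is tolerated here and handled during averaging.
#'
#' @param df A data.frame with the columns above.
#' @return `df` with class `pf_dataset` prepended, ordered by
#'   `(replicate, sweep position)`.
#' @export
pf_dataset <- function(df) {
  req <- c("vessel_id", "replicate", "q", "p_a", "p_d")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("empty dataset", call. = FALSE)
  for (col in c("replicate", "q", "p_a", "p_d")) {
    if (!is.numeric(df[[col]]) || any(!is.finite(df[[col]])))
      stop(sprintf("column `%s` must be finite numeric", col), call. = FALSE)
  }
  if (any(df$q < 0)) stop("flow `q` must be >= 0", call. = FALSE)
  if (any(df$p_a <= 0) || any(df$p_d <= 0))
    stop("pressures must be > 0", call. = FALSE)
  if (any(df$replicate < 1) || any(df$replicate != round(df$replicate)))
    stop("`replicate` must be a positive integer", call. = FALSE)
  counts <- table(df$replicate)
  if (length(unique(counts)) != 1L)
    stop("structural error: replicates have unequal record counts",
         call. = FALSE)
  df <- df[order(df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pf_dataset", "data.frame")
  df
}

#' Average replicate sweeps into one dP-Q curve
#'
#' Collapses the replicate sweeps of a [pf_dataset()] into one averaged
#' record per flow setpoint: the arithmetic mean of `q`, `p_a` and `p_d`
#' across replicates, the mean pressure drop `dp = mean(p_a) - mean(p_d)`,
#' and the sample standard deviation of the per-replicate pressure drop.
#' Records whose `p_d` exceeds `p_a` by more than `pa_tolerance * p_a`
#' (physically impossible beyond noise) are rejected with a warning and the
#' remaining replicates averaged.
#'
#' @param dataset A [pf_dataset()].
#' @param pa_tolerance Tolerated relative excess of `p_d` over `p_a`
#'   (default 0.01, i.e. 1% of `p_a`).
#' @return A data.frame of class `pq_points` with columns `q`, `dp`, `p_a`,
#'   `p_d`, `sd_dp`, `n_rep`, one row per setpoint in sweep order.
#' @export
average_replicates <- function(dataset, pa_tolerance = 0.01) {
  if (!inherits(dataset, "pf_dataset")) dataset <- pf_dataset(dataset)
  reps <- split(seq_len(nrow(dataset)), dataset$replicate)
  n_sp <- length(reps[[1]])
  if (n_sp < 3)
    stop("structural error: need at least 3 flow setpoints to characterize the curve",
         call. = FALSE)
  get_mat <- function(col)
    vapply(reps, function(idx) dataset[[col]][idx], numeric(n_sp))
  qm <- get_mat("q"); pam <- get_mat("p_a"); pdm <- get_mat("p_d")

  bad <- pdm > pam * (1 + pa_tolerance)
  if (any(bad)) {
    warning(sprintf(
      "rejected %d record(s) with p_d exceeding p_a by more than %.3g%% of p_a",
      sum(bad), 100 * pa_tolerance), call. = FALSE)
    qm[bad] <- NA; pam[bad] <- NA; pdm[bad] <- NA
  }
  dpm <- pam - pdm
  out <- data.frame(
    q = rowMeans(qm, na.rm = TRUE),
    dp = rowMeans(pam, na.rm = TRUE) - rowMeans(pdm, na.rm = TRUE),
    p_a = rowMeans(pam, na.rm = TRUE),
    p_d = rowMeans(pdm, na.rm = TRUE),
    sd_dp = apply(dpm, 1, stats::sd, na.rm = TRUE),
    n_rep = rowSums(!is.na(qm))
  )
  out <- out[out$n_rep > 0, , drop = FALSE]
  if (nrow(out) < 3)
    stop("structural error: fewer than 3 usable setpoints after rejection",
         call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pq_points", "data.frame")
  out
}

#' Fit the quadratic-through-origin stenosis law
#'
#' Weighted least squares of the averaged pressure drop on `(q, q^2)` with no
#' intercept (the drop must vanish at zero flow in a rigid loop) and
#' non-negativity constraints on both coefficients. With only two parameters
#' the constrained problem is solved by active-set enumeration: the
#' unconstrained fit is accepted when feasible, otherwise the candidate fits
#' with each (or both) coefficients clamped to zero are compared by weighted
#' residual sum of squares.
#'
#' Weighting: under multiplicative sensor noise the variance of an averaged
#' pressure drop is proportional to `(p_a^2 + p_d^2) / n_rep` with a common
#' unknown factor, so the relative weights are known from the measured
#' pressures alone; this `"noise_structure"` scheme is the default whenever
#' the averaged pressures are available. Empirical `1/sd^2` weights from the
#' per-setpoint replicate standard deviations (`"replicate_sd"`) are offered
#' but carry only `n_rep - 1` degrees of freedom each, which makes them
#' noisy enough to inflate the estimator variance with triplicate sweeps.
#' `"uniform"` ignores both.
#'
#' @param points A `pq_points` data.frame from [average_replicates()], or any
#'   data.frame with columns `q`, `dp` (and optionally `p_a`, `p_d`,
#'   `n_rep`, `sd_dp`).
#' @param weighting One of `"auto"` (default: `"noise_structure"` when the
#'   pressure columns are present, else `"replicate_sd"` when positive
#'   `sd_dp` is present, else uniform), `"noise_structure"`,
#'   `"replicate_sd"`, `"uniform"`.
#' @return An object of class `pq_curve_fit`: fields `a`, `b` (clamped
#'   coefficients), `covariance` (2x2, rows/cols `a`, `b`; zero for clamped
#'   terms), `rmse` (unweighted residual RMSE, mmHg), `n_points`, and
#'   `clamped` (character vector of clamped coefficient names).
#' @examples
#' pts <- data.frame(q = c(50, 100, 150, 200),
#'                   dp = 0.05 * c(50, 100, 150, 200) +
#'                        0.002 * c(50, 100, 150, 200)^2)
#' fit_pq_curve(pts)
#' @export
fit_pq_curve <- function(points, weighting = c("auto", "noise_structure",
                                               "replicate_sd", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(points), all(c("q", "dp") %in% names(points)))
  q <- points$q
  dp <- points$dp
  n <- length(q)
  if (n < 3) stop("fit error: need at least 3 distinct setpoints", call. = FALSE)
  if (length(unique(signif(q, 12))) < 3 || all(q == 0))
    stop("fit error: rank-deficient design (flow setpoints not distinct)",
         call. = FALSE)
  sd_dp <- points$sd_dp
  has_press <- all(c("p_a", "p_d") %in% names(points))
  has_sd <- !is.null(sd_dp) && all(is.finite(sd_dp)) && all(sd_dp > 0)
  if (weighting == "auto")
    weighting <- if (has_press) "noise_structure"
                 else if (has_sd) "replicate_sd" else "uniform"
  w <- switch(weighting,
    noise_structure = {
      if (!has_press)
        stop("noise_structure weighting needs `p_a` and `p_d` columns",
             call. = FALSE)
      n_rep <- if (!is.null(points$n_rep)) points$n_rep else rep(1, n)
      n_rep / (points$p_a^2 + points$p_d^2)
    },
    replicate_sd = {
      if (!has_sd)
        stop("replicate_sd weighting needs positive `sd_dp`", call. = FALSE)
      1 / sd_dp^2
    },
    uniform = rep(1, n))

  X <- cbind(q = q, q2 = q^2)
  wls <- function(cols) {
    Xc <- X[, cols, drop = FALSE]
    xtwx <- crossprod(Xc * w, Xc)
    beta <- tryCatch(solve(xtwx, crossprod(Xc * w, dp)),
                     error = function(e)
                       stop("fit error: singular design", call. = FALSE))
    res <- dp - Xc %*% beta
    list(cols = cols, beta = drop(beta), wssr = sum(w * res^2),
         res = drop(res), xtwx_inv = solve(xtwx))
  }
  full <- wls(c("q", "q2"))
  cand <- if (all(full$beta >= 0)) full else {
    cands <- list(wls("q"), wls("q2"))
    cands <- Filter(function(f) all(f$beta >= 0), cands)
    if (length(cands) == 0)
      list(cols = character(0), beta = numeric(0), wssr = sum(w * dp^2),
           res = dp, xtwx_inv = matrix(0, 0, 0))
    else cands[[which.min(vapply(cands, `[[`, numeric(1), "wssr"))]]
  }

  coefs <- c(q = 0, q2 = 0)
  coefs[cand$cols] <- cand$beta
  p_free <- length(cand$cols)
  sigma2 <- if (n > p_free) cand$wssr / (n - p_free) else 0
  covariance <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  if (p_free > 0) {
    idx <- match(cand$cols, c("q", "q2"))
    covariance[idx, idx] <- sigma2 * cand$xtwx_inv
  }
  structure(list(a = unname(coefs["q"]), b = unname(coefs["q2"]),
                 covariance = covariance,
                 rmse = sqrt(mean(cand$res^2)),
                 n_points = n,
                 clamped = setdiff(c("a", "b"),
                                   c("a", "b")[match(cand$cols, c("q", "q2"))])),
            class = "pq_curve_fit")
}

#' @export
print.pq_curve_fit <- function(x, ...) {
  cat(sprintf("dP-Q fit over %d points: dP = %.4g*Q + %.4g*Q^2 (rmse %.3g mmHg)\n",
              x$n_points, x$a, x$b, x$rmse))
  if (length(x$clamped) > 0)
    cat("  clamped at zero:", paste(x$clamped, collapse = ", "), "\n")
  invisible(x)
}

#' Stenosis resistance at a given flow
#'
#' The flow-dependent stenosis resistance implied by a fit,
#' `R_p(q) = a + b*q` (mmHg.min/mL), non-decreasing in `q`.
#'
#' @param fit A `pq_curve_fit` or `pq_coefficients`.
#' @param q Flow(s) in mL/min, >= 0.
#' @return Resistance values in mmHg.min/mL.
#' @export
stenosis_resistance <- function(fit, q) {
  stopifnot(is.numeric(q))
  if (any(q < 0)) stop("`q` must be >= 0", call. = FALSE)
  fit$a + fit$b * q
}

#' Propagate sensor noise into the clinical ratios
#'
#' First-order (Taylor) propagation of the independent relative sensor
#' errors into the relative standard deviation of the pressure ratio
#' `p_d/p_a` and of the flow ratio `q/q_rest`: for independent
#' multiplicative errors these are `sqrt(sd_pd^2 + sd_pa^2)` and `sd_q`
#' respectively (the resting flow is a model constant, not a measurement).
#'
#' @param points A `pq_points` data.frame (needs columns `q`, `p_a`, `p_d`).
#' @param noise A [noise_model()].
#' @param line A [cfr_line()] supplying the resting flow `q_rest`.
#' @return A data.frame of class `ratio_uncertainty` with one row per point:
#'   `q`, `pressure_ratio`, `flow_ratio`, `pressure_ratio_rel_sd`,
#'   `flow_ratio_rel_sd` (unitless fractions).
#' @export
propagate_uncertainty <- function(points, noise = noise_model(),
                                  line = cfr_line()) {
  stopifnot(is.data.frame(points), inherits(noise, "noise_model"),
            inherits(line, "cfr_line"))
  if (any(points$p_a <= 0) || any(points$p_d <= 0))
    stop("pressures must be > 0", call. = FALSE)
  if (line$q_rest <= 0) stop("`q_rest` must be > 0", call. = FALSE)
  out <- data.frame(
    q = points$q,
    pressure_ratio = points$p_d / points$p_a,
    flow_ratio = points$q / line$q_rest,
    pressure_ratio_rel_sd = sqrt(2) * noise$pressure_relative_sd,
    flow_ratio_rel_sd = noise$flow_relative_sd
  )
  class(out) <- c("ratio_uncertainty", "data.frame")
  out
}
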