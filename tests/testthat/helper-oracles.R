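# Independent oracles and fixture builders shared across the suite.

# Bisection oracle for the hyperemic intersection: root of
# g(Q) = m*(p_a - p_zf - a*Q - b*Q^2) - Q on [0, 10*m*(p_a - p_zf)].
# Kept deliberately independent of the closed-form solver.
bisect_hyperemia <- function(a, b, p_a, m, p_zf = 20, tol = 1e-12) {
  g <- function(q) m * (p_a - p_zf - a * q - b * q^2) - q
  upper <- 10 * m * (p_a - p_zf)
  stopifnot(g(0) > 0, g(upper) < 0)
  stats::uniroot(g, c(0, upper), tol = tol)$root
}

# Exhaustive concordant-pair AUC: P(x_pos < x_neg) + 0.5*P(ties), where the
# positive class carries the *lower* FFR estimate.
auc_by_counting <- function(x, positive) {
  xp <- x[positive]
  xn <- x[!positive]
  tot <- 0
  for (a in xp) for (b in xn)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(xp) * length(xn))
}

# Direct Clopper-Pearson interval by binomial tail inversion.
clopper_pearson <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) -
                     alpha / 2, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# Noise-free bench sweep laid out as a pf_dataset, replicated verbatim.
exact_dataset <- function(a, b, p_a, setpoints = seq(20, 140, length.out = 7),
                          n_rep = 3, id = "v1") {
  dp <- a * setpoints + b * setpoints^2
  pf_dataset(do.call(rbind, lapply(seq_len(n_rep), function(r)
    data.frame(vessel_id = id, replicate = r, q = setpoints,
               p_a = p_a, p_d = p_a - dp))))
}

toy_pairs <- function() {
  data.frame(
    vessel_id = sprintf("v%02d", 1:10),
    ffr3d = c(0.55, 0.61, 0.68, 0.72, 0.74, 0.77, 0.81, 0.85, 0.88, 0.93),
    ffr_ref = c(0.70, 0.75, 0.62, 0.79, 0.83, 0.72, 0.85, 0.90, 0.78, 0.95))
}
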