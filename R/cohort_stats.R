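# Cohort-level concordance and discrimination statistics: Spearman
# correlation, paired mean comparison, Bland-Altman agreement with
# proportional-bias test, and ROC analysis with a Youden-optimal threshold.

check_pairs <- function(pairs, n_min = 2) {
  stopifnot(is.data.frame(pairs), all(c("ffr3d", "ffr_ref") %in% names(pairs)))
  x <- pairs$ffr3d
  y <- pairs$ffr_ref
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite FFR values", call. = FALSE)
  if (any(x <= 0) || any(x > 1) || any(y <= 0) || any(y > 1))
    stop("FFR values must lie in (0, 1]", call. = FALSE)
  if (nrow(pairs) < n_min)
    stop(sprintf("insufficient data: need at least %d pairs", n_min),
         call. = FALSE)
  pairs
}

#' Spearman rank correlation of paired FFR estimates
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' t-approximation `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` df by default;
#' `method = "exact"` delegates to the exact null distribution (only for
#' small n without ties).
#'
#' @param pairs Data.frame with columns `ffr3d` and `ffr_ref`.
#' @param method `"t"` (default) or `"exact"`.
#' @return List with `r` and `p`.
#' @export
spearman_concordance <- function(pairs, method = c("t", "exact")) {
  method <- match.arg(method)
  pairs <- check_pairs(pairs, n_min = 3)
  x <- pairs$ffr3d
  y <- pairs$ffr_ref
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  r <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  if (method == "exact") {
    ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    p <- ct$p.value
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d_i = ffr3d_i - ffr_ref_i`: bias is the mean difference and
#' the 95% limits of agreement are `bias +/- 1.96 * sd(d)` (sample sd,
#' `n - 1` denominator). Proportional bias is assessed as the Spearman
#' correlation of the differences with the pair means.
#'
#' @param pairs Data.frame with columns `ffr3d` and `ffr_ref`.
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `proportional_bias_r`, `proportional_bias_p` (the latter two `NA` when
#'   the differences or means are constant).
#' @export
bland_altman <- function(pairs) {
  pairs <- check_pairs(pairs, n_min = 2)
  d <- pairs$ffr3d - pairs$ffr_ref
  avg <- (pairs$ffr3d + pairs$ffr_ref) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  prop <- list(r = NA_real_, p = NA_real_)
  if (sd_d > 0 && stats::sd(avg) > 0 && length(d) >= 3) {
    r <- stats::cor(d, avg, method = "spearman")
    n <- length(d)
    p <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
    prop <- list(r = r, p = p)
  }
  list(bias = bias, sd_diff = sd_d,
       loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
       proportional_bias_r = prop$r, proportional_bias_p = prop$p)
}

#' Paired comparison of mean FFR
#'
#' Two-sided paired t-test on the differences.
#'
#' @param pairs Data.frame with columns `ffr3d` and `ffr_ref`.
#' @return Two-sided p-value.
#' @export
compare_means <- function(pairs) {
  pairs <- check_pairs(pairs, n_min = 2)
  d <- pairs$ffr3d - pairs$ffr_ref
  if (stats::sd(d) == 0)
    stop("degenerate test: zero-variance differences", call. = FALSE)
  stats::t.test(pairs$ffr3d, pairs$ffr_ref, paired = TRUE)$p.value
}

#' ROC analysis of FFR discrimination
#'
#' Dichotomizes the reference at `reference_cutoff` (positive/ischemic:
#' `ffr_ref <= cutoff`) and sweeps all distinct `ffr3d` values as candidate
#' thresholds, predicting positive when `ffr3d <= t`. The AUC is the
#' trapezoidal area under the empirical ROC (equal to the Mann-Whitney
#' statistic with ties counted 1/2); its 95% CI is DeLong's. The optimal
#' threshold maximizes Youden's J = sensitivity + specificity - 1, ties
#' broken toward higher specificity (and then toward the lower threshold).
#' Sensitivity/specificity CIs are Clopper-Pearson exact binomial.
#'
#' @param pairs Data.frame with columns `ffr3d` and `ffr_ref`.
#' @param reference_cutoff Ischemia cutoff on the reference FFR
#'   (default 0.80).
#' @return An object of class `roc_report`: `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `optimal_threshold`, `sensitivity`, `sensitivity_ci`,
#'   `specificity`, `specificity_ci`, `youden`, `reference_cutoff`, `n_pos`,
#'   `n_neg`, and the full `curve` (threshold, sensitivity, specificity).
#' @export
roc_analysis <- function(pairs, reference_cutoff = 0.80) {
  pairs <- check_pairs(pairs, n_min = 2)
  pos <- pairs$ffr_ref <= reference_cutoff
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("no discrimination defined: reference contains a single class",
         call. = FALSE)
  x <- pairs$ffr3d

  thr <- sort(unique(x))
  sens <- vapply(thr, function(t) mean(x[pos] <= t), numeric(1))
  spec <- vapply(thr, function(t) mean(x[!pos] > t), numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)

  # Trapezoid over the full ROC path including the (0,0) and (1,1) corners.
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  # DeLong CI on the same AUC; lower ffr3d predicts the positive class, so
  # controls (non-ischemic) have the higher predictor values.
  roc_obj <- pROC::roc(response = pos, predictor = x,
                       levels = c(FALSE, TRUE), direction = ">",
                       quiet = TRUE)
  # pROC emits an informational warning for degenerate (AUC = 1) curves;
  # the collapsed interval is the correct answer there.
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(roc_obj, method = "delong")))

  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[order(-spec[best], thr[best])][1]

  tp <- round(sens[best] * n_pos)
  tn <- round(spec[best] * n_neg)
  sens_ci <- stats::binom.test(tp, n_pos)$conf.int
  spec_ci <- stats::binom.test(tn, n_neg)$conf.int

  structure(list(auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[3],
                 optimal_threshold = thr[best],
                 sensitivity = sens[best],
                 sensitivity_ci = as.numeric(sens_ci),
                 specificity = spec[best],
                 specificity_ci = as.numeric(spec_ci),
                 youden = j[best],
                 reference_cutoff = reference_cutoff,
                 n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("ROC (reference FFR <= %.2f; %d ischemic / %d non-ischemic)\n",
              x$reference_cutoff, x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci_low, x$auc_ci_high))
  cat(sprintf("  Youden threshold <= %.3f: sens %.1f%% (%.1f-%.1f), spec %.1f%% (%.1f-%.1f)\n",
              x$optimal_threshold,
              100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2],
              100 * x$specificity, 100 * x$specificity_ci[1],
              100 * x$specificity_ci[2]))
  invisible(x)
}

#' Full concordance report for a cohort of FFR pairs
#'
#' Bundles [spearman_concordance()], [compare_means()], [bland_altman()] and
#' summary means into one report.
#'
#' @param pairs Data.frame with columns `ffr3d` and `ffr_ref` (and
#'   optionally `vessel_id`).
#' @return An object of class `concordance_report`.
#' @export
concordance_report <- function(pairs) {
  pairs <- check_pairs(pairs, n_min = 3)
  sp <- spearman_concordance(pairs)
  ba <- bland_altman(pairs)
  p_means <- tryCatch(compare_means(pairs), error = function(e) NA_real_)
  structure(list(n = nrow(pairs),
                 spearman_r = sp$r, spearman_p = sp$p,
                 mean_ffr3d = mean(pairs$ffr3d),
                 sd_ffr3d = stats::sd(pairs$ffr3d),
                 mean_ref = mean(pairs$ffr_ref),
                 sd_ref = stats::sd(pairs$ffr_ref),
                 paired_p = p_means,
                 bias = ba$bias, sd_diff = ba$sd_diff,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 proportional_bias_r = ba$proportional_bias_r,
                 proportional_bias_p = ba$proportional_bias_p),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance over %d vessels\n", x$n))
  cat(sprintf("  FFR estimate %.2f +/- %.2f vs reference %.2f +/- %.2f (paired p = %.2g)\n",
              x$mean_ffr3d, x$sd_ffr3d, x$mean_ref, x$sd_ref, x$paired_p))
  cat(sprintf("  Spearman r = %.2f (p = %.2g)\n", x$spearman_r, x$spearman_p))
  cat(sprintf("  Bland-Altman bias %.3f (LOA %.3f to %.3f); proportional bias r = %.2f (p = %.2g)\n",
              x$bias, x$loa_low, x$loa_high,
              x$proportional_bias_r, x$proportional_bias_p))
  invisible(x)
}
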