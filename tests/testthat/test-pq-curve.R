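# Replicate averaging, constrained quadratic fitting, ratio uncertainty.

test_that("replicate averaging reproduces hand arithmetic", {
  # setpoint 1 carries dP replicates {9, 10, 11}: mean 10, sd 1
  mk <- function(rep, pd1) data.frame(
    vessel_id = "v1", replicate = rep, q = c(50, 100, 150),
    p_a = 90, p_d = c(pd1, 80, 70))
  d <- pf_dataset(rbind(mk(1, 81), mk(2, 80), mk(3, 79)))
  avg <- average_replicates(d)
  expect_equal(nrow(avg), 3)
  expect_equal(avg$dp[1], 10)
  expect_equal(avg$sd_dp[1], 1)
  expect_equal(avg$sd_dp[2:3], c(0, 0))
  # identical replicates collapse to any single replicate with sd 0
  d_id <- pf_dataset(rbind(mk(1, 80), mk(2, 80), mk(3, 80)))
  avg_id <- average_replicates(d_id)
  expect_equal(avg_id$q, c(50, 100, 150))
  expect_true(all(avg_id$sd_dp == 0))
})

test_that("averaging enforces dataset structure", {
  base <- data.frame(vessel_id = "v1", replicate = 1, q = c(50, 100, 150),
                     p_a = 90, p_d = c(85, 80, 70))
  # unequal replicate record counts
  expect_error(pf_dataset(rbind(base, base[1:2, ] |>
                                  transform(replicate = 2))),
               "structural error")
  # a single setpoint cannot characterize a curve
  one <- data.frame(vessel_id = "v1", replicate = 1:3, q = 100,
                    p_a = 90, p_d = 80)
  expect_error(average_replicates(pf_dataset(one)), "structural error")
  # p_d above p_a beyond 1% of p_a is rejected with a warning
  noisy <- base
  noisy$p_d[1] <- 92
  d <- pf_dataset(rbind(noisy, transform(base, replicate = 2),
                        transform(base, replicate = 3)))
  expect_warning(avg <- average_replicates(d), "rejected 1 record")
  expect_equal(avg$n_rep, c(2, 3, 3))
})

test_that("noise-free quadratic data are fitted exactly", {
  for (co in list(c(0.05, 0.002), c(0.3, 0.001), c(0.02, 0))) {
    d <- exact_dataset(co[1], co[2], p_a = 95)
    fit <- fit_pq_curve(average_replicates(d))
    expect_equal(fit$a, co[1], tolerance = 1e-9)
    expect_equal(fit$b, co[2], tolerance = 1e-9)
    # machine-level residuals on realizable data
    expect_lt(fit$rmse, 1e-9)
  }
  # pure linear law: b clamped or estimated at 0
  d <- exact_dataset(0.1, 0, p_a = 90)
  fit <- fit_pq_curve(average_replicates(d))
  expect_equal(fit$b, 0, tolerance = 1e-12)
  expect_equal(fit$a, 0.1, tolerance = 1e-9)
})

test_that("non-negativity is enforced by clamp-and-refit", {
  # concave points would pull b negative; the constrained fit clamps it
  pts <- data.frame(q = c(50, 100, 150, 200),
                    dp = c(6, 10.5, 13.5, 15.5))
  fit <- fit_pq_curve(pts)
  expect_gte(fit$a, 0)
  expect_gte(fit$b, 0)
  expect_true("b" %in% fit$clamped)
  # clamped fit must not beat the interior optimum on feasible data
  pts2 <- data.frame(q = c(50, 100, 150, 200),
                     dp = 0.05 * c(50, 100, 150, 200) +
                          0.002 * c(50, 100, 150, 200)^2)
  expect_length(fit_pq_curve(pts2)$clamped, 0)
  expect_error(fit_pq_curve(data.frame(q = c(100, 100, 100),
                                       dp = c(10, 10, 10))),
               "rank-deficient")
})

test_that("stenosis resistance is non-negative and non-decreasing", {
  d <- exact_dataset(0.05, 0.002, p_a = 95)
  fit <- fit_pq_curve(average_replicates(d))
  q <- seq(0, 300, by = 10)
  rp <- stenosis_resistance(fit, q)
  expect_true(all(rp >= 0))
  expect_true(all(diff(rp) >= 0))
})

test_that("fit covariance shrinks with replication", {
  v <- synthetic_vessel("v", vessel_geometry(3, 60, 20), 90)
  var_b <- vapply(c(3, 12), function(nrep) {
    vb <- vapply(1:60, function(s) {
      d <- simulate_measurements(v, n_replicates = nrep, seed = s)
      fit_pq_curve(average_replicates(d))$covariance["b", "b"]
    }, numeric(1))
    median(vb)
  }, numeric(1))
  # quadrupling the replicates should shrink the variance about 4-fold
  expect_equal(var_b[1] / var_b[2], 4, tolerance = 0.5)
})

test_that("ratio uncertainties follow first-order propagation", {
  pts <- data.frame(q = c(50, 100, 150), p_a = 90, p_d = c(85, 78, 66))
  # zero sensor noise: zero ratio uncertainty
  u0 <- propagate_uncertainty(pts, noise_model(0, 0))
  expect_true(all(u0$pressure_ratio_rel_sd == 0))
  expect_true(all(u0$flow_ratio_rel_sd == 0))
  # 0.5%/0.5% -> pressure-ratio rel sd sqrt(2)*0.5% ~ 0.71%, under 1%
  u <- propagate_uncertainty(pts, noise_model(0.005, 0.005))
  expect_equal(u$pressure_ratio_rel_sd[1], sqrt(2) * 0.005)
  expect_lt(max(u$pressure_ratio_rel_sd), 0.01)
  expect_equal(u$flow_ratio[2], 2)  # 100 / q_rest 50
  expect_error(propagate_uncertainty(transform(pts, p_d = 0),
                                     noise_model()), "pressures")
})

test_that("first-order pressure-ratio uncertainty agrees with Monte-Carlo", {
  set.seed(81)
  n <- 1e5
  pa <- 90 * (1 + rnorm(n, 0, 0.005))
  pd <- 70 * (1 + rnorm(n, 0, 0.005))
  mc <- sd(pd / pa) / mean(pd / pa)
  expect_equal(mc, sqrt(2) * 0.005, tolerance = 0.05)
})
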