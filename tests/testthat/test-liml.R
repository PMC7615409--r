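make_dataset <- function(truth, n = 5000, seed = 1) {
  draw_summary_stats(truth, n, n, seed = seed)
}

test_that("build_moment_system computes variance components and clips", {
  p <- 30; r <- 2
  truth <- synth_region(p = p, r = r, seed = 12)
  varz <- structure(list(variant_ids = paste0("v", 1:p),
                         matrix = truth$var_z), class = "fmr_varz")
  loadings <- estimate_loadings(varz, r)

  # delta_x = 0: sigma_V^2 = var(X) exactly
  ds0 <- factormr:::new_summary_dataset(paste0("v", 1:p), numeric(p),
                                        truth$delta_y, 1000, 1000, 1, 1,
                                        truth$variant_variances)
  ms0 <- build_moment_system(ds0, loadings, varz)
  expect_equal(ms0$sigma_v2, 1)
  expect_equal(ms0$G_hat, numeric(r))

  # quadratic form exhausting var(X): clipped at the floor with a warning
  mx_target <- drop(crossprod(loadings$loadings, truth$delta_x))
  om <- factor_moments(loadings, varz)$omega0
  scale <- sqrt(1 / drop(crossprod(mx_target, solve(om, mx_target))))
  ds1 <- factormr:::new_summary_dataset(paste0("v", 1:p),
                                        truth$delta_x * scale * 1.01,
                                        truth$delta_y, 1000, 1000, 1, 1,
                                        truth$variant_variances)
  expect_warning(ms1 <- build_moment_system(ds1, loadings, varz),
                 "clipped")
  expect_equal(ms1$sigma_v2, 1e-10)

  # solver-vs-inverse oracle on a random instance
  truth5 <- synth_region(p = 30, r = 3, seed = 5)
  n5 <- calibrate_n(truth5, 20)
  data5 <- draw_summary_stats(truth5, n5, n5, seed = 6)
  ld5 <- ld_matrix(paste0("v", 1:30), truth5$rho)
  varz5 <- build_variant_covariance(ld5, noisy_variant_variances(truth5, n5,
                                                                 5))
  load5 <- estimate_loadings(varz5, 3)
  ms5 <- build_moment_system(data5, load5, varz5)
  mx <- -ms5$G_hat
  oracle <- 1 - drop(t(mx) %*% solve(ms5$omega0) %*% mx)
  expect_equal(ms5$sigma_v2, oracle, tolerance = 1e-10)
})

test_that("moment_covariance is the stated scalar multiple of omega0", {
  ms <- random_moment_system(2, r = 3)
  expect_equal(moment_covariance(0, ms),
               ms$omega0 * ms$sigma_e2 / ms$n_y)
  expect_equal(moment_covariance(0.7, ms), moment_covariance(-0.7, ms))
  ms$n_x <- ms$n_y <- 1000L
  expect_equal(moment_covariance(1, ms),
               ms$omega0 * (ms$sigma_e2 + ms$sigma_v2) / 1000)
})

test_that("fit_fliml recovers exact proportionality and the GLS slope", {
  # delta_y = theta0 * delta_x exactly: objective 0 at theta0
  ms <- random_moment_system(9, r = 4)
  theta0 <- 0.42
  ms$g_y <- -theta0 * ms$G_hat   # g(theta0) = g_y + theta0 G = 0
  fit <- fit_fliml(ms)
  expect_equal(fit$theta, theta0, tolerance = 1e-10)
  expect_equal(fit$objective_at_min, 0, tolerance = 1e-12)
  expect_true(fit$ci_low <= fit$theta && fit$theta <= fit$ci_high)

  # sigma_v2 -> 0: weighting no longer depends on theta, GLS slope -b/a
  ms2 <- random_moment_system(10, r = 3)
  ms2$sigma_v2 <- 1e-12
  cf <- factormr:::objective_coefs(ms2)
  fit2 <- fit_fliml(ms2)
  expect_equal(fit2$theta, -cf$b / cf$a, tolerance = 1e-6)
})

test_that("fit_fliml agrees with a dense grid oracle", {
  for (seed in c(1, 7, 23)) {
    ms <- random_moment_system(seed, r = sample(2:5, 1))
    fit <- fit_fliml(ms)
    coarse <- seq(-50, 50, length.out = 100001L)
    qc <- factormr:::liml_objective(coarse, ms)
    c0 <- coarse[which.min(qc)]
    fine <- seq(c0 - 0.01, c0 + 0.01, length.out = 200001L)
    oracle <- fine[which.min(factormr:::liml_objective(fine, ms))]
    expect_equal(fit$theta, oracle, tolerance = 1e-4)
  }
})

test_that("fit_fliml is scale-equivariant and objective is non-negative", {
  truth <- synth_region(p = 30, r = 3, seed = 14, theta0 = 0.2)
  n <- calibrate_n(truth, 30)
  data <- make_dataset(truth, n, seed = 3)
  varz <- structure(list(variant_ids = data$variant_ids,
                         matrix = truth$var_z), class = "fmr_varz")
  loadings <- estimate_loadings(varz, 3)
  ms <- build_moment_system(data, loadings, varz)
  fit <- fit_fliml(ms)

  kappa <- 3.7
  data_k <- data
  data_k$delta_x <- data$delta_x * kappa
  data_k$delta_y <- data$delta_y * kappa
  data_k$var_x <- data$var_x * kappa^2
  data_k$var_y <- data$var_y * kappa^2
  fit_k <- fit_fliml(build_moment_system(data_k, loadings, varz))
  expect_equal(fit_k$theta, fit$theta, tolerance = 1e-10)
  expect_gte(fit$objective_at_min, 0)
})

test_that("Wald coverage under strong factors is near nominal", {
  truth <- synth_region(p = 40, r = 3, seed = 77, theta0 = 0.3)
  n <- calibrate_n(truth, 50)
  varz <- structure(list(variant_ids = paste0("v", 1:40),
                         matrix = truth$var_z), class = "fmr_varz")
  loadings <- estimate_loadings(varz, 3)
  cover <- vapply(1:1000, function(b) {
    d <- draw_summary_stats(truth, n, n, seed = 1000 + b)
    fit <- fit_fliml(suppressWarnings(build_moment_system(d, loadings, varz)))
    fit$ci_low <= 0.3 && 0.3 <= fit$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.93)
  expect_lt(mean(cover), 0.97)
})

test_that("sargan_hansen diagnostics behave at and away from the minimizer", {
  ms <- random_moment_system(15, r = 4)
  theta0 <- 0.21
  ms$g_y <- -theta0 * ms$G_hat
  sh <- sargan_hansen(theta0, ms)
  expect_equal(sh$statistic, 0, tolerance = 1e-12)
  expect_equal(sh$p_value, 1)

  ms2 <- random_moment_system(16, r = 5)
  fit <- fit_fliml(ms2)
  stat_min <- sargan_hansen(fit$theta, ms2)$statistic
  for (t in c(-1, 0, 0.5, 2)) {
    expect_gte(sargan_hansen(t, ms2)$statistic, stat_min - 1e-10)
  }
  # substituted-value convention uses df = r
  expect_equal(sargan_hansen(0.5, ms2, df = ms2$r)$null_law, "chi2_5")
})

test_that("sargan_hansen null rejection rate is calibrated", {
  truth <- synth_region(p = 40, r = 5, seed = 31, theta0 = 0.1)
  n <- calibrate_n(truth, 20)
  varz <- structure(list(variant_ids = paste0("v", 1:40),
                         matrix = truth$var_z), class = "fmr_varz")
  loadings <- estimate_loadings(varz, 5)
  rej <- vapply(1:2000, function(b) {
    d <- draw_summary_stats(truth, n, n, seed = 5000 + b)
    ms <- suppressWarnings(build_moment_system(d, loadings, varz))
    sargan_hansen(fit_fliml(ms)$theta, ms)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("factor F-statistic has the stated functional form", {
  ms <- random_moment_system(18, r = 3)
  ms$G_hat <- numeric(3)
  expect_equal(factor_f_statistic(ms), 1)

  ms2 <- random_moment_system(19, r = 3)
  f1 <- factor_f_statistic(ms2)
  ms2$n_x <- 2L * ms2$n_x
  expect_equal(factor_f_statistic(ms2) - 1, 2 * (f1 - 1), tolerance = 1e-12)
})

test_that("factor F-statistic tracks the individual-level regression F", {
  # individual-level oracle: regress X on the true factor scores
  set.seed(55)
  n <- 5e4; p <- 20; r <- 2
  truth <- synth_region(p = p, r = r, seed = 55, genetic_var_x = 0.004)
  lam_c <- truth$loadings / sqrt(truth$variant_variances)  # correlation scale
  f <- matrix(rnorm(n * r), n)
  e <- matrix(rnorm(n * p), n) %*% diag(truth$idio_sd /
                                          sqrt(truth$variant_variances))
  z <- (f %*% t(lam_c) + e) %*% diag(sqrt(truth$variant_variances))
  # X = eta' f + v with delta_x = Lambda eta implied by the truth
  eta <- drop(solve(crossprod(truth$loadings),
                    crossprod(truth$loadings, truth$delta_x)))
  gvar <- drop(crossprod(eta))  # var of eta'f with Sigma_F = I
  x <- drop(f %*% eta) + rnorm(n, sd = sqrt(1 - gvar))
  fs <- z %*% truth$loadings
  ols <- summary(lm(x ~ fs))
  f_oracle <- unname(ols$fstatistic[1])

  ds <- factormr:::new_summary_dataset(paste0("v", 1:p),
                                       drop(crossprod(z, x)) / n,
                                       truth$delta_y, n, n, 1, 1,
                                       truth$variant_variances)
  varz <- structure(list(variant_ids = paste0("v", 1:p),
                         matrix = truth$var_z), class = "fmr_varz")
  ms <- build_moment_system(ds, estimate_loadings(varz, r), varz)
  expect_equal(factor_f_statistic(ms), f_oracle, tolerance = 0.15)
})
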