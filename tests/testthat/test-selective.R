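test_that("pretest_factors screens on |t| with a strict threshold", {
  ms <- random_moment_system(7, r = 3)
  # engineer t-stats (3, 1, -4): G_hat = t * sqrt(diag(D_GG))
  d <- sqrt(diag(ms$omega0 * ms$sigma_v2 / ms$n_x))
  ms$G_hat <- c(3, 1, -4) * d
  sel <- pretest_factors(ms, nu = 0.05)
  expect_equal(sel$selected, c(1L, 3L))
  expect_equal(sel$threshold, qnorm(0.975))
  expect_equal(sel$r_star, 2L)
  expect_equal(dim(sel$selection_matrix), c(3L, 2L))
  expect_equal(sel$selection_matrix[cbind(c(1, 3), c(1, 2))], c(1, 1))

  # boundary |t| = c counts as NOT selected
  ms$G_hat <- c(qnorm(0.975), 3, 0) * d
  sel_b <- pretest_factors(ms, nu = 0.05)
  expect_equal(sel_b$selected, 2L)

  # nu near 1: threshold ~ 0, everything (nonzero) selected
  ms2 <- random_moment_system(8, r = 4)
  expect_equal(pretest_factors(ms2, nu = 0.9999)$r_star, 4L)

  # G = 0: nothing relevant, informative error
  ms3 <- random_moment_system(9, r = 3)
  ms3$G_hat <- numeric(3)
  expect_error(pretest_factors(ms3, nu = 0.05), "no relevant factors")
})

test_that("fit_sliml reduces to F-LIML under full selection", {
  ms <- pipeline_moment_system(13, p = 40, r = 3, f_target = 40,
                               theta0 = 0.2)
  sel_all <- pretest_factors(ms, nu = 0.9999)
  expect_equal(sel_all$r_star, ms$r)
  fit_s <- fit_sliml(ms, sel_all)
  fit_f <- fit_fliml(ms)
  expect_equal(fit_s$theta_s, fit_f$theta, tolerance = 1e-10)
  expect_equal(fit_s$v_s, fit_f$variance, tolerance = 1e-10)
})

test_that("single-factor S-LIML equals the just-identified ratio", {
  ms <- random_moment_system(14, r = 4)
  d <- sqrt(diag(ms$omega0 * ms$sigma_v2 / ms$n_x))
  ms$G_hat <- c(6, 0.1, -0.1, 0.05) * d   # only factor 1 passes
  sel <- pretest_factors(ms, nu = 0.01)
  expect_equal(sel$selected, 1L)
  fit <- fit_sliml(ms, sel)
  # g_j(theta) = g_y_j + theta G_j = 0  =>  theta = -g_y_j / G_j
  expect_equal(fit$theta_s, -ms$g_y[1] / ms$G_hat[1], tolerance = 1e-8)
  expect_equal(fit$objective_at_min, 0, tolerance = 1e-10)
})

test_that("conditional test reduces to Wald when selection is ignorable", {
  # c_g = 0: truncation never binds, quantiles are theta0 +/- z sqrt(v_s)
  fit <- structure(list(theta_s = 0.1, v_s = 0.04, se = 0.2,
                        c_g = rep(0, 3), d_diag = rep(1, 3),
                        u = c(3, -4, 5),
                        selection = structure(list(
                          t_stats = c(3, -4, 5), threshold = qnorm(0.995),
                          nu = 0.01, selected = 1:3,
                          selection_matrix = diag(3), r_star = 3L),
                          class = "fmr_selection"),
                        alpha = 0.05),
                   class = "fmr_sliml")
  ct <- conditional_test(0.3, fit, n_draws = 2e5, seed = 10)
  expect_equal(ct$acceptance_prob, 1)
  expect_equal(ct$n_kept, ct$n_draws)
  z <- qnorm(0.975) * 0.2
  expect_lt(abs(ct$lower_q - (0.3 - z)), 0.01)
  expect_lt(abs(ct$upper_q - (0.3 + z)), 0.01)
  expect_false(ct$reject)   # 0.1 inside [0.3 - 0.39, 0.3 + 0.39]

  # determinism: identical seed, identical result
  ct2 <- conditional_test(0.3, fit, n_draws = 2e5, seed = 10)
  expect_identical(ct, ct2)
})

test_that("conditional quantiles match a joint-Gaussian rejection sampler", {
  # 2-factor toy with known (c_g, v_s, u); factor 1 selected, factor 2 not
  v_s <- 0.5
  c_g <- c(0.4, -0.3)
  thr <- qnorm(0.975)
  u_obs <- c(2.4, 0.3)
  theta0 <- 0.2
  fit <- structure(list(theta_s = 0.3, v_s = v_s, se = sqrt(v_s),
                        c_g = c_g, d_diag = c(1, 1), u = u_obs,
                        selection = structure(list(
                          t_stats = c(2.8, 0.5), threshold = thr, nu = 0.05,
                          selected = 1L,
                          selection_matrix = matrix(c(1, 0), 2),
                          r_star = 1L), class = "fmr_selection"),
                        alpha = 0.05),
                   class = "fmr_sliml")
  ct <- conditional_test(theta0, fit, n_draws = 4e5, seed = 3)

  # oracle: draw (theta, T) from the joint Gaussian, window-condition on
  # U = T - c_g theta / v_s near u_obs, apply the selection event to T
  set.seed(1234)
  n_o <- 4e6
  v_g <- diag(2)
  sigma <- rbind(c(v_s, c_g), cbind(c_g, v_g))
  mu <- c(theta0, u_obs + c_g * theta0 / v_s)  # U centered at u_obs
  ch <- chol(sigma)
  draws <- matrix(rnorm(n_o * 3), n_o) %*% ch
  draws <- sweep(draws, 2, mu, "+")
  th <- draws[, 1]; tt <- draws[, 2:3]
  u_draw <- tt - outer(th, c_g / v_s)
  h <- 0.05
  keep <- abs(u_draw[, 1] - u_obs[1]) < h & abs(u_draw[, 2] - u_obs[2]) < h &
    abs(tt[, 1]) > thr & abs(tt[, 2]) <= thr
  expect_gt(sum(keep), 3000)
  th_k <- th[keep]
  for (pr in c(0.025, 0.975)) {
    q_o <- quantile(th_k, pr, names = FALSE)
    dens <- density(th_k)
    f_q <- approx(dens$x, dens$y, xout = q_o)$y
    se_o <- sqrt(pr * (1 - pr) / length(th_k)) / f_q
    q_i <- if (pr < 0.5) ct$lower_q else ct$upper_q
    expect_lt(abs(q_i - q_o), 3 * se_o + 0.01)
  }
})

test_that("selective CI nests across levels and covers the estimate", {
  ms <- pipeline_moment_system(17, p = 40, r = 4, f_target = 20,
                               theta0 = 0.25)
  sel <- pretest_factors(ms, nu = 0.05)
  fit <- fit_sliml(ms, sel)
  ci05 <- selective_ci(fit, alpha = 0.05, n_draws = 2e4, seed = 5,
                       resolution = 101L)
  ci01 <- selective_ci(fit, alpha = 0.01, n_draws = 2e4, seed = 5,
                       bracket = ci05$bracket, resolution = 101L)
  expect_gte(nrow(ci05$intervals), 1)
  # 95% CI inside 99% CI under common random numbers
  expect_gte(ci05$intervals[1, 1], ci01$intervals[1, 1] - 1e-6)
  expect_lte(ci05$intervals[nrow(ci05$intervals), 2],
             ci01$intervals[nrow(ci01$intervals), 2] + 1e-6)
  # contains the point estimate
  expect_true(any(ci05$intervals[, 1] <= fit$theta_s &
                    fit$theta_s <= ci05$intervals[, 2]))
})

test_that("selective CI matches the Wald interval when c_g = 0", {
  fit <- structure(list(theta_s = 0.15, v_s = 0.01, se = 0.1,
                        c_g = rep(0, 2), d_diag = rep(1, 2), u = c(4, -5),
                        selection = structure(list(
                          t_stats = c(4, -5), threshold = qnorm(0.995),
                          nu = 0.01, selected = 1:2,
                          selection_matrix = diag(2), r_star = 2L),
                          class = "fmr_selection"),
                        alpha = 0.05),
                   class = "fmr_sliml")
  ci <- selective_ci(fit, alpha = 0.05, n_draws = 1e5, seed = 2,
                     resolution = 201L)
  z <- qnorm(0.975) * 0.1
  expect_lt(abs(unname(ci$intervals[1, 1]) - (0.15 - z)), 0.02)
  expect_lt(abs(unname(ci$intervals[1, 2]) - (0.15 + z)), 0.02)
})

test_that("selective type I error is controlled on pipeline data", {
  # mixture of strong and weak factors, nu = 0.05 (F = 5 per the adaptive
  # rule); size measured conditional on selection, true theta0 nonzero so
  # the selection/estimate dependence (c_g != 0) is active
  theta0 <- 0.2
  truth <- synth_region(p = 60, r = 5, seed = 23, theta0 = theta0)
  n <- calibrate_n(truth, 5)
  ld <- ld_matrix(paste0("v", 1:60), truth$rho)
  rej_cond <- logical(0)
  for (b in 1:600) {
    res <- tryCatch(suppressWarnings({
      vhat <- noisy_variant_variances(truth, n, seed = 40000 + b)
      varz <- build_variant_covariance(ld, vhat)
      loadings <- estimate_loadings(varz, 5)
      d <- draw_summary_stats(truth, n, n, seed = 60000 + b)
      ms <- build_moment_system(d, loadings, varz)
      sel <- pretest_factors(ms, nu = 0.05)
      fit <- fit_sliml(ms, sel)
      conditional_test(theta0, fit, n_draws = 2e4, seed = 80000 + b)$reject
    }), error = function(e) NULL)
    if (!is.null(res)) rej_cond <- c(rej_cond, res)
  }
  expect_gt(length(rej_cond), 300)
  expect_gt(mean(rej_cond), 0.03)
  expect_lt(mean(rej_cond), 0.07)
})

test_that("conditional test stays calibrated where naive Wald inflates", {
  # exact joint-Gaussian winner's-curse regime: a borderline-relevant factor
  # (pre-test mean 1.0 against threshold 1.96) strongly correlated with the
  # estimate. Selection truncates the lower tail, so the unadjusted Wald
  # test over-rejects while the conditional test holds its level.
  set.seed(99)
  v_s <- 0.25; c_g <- c(0.8 * 0.5, 0); thr <- qnorm(0.975); theta0 <- 0.2
  mu_t <- c(1.0, 0.3)
  sigma <- rbind(c(v_s, c_g), cbind(c_g, diag(2)))
  ch <- chol(sigma)
  rej_cond <- rej_naive <- logical(0)
  for (b in 1:1000) {
    repeat {
      d <- drop(crossprod(ch, rnorm(3))) + c(theta0, mu_t)
      if (abs(d[2]) > thr && abs(d[3]) <= thr) break
    }
    th <- d[1]; tt <- d[2:3]
    fit <- structure(list(theta_s = th, v_s = v_s, se = sqrt(v_s),
                          c_g = c_g, d_diag = c(1, 1),
                          u = tt - c_g * th / v_s,
                          selection = structure(list(
                            t_stats = tt, threshold = thr, nu = 0.05,
                            selected = 1L,
                            selection_matrix = matrix(c(1, 0), 2),
                            r_star = 1L), class = "fmr_selection"),
                          alpha = 0.05),
                     class = "fmr_sliml")
    ct <- tryCatch(conditional_test(theta0, fit, n_draws = 2e4, seed = b),
                   error = function(e) NULL)
    if (is.null(ct)) next
    rej_cond <- c(rej_cond, ct$reject)
    rej_naive <- c(rej_naive, abs(th - theta0) > qnorm(0.975) * sqrt(v_s))
  }
  expect_gt(mean(rej_cond), 0.03)
  expect_lt(mean(rej_cond), 0.07)
  expect_gt(mean(rej_naive), 0.07)   # naive Wald-after-selection inflates
  expect_gt(mean(rej_naive), mean(rej_cond))
})
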