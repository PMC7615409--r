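#' Build the factor-level moment system
#'
#' Projects the covariance-scale associations onto the estimated factors and
#' computes the variance components needed by all estimators and tests:
#' \itemize{
#'   \item g(theta) = t(Lambda_hat) (delta_y - delta_x * theta) =
#'     `g_y + theta * G_hat`, with `G_hat = -t(Lambda_hat) delta_x`;
#'   \item `omega0` = t(Lambda_hat) var(Z) Lambda_hat;
#'   \item `sigma_v2` = var(X) - q_x and `sigma_e2` = var(Y) - q_y, where
#'     q_x, q_y are the omega0-weighted quadratic forms of the projected
#'     associations.
#' }
#' Negative plug-in variance components are clipped at
#' `1e-10 * var(trait)` with a warning.
#'
#' @param data An `fmr_dataset`.
#' @param loadings An `fmr_loadings` with the same p.
#' @param varz The `fmr_varz` used to estimate the loadings.
#' @return Object of class `fmr_moment_system`.
#' @export
build_moment_system <- function(data, loadings, varz) {
  stopifnot(inherits(data, "fmr_dataset"), inherits(loadings, "fmr_loadings"))
  lam <- loadings$loadings
  p <- nrow(lam)
  stopifnot(length(data$delta_x) == p)
  omega0 <- factor_moments(loadings, varz)$omega0
  r <- ncol(lam)
  kappa <- tryCatch(kappa(omega0, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e12) {
    stop("Omega0 is (near-)singular; reduce the number of factors r",
         call. = FALSE)
  }
  mx <- drop(crossprod(lam, data$delta_x))  # t(Lambda) delta_x
  my <- drop(crossprod(lam, data$delta_y))
  qx <- drop(crossprod(mx, solve(omega0, mx)))
  qy <- drop(crossprod(my, solve(omega0, my)))
  clip <- function(val, trait_var, label) {
    floor_val <- 1e-10 * trait_var
    if (val < floor_val) {
      warning("estimated ", label, " is not positive (", format(val),
              "); clipped at ", format(floor_val), call. = FALSE)
      floor_val
    } else val
  }
  structure(list(g_y = my, G_hat = -mx, omega0 = omega0,
                 sigma_v2 = clip(data$var_x - qx, data$var_x, "sigma_V^2"),
                 sigma_e2 = clip(data$var_y - qy, data$var_y, "sigma_eps^2"),
                 n_x = data$n_x, n_y = data$n_y, r = as.integer(r),
                 var_x = data$var_x, var_y = data$var_y),
            class = "fmr_moment_system")
}

#' @export
print.fmr_moment_system <- function(x, ...) {
  cat("factor moment system: r =", x$r,
      " sigma_V^2 =", format(x$sigma_v2),
      " sigma_eps^2 =", format(x$sigma_e2), "\n")
  invisible(x)
}

# g(theta) = g_y + theta * G_hat
moment_value <- function(theta, ms) ms$g_y + theta * ms$G_hat

# scalar multiplier s(theta) with Omega(theta) = omega0 * s(theta)
moment_scalar <- function(theta, ms) {
  ms$sigma_e2 / ms$n_y + theta^2 * ms$sigma_v2 / ms$n_x
}

#' Variance of the moment vector at a hypothesized effect
#'
#' Omega(theta) = omega0 * (sigma_e2 / n_y + theta^2 sigma_v2 / n_x):
#' a scalar multiple of the factor covariance.
#'
#' @param theta Hypothesized causal effect.
#' @param ms An `fmr_moment_system`.
#' @return r x r symmetric PSD matrix.
#' @export
moment_covariance <- function(theta, ms) {
  s <- moment_scalar(theta, ms)
  if (s <= 0) stop("zero moment variance: both variance components vanish",
                   call. = FALSE)
  ms$omega0 * s
}

# quadratic-form coefficients of the LIML objective:
# g(theta)' omega0^-1 g(theta) = a theta^2 + 2 b theta + c
objective_coefs <- function(ms) {
  sol_g <- solve(ms$omega0, ms$G_hat)
  list(a = drop(crossprod(ms$G_hat, sol_g)),
       b = drop(crossprod(ms$g_y, sol_g)),
       c = drop(crossprod(ms$g_y, solve(ms$omega0, ms$g_y))))
}

# Q(theta) = g' Omega(theta)^-1 g, vectorized over theta
liml_objective <- function(theta, ms, coefs = objective_coefs(ms)) {
  num <- coefs$a * theta^2 + 2 * coefs$b * theta + coefs$c
  den <- ms$sigma_e2 / ms$n_y + theta^2 * ms$sigma_v2 / ms$n_x
  num / den
}

#' Factor-LIML point estimation with Wald inference
#'
#' Minimizes Q(theta) = g(theta)' Omega(theta)^-1 g(theta). Because
#' Omega(theta) is a scalar multiple of omega0, Q is a ratio of quadratics in
#' theta and the first-order condition is a quadratic equation solved in
#' closed form; of its real roots the one with the smaller objective value is
#' the minimizer. A dense grid search is used as fallback if the quadratic
#' degenerates. The Wald variance is V = (G' Omega(theta_hat)^-1 G)^-1.
#'
#' @param ms An `fmr_moment_system`.
#' @param alpha Two-sided level for the confidence interval (default 0.05).
#' @return Object of class `fmr_fliml`: `theta`, `variance`, `se`,
#'   `ci_low`, `ci_high`, `objective_at_min`, plus `alpha`.
#' @export
fit_fliml <- function(ms, alpha = 0.05) {
  stopifnot(inherits(ms, "fmr_moment_system"), alpha > 0, alpha < 1)
  cf <- objective_coefs(ms)
  de <- ms$sigma_e2 / ms$n_y
  dv <- ms$sigma_v2 / ms$n_x
  # d/dtheta [ (a t^2 + 2 b t + c) / (de + dv t^2) ] = 0
  #   <=>  b dv t^2 - (a de - c dv) t - b de = 0
  A <- cf$b * dv
  B <- -(cf$a * de - cf$c * dv)
  C <- -cf$b * de
  roots <- numeric(0)
  if (abs(A) > 1e-14 * max(abs(B), abs(C), 1)) {
    disc <- B^2 - 4 * A * C
    if (disc >= 0) roots <- (-B + c(1, -1) * sqrt(disc)) / (2 * A)
  } else if (abs(B) > 0) {
    roots <- -C / B
  }
  if (length(roots) == 0) {
    # degenerate coefficients (e.g. b = 0): fall back to a bracketed grid
    if (cf$a <= 0) stop("degenerate LIML objective: no real minimizer",
                        call. = FALSE)
    span <- 10 * (1 + sqrt(cf$c / cf$a))
    grid <- seq(-span, span, length.out = 200001L)
    roots <- grid[which.min(liml_objective(grid, ms, cf))]
  }
  obj <- liml_objective(roots, ms, cf)
  theta <- roots[which.min(obj)]
  variance <- moment_scalar(theta, ms) / cf$a
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(theta = theta, variance = variance, se = sqrt(variance),
                 ci_low = theta - z * sqrt(variance),
                 ci_high = theta + z * sqrt(variance),
                 objective_at_min = max(min(obj), 0), alpha = alpha),
            class = "fmr_fliml")
}

#' @export
print.fmr_fliml <- function(x, ...) {
  cat(sprintf("F-LIML estimate: theta = %.4f (se %.4f), %d%% CI [%.4f, %.4f]\n",
              x$theta, x$se, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high))
  invisible(x)
}

#' Sargan-Hansen heterogeneity (over-identification) test
#'
#' Evaluates the moment quadratic form Q(theta) at `theta_eval` and refers it
#' to a chi-square upper tail. At the F-LIML minimizer one degree of freedom
#' is absorbed by estimation (df = r - 1); when `theta_eval` is a substituted
#' value, e.g. the midpoint of a robust confidence interval for methods that
#' provide no point estimate, no parameter is estimated and df = r. Both
#' conventions are available through `df`.
#'
#' @param theta_eval Effect value at which the statistic is evaluated.
#' @param ms An `fmr_moment_system` (needs r >= 2 for a meaningful test).
#' @param df Degrees of freedom; default `ms$r - 1`, use `ms$r` for a
#'   substituted (non-estimated) `theta_eval`.
#' @return Object of class `fmr_test` with `statistic`, `p_value`,
#'   `null_law` and `theta0 = theta_eval`.
#' @export
sargan_hansen <- function(theta_eval, ms, df = ms$r - 1L) {
  stopifnot(inherits(ms, "fmr_moment_system"), df >= 1)
  stat <- liml_objective(theta_eval, ms)
  new_fmr_test(statistic = stat,
               p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
               null_law = sprintf("chi2_%d", df), theta0 = theta_eval,
               method = "Sargan-Hansen")
}

#' First-stage F-statistic of the estimated factors
#'
#' Aggregate instrument strength of the estimated factors for the exposure,
#' in the expected-first-stage-F form
#' F = 1 + n_x * (Lambda' delta_x)' omega0^-1 (Lambda' delta_x) / (r sigma_v2),
#' i.e. 1 + concentration parameter / r.
#'
#' @param ms An `fmr_moment_system`.
#' @param r Number of instruments; defaults to `ms$r`.
#' @return Scalar F >= 1.
#' @export
factor_f_statistic <- function(ms, r = ms$r) {
  if (ms$sigma_v2 <= 1.5e-10 * ms$var_x) {
    warning("sigma_V^2 at clip floor; F-statistic unreliable", call. = FALSE)
  }
  a <- drop(crossprod(ms$G_hat, solve(ms$omega0, ms$G_hat)))
  1 + ms$n_x * a / (r * ms$sigma_v2)
}

# shared constructor for simple test results
new_fmr_test <- function(statistic, p_value, null_law, theta0, method) {
  structure(list(statistic = statistic,
                 p_value = min(max(p_value, 0), 1),
                 null_law = null_law, theta0 = theta0, method = method),
            class = "fmr_test")
}

#' @export
print.fmr_test <- function(x, ...) {
  cat(sprintf("%s test at theta0 = %.4f: statistic = %.4f, p = %.4g (%s)\n",
              x$method, x$theta0, x$statistic, x$p_value, x$null_law))
  invisible(x)
}
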