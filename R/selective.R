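#' Pre-test estimated factors for relevance
#'
#' Screens each estimated factor j with the t-statistic
#' `T_j = G_hat_j / sqrt((D_GG)_jj)`, `D_GG = omega0 * sigma_v2 / n_x`,
#' against the two-sided normal critical value `c_nu = qnorm(1 - nu/2)`.
#' Factors with `|T_j| > c_nu` (strictly) are selected as instruments;
#' a boundary value counts as not selected.
#'
#' @param ms An `fmr_moment_system`.
#' @param nu Pre-test level in (0, 1); default 0.01.
#' @return Object of class `fmr_selection`: `t_stats`, `threshold`, `nu`,
#'   `selected` (ordered indices), `selection_matrix` (r x r* 0/1), `r_star`.
#'   Errors when no factor passes.
#' @export
pretest_factors <- function(ms, nu = 0.01) {
  stopifnot(inherits(ms, "fmr_moment_system"), nu > 0, nu < 1)
  delta_gg <- ms$omega0 * (ms$sigma_v2 / ms$n_x)
  d <- diag(delta_gg)
  if (any(d <= 0)) stop("non-positive diagonal in Delta_GG", call. = FALSE)
  t_stats <- ms$G_hat / sqrt(d)
  threshold <- stats::qnorm(1 - nu / 2)
  selected <- which(abs(t_stats) > threshold)
  if (length(selected) == 0L) {
    stop("no relevant factors at level nu = ", nu,
         "; use the identification-robust tests (ar_test/lm_test/clr_test) ",
         "instead", call. = FALSE)
  }
  gamma <- matrix(0, nrow = ms$r, ncol = length(selected))
  gamma[cbind(selected, seq_along(selected))] <- 1
  structure(list(t_stats = t_stats, threshold = threshold, nu = nu,
                 selected = selected, selection_matrix = gamma,
                 r_star = length(selected)),
            class = "fmr_selection")
}

#' @export
print.fmr_selection <- function(x, ...) {
  cat("factor pre-test (nu =", x$nu, "): selected", x$r_star, "of",
      length(x$t_stats), "factors:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# moment system restricted to the selected factors; the scalar variance
# components are kept from the full system (they estimate the same scalars)
project_moment_system <- function(ms, selection) {
  sel <- selection$selected
  structure(list(g_y = ms$g_y[sel], G_hat = ms$G_hat[sel],
                 omega0 = ms$omega0[sel, sel, drop = FALSE],
                 sigma_v2 = ms$sigma_v2, sigma_e2 = ms$sigma_e2,
                 n_x = ms$n_x, n_y = ms$n_y, r = length(sel),
                 var_x = ms$var_x, var_y = ms$var_y),
            class = "fmr_moment_system")
}

#' Selected-factor LIML (S-LIML) fit
#'
#' F-LIML applied to the moment system restricted to the factors retained by
#' the relevance pre-test, together with the quantities needed for selective
#' inference: the selection-estimate covariance direction `c_g`, the diagonal
#' of `D_GG`, and the observed sufficient statistic
#' `u = t_stats - c_g * theta_s / v_s`.
#'
#' @param ms The full `fmr_moment_system`.
#' @param selection An `fmr_selection` from [pretest_factors()].
#' @param alpha Level for the (naive Wald) CI stored on the fit.
#' @return Object of class `fmr_sliml`: `theta_s`, `v_s`, `se`, `ci_low`,
#'   `ci_high` (naive Wald, not selection-adjusted), `c_g`, `d_diag`, `u`,
#'   `selection`, `alpha`.
#' @export
fit_sliml <- function(ms, selection, alpha = 0.05) {
  stopifnot(inherits(selection, "fmr_selection"))
  ms_s <- project_moment_system(ms, selection)
  fit <- fit_fliml(ms_s, alpha = alpha)
  theta_s <- fit$theta
  delta_gg <- ms$omega0 * (ms$sigma_v2 / ms$n_x)
  d_diag <- diag(delta_gg)
  gamma <- selection$selection_matrix
  omega_s <- crossprod(gamma, moment_covariance(theta_s, ms) %*% gamma)
  g_s <- drop(crossprod(gamma, ms$G_hat))
  v_s <- 1 / drop(crossprod(g_s, solve(omega_s, g_s)))
  c_g <- -drop((1 / sqrt(d_diag)) *
                 (delta_gg %*% gamma %*% solve(omega_s, g_s))) * v_s * theta_s
  u <- selection$t_stats - c_g * theta_s / v_s
  structure(list(theta_s = theta_s, v_s = v_s, se = sqrt(v_s),
                 ci_low = theta_s - stats::qnorm(1 - alpha / 2) * sqrt(v_s),
                 ci_high = theta_s + stats::qnorm(1 - alpha / 2) * sqrt(v_s),
                 c_g = c_g, d_diag = d_diag, u = u,
                 objective_at_min = fit$objective_at_min,
                 selection = selection, alpha = alpha),
            class = "fmr_sliml")
}

#' @export
print.fmr_sliml <- function(x, ...) {
  cat(sprintf(paste0("S-LIML estimate (r* = %d of %d factors): ",
                     "theta = %.4f (se %.4f)\n"),
              x$selection$r_star, length(x$selection$t_stats),
              x$theta_s, x$se))
  invisible(x)
}

# simulate the conditional law of theta_s given U = u and the selection
# event; returns list(thetas = kept draws, n_kept).
# u_bar(K) = u + c_g * theta(K) / v_s with theta(K) = theta0 + sqrt(v_s) K;
# this is the algebraically consistent reconstruction for theta0 != 0 (the
# textbook display u + c_g K / sqrt(v_s) is recovered at theta0 = 0).
# form = "display" exposes the literal display for audit.
conditional_draws <- function(theta0, fit, n_draws, seed,
                              form = c("consistent", "display")) {
  form <- match.arg(form)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  k <- stats::rnorm(n_draws)
  thetas <- theta0 + sqrt(fit$v_s) * k
  sel <- fit$selection
  in_sel <- seq_along(fit$u) %in% sel$selected
  u_bar <- if (form == "consistent") {
    outer(fit$c_g / fit$v_s, thetas) + fit$u
  } else {
    outer(fit$c_g / sqrt(fit$v_s), k) + fit$u
  }
  above <- abs(u_bar) > sel$threshold
  ok <- colSums(above[in_sel, , drop = FALSE]) == sum(in_sel) &
    colSums(above[!in_sel, , drop = FALSE]) == 0L
  list(thetas = thetas[ok], n_kept = sum(ok), n_draws = n_draws)
}

#' Selective (conditional) test of a hypothesized effect after pre-testing
#'
#' Tests H0: theta = theta0 for the S-LIML estimator, conditioning on the
#' factor-selection event and on the sufficient statistic U for the nuisance
#' factor-association means. Monte-Carlo evaluation: draw K ~ N(0,1),
#' form candidate estimates `theta(K) = theta0 + sqrt(v_s) K`, reconstruct
#' the pre-test vector `u_bar(K) = u + c_g theta(K) / v_s`, keep draws on
#' which the observed selection event recurs, and compare the observed
#' `theta_s` with the alpha/2 and 1-alpha/2 empirical quantiles of the kept
#' draws.
#'
#' @param theta0 Hypothesized effect.
#' @param fit An `fmr_sliml` fit.
#' @param alpha Level (default 0.05).
#' @param n_draws Monte-Carlo draws (default 2e5, minimum 1e4).
#' @param seed Integer seed for the K-stream.
#' @param form `"consistent"` (default) or `"display"`; see Details in the
#'   package vignette.
#' @return Object of class `fmr_condtest`: `theta0`, `lower_q`, `upper_q`,
#'   `reject`, `acceptance_prob`, `n_draws`, `n_kept`, `seed`.
#' @export
conditional_test <- function(theta0, fit, alpha = 0.05, n_draws = 2e5,
                             seed = 1L, form = c("consistent", "display")) {
  stopifnot(inherits(fit, "fmr_sliml"), n_draws >= 1e4)
  cd <- conditional_draws(theta0, fit, n_draws, seed, form = match.arg(form))
  if (cd$n_kept < 100L) {
    stop("selection event too rare under H0 (", cd$n_kept,
         " of ", n_draws, " draws kept); increase draws or report an ",
         "identification-robust interval", call. = FALSE)
  }
  qs <- stats::quantile(cd$thetas, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
  structure(list(theta0 = theta0, lower_q = qs[1], upper_q = qs[2],
                 reject = fit$theta_s < qs[1] || fit$theta_s > qs[2],
                 acceptance_prob = cd$n_kept / n_draws,
                 n_draws = n_draws, n_kept = cd$n_kept, seed = seed,
                 alpha = alpha),
            class = "fmr_condtest")
}

#' @export
print.fmr_condtest <- function(x, ...) {
  cat(sprintf(paste0("selective test at theta0 = %.4f: conditional ",
                     "quantiles [%.4f, %.4f], %s (selection prob %.3f)\n"),
              x$theta0, x$lower_q, x$upper_q,
              if (x$reject) "REJECT" else "do not reject",
              x$acceptance_prob))
  invisible(x)
}

#' Selective confidence interval by inversion of the conditional test
#'
#' Scans a grid of null values, keeping those not rejected by
#' [conditional_test()]. One K-stream (common random numbers) is reused
#' across the grid so that the acceptance region is smooth in theta0;
#' endpoints are refined by bisection.
#'
#' @param fit An `fmr_sliml` fit.
#' @param alpha Level (default 0.05).
#' @param bracket Search interval; default the naive Wald interval widened
#'   by a factor 5.
#' @param resolution Grid size (default 201).
#' @param n_draws,seed As in [conditional_test()].
#' @return An `fmr_confset`.
#' @export
selective_ci <- function(fit, alpha = 0.05, bracket = NULL,
                         resolution = 201L, n_draws = 2e5, seed = 1L) {
  stopifnot(inherits(fit, "fmr_sliml"))
  if (is.null(bracket)) {
    half <- 5 * stats::qnorm(1 - alpha / 2) * fit$se
    bracket <- c(fit$theta_s - half, fit$theta_s + half)
  }
  accept <- function(theta0) {
    res <- tryCatch(conditional_test(theta0, fit, alpha = alpha,
                                     n_draws = n_draws, seed = seed),
                    error = function(e) NULL)
    !is.null(res) && !res$reject
  }
  grid <- seq(bracket[1], bracket[2], length.out = resolution)
  inside <- vapply(grid, accept, logical(1))
  intervals <- matrix(numeric(0), ncol = 2,
                      dimnames = list(NULL, c("low", "high")))
  if (any(inside)) {
    run <- rle(inside)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (k in which(run$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      lo <- grid[i0]; hi <- grid[i1]
      if (i0 > 1L) {
        a <- grid[i0 - 1L]; b <- grid[i0]
        for (i in 1:30) {
          mid <- (a + b) / 2
          if (accept(mid)) b <- mid else a <- mid
          if (b - a < 1e-4) break
        }
        lo <- (a + b) / 2
      }
      if (i1 < resolution) {
        a <- grid[i1]; b <- grid[i1 + 1L]
        for (i in 1:30) {
          mid <- (a + b) / 2
          if (accept(mid)) a <- mid else b <- mid
          if (b - a < 1e-4) break
        }
        hi <- (a + b) / 2
      }
      intervals <- rbind(intervals, c(lo, hi))
    }
  }
  unbounded <- nrow(intervals) > 0 &&
    (abs(intervals[1, 1] - bracket[1]) < 1e-8 * diff(bracket) ||
       abs(intervals[nrow(intervals), 2] - bracket[2]) < 1e-8 * diff(bracket))
  structure(list(intervals = intervals, alpha = alpha, bracket = bracket,
                 unbounded = unbounded, test = "sliml"),
            class = "fmr_confset")
}
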