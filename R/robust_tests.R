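#' Orthogonalized score and strength statistics
#'
#' Computes, at a hypothesized effect `theta0`, the asymptotically
#' independent pair
#' \itemize{
#'   \item `S_bar = Omega(theta0)^{-1/2} g(theta0)` — carries the evidence on
#'     instrument validity;
#'   \item `T_bar = (D_GG - D_G Omega(theta0)^{-1} D_G)^{-1/2}
#'     (G_hat - D_G Omega(theta0)^{-1} g(theta0))` — carries instrument
#'     strength, with `D_GG = omega0 * sigma_v2 / n_x` and
#'     `D_G = D_GG * theta0`;
#' }
#' together with the quadratic forms `Q_S = S'S`, `Q_ST = S'T`, `Q_T = T'T`
#' feeding the F-AR, F-LM and F-CLR statistics. Matrix inverse square roots
#' are symmetric (eigendecomposition), so all quantities are invariant to
#' rotation of the estimated factors.
#'
#' @param theta0 Hypothesized causal effect.
#' @param ms An `fmr_moment_system`.
#' @return Object of class `fmr_st`: `S_bar`, `T_bar`, `Q_S`, `Q_ST`, `Q_T`,
#'   `delta_gg`, `delta_g`, `theta0`, `r`.
#' @export
st_statistics <- function(theta0, ms) {
  stopifnot(inherits(ms, "fmr_moment_system"))
  g0 <- moment_value(theta0, ms)
  omega <- moment_covariance(theta0, ms)
  delta_gg <- ms$omega0 * (ms$sigma_v2 / ms$n_x)
  delta_g <- delta_gg * theta0
  s_bar <- drop(sym_inv_sqrt(omega, "Omega(theta0)") %*% g0)
  # bracket = D_GG - D_G Omega^-1 D_G; with Omega = omega0 * s these are all
  # scalar multiples of omega0, but we keep the matrix algebra general
  omega_inv_dg <- solve(omega, delta_g)
  bracket <- delta_gg - delta_g %*% omega_inv_dg
  bracket <- (bracket + t(bracket)) / 2
  t_bar <- drop(sym_inv_sqrt(bracket, "T_bar bracket matrix") %*%
                  (ms$G_hat - delta_g %*% solve(omega, g0)))
  structure(list(S_bar = s_bar, T_bar = t_bar,
                 Q_S = sum(s_bar^2), Q_ST = sum(s_bar * t_bar),
                 Q_T = sum(t_bar^2),
                 delta_gg = delta_gg, delta_g = delta_g,
                 theta0 = theta0, r = ms$r),
            class = "fmr_st")
}

#' Factor Anderson-Rubin test
#'
#' F-AR = Q_S, referred to chi-square with r degrees of freedom. Valid
#' whatever the strength of the factor-exposure associations.
#'
#' @param theta0 Hypothesized effect.
#' @param ms An `fmr_moment_system`.
#' @return An `fmr_test`.
#' @export
ar_test <- function(theta0, ms) {
  st <- st_statistics(theta0, ms)
  new_fmr_test(statistic = st$Q_S,
               p_value = stats::pchisq(st$Q_S, df = st$r, lower.tail = FALSE),
               null_law = sprintf("chi2_%d", st$r), theta0 = theta0,
               method = "F-AR")
}

#' Factor Lagrange multiplier (score) test
#'
#' F-LM = Q_ST^2 / Q_T, referred to chi-square with 1 degree of freedom.
#'
#' @inheritParams ar_test
#' @return An `fmr_test`.
#' @export
lm_test <- function(theta0, ms) {
  st <- st_statistics(theta0, ms)
  if (st$Q_T <= 0) {
    stop("Q_T = 0: instruments entirely irrelevant, LM test degenerate",
         call. = FALSE)
  }
  stat <- st$Q_ST^2 / st$Q_T
  new_fmr_test(statistic = stat,
               p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               null_law = "chi2_1", theta0 = theta0, method = "F-LM")
}

# CLR statistic from the quadratic forms; discriminant clipped at 0 within
# a -1e-10 relative tolerance (Cauchy-Schwarz guarantees it in exact math)
clr_statistic <- function(q_s, q_st, q_t) {
  disc <- (q_s + q_t)^2 - 4 * (q_s * q_t - q_st^2)
  if (disc < -1e-10 * max((q_s + q_t)^2, 1)) {
    stop("negative CLR discriminant: inconsistent quadratic forms",
         call. = FALSE)
  }
  (q_s - q_t + sqrt(max(disc, 0))) / 2
}

#' Conditional p-value for the CLR statistic
#'
#' Under the null the CLR statistic, conditional on the strength statistic
#' `q_t`, is distributed as
#' `[s1 + s2 - q_t + sqrt((s1 + s2 - q_t)^2 + 4 s1 q_t)] / 2` with
#' independent `s1 ~ chi2_1` and `s2 ~ chi2_(r-1)`. The upper-tail
#' probability at `m` reduces to a one-dimensional integral over s1 on
#' `[0, m]` with the chi2_(r-1) tail in closed form: the event boundary is
#' `s2* = (m - s1)(1 + q_t / m)`.
#'
#' @param m Observed CLR statistic (>= 0).
#' @param q_t Conditioning statistic (>= 0).
#' @param r Number of factors (>= 1).
#' @param method `"numeric"` (adaptive quadrature, default) or
#'   `"montecarlo"`.
#' @param mc_draws Number of Monte-Carlo draws (default 1e5).
#' @param seed Optional seed for the Monte-Carlo path.
#' @return Scalar p-value.
#' @export
clr_pvalue <- function(m, q_t, r, method = c("numeric", "montecarlo"),
                       mc_draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(q_t >= -1e-12, r >= 1)
  q_t <- max(q_t, 0)
  if (m <= 0) return(1)
  if (r == 1) {
    # CLR collapses to s1 exactly
    return(stats::pchisq(m, df = 1, lower.tail = FALSE))
  }
  if (method == "numeric") {
    integrand <- function(s1) {
      s2_star <- (m - s1) * (1 + q_t / m)
      stats::dchisq(s1, df = 1) *
        stats::pchisq(s2_star, df = r - 1, lower.tail = FALSE)
    }
    inner <- stats::integrate(integrand, 0, m, rel.tol = 1e-8,
                              abs.tol = 1e-10, subdivisions = 500L)$value
    p <- stats::pchisq(m, df = 1, lower.tail = FALSE) + inner
    min(max(p, 0), 1)
  } else {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    s1 <- stats::rchisq(mc_draws, df = 1)
    s2 <- stats::rchisq(mc_draws, df = r - 1)
    w <- s1 + s2 - q_t
    draws <- (w + sqrt(w^2 + 4 * s1 * q_t)) / 2
    mean(draws >= m)
  }
}

#' Factor conditional likelihood ratio test
#'
#' F-CLR = `[Q_S - Q_T + sqrt((Q_S + Q_T)^2 - 4 (Q_S Q_T - Q_ST^2))] / 2`,
#' with p-value computed conditional on Q_T (see [clr_pvalue()]). The most
#' powerful of the three identification-robust tests in typical
#' over-identified settings.
#'
#' @inheritParams ar_test
#' @param pvalue_method `"numeric"` or `"montecarlo"` (see [clr_pvalue()]).
#' @param mc_draws Monte-Carlo draws when `pvalue_method = "montecarlo"`.
#' @param seed Optional Monte-Carlo seed.
#' @return An `fmr_test`.
#' @export
clr_test <- function(theta0, ms, pvalue_method = c("numeric", "montecarlo"),
                     mc_draws = 1e5, seed = NULL) {
  pvalue_method <- match.arg(pvalue_method)
  st <- st_statistics(theta0, ms)
  stat <- clr_statistic(st$Q_S, st$Q_ST, st$Q_T)
  p <- clr_pvalue(stat, st$Q_T, st$r, method = pvalue_method,
                  mc_draws = mc_draws, seed = seed)
  new_fmr_test(statistic = stat, p_value = p,
               null_law = sprintf("clr_conditional(Q_T=%.4g)", st$Q_T),
               theta0 = theta0, method = "F-CLR")
}

#' Confidence set by inversion of an identification-robust test
#'
#' Scans a grid of hypothesized effects, keeps the region where the test
#' p-value is at least `alpha`, and refines the endpoints of each kept run by
#' bisection. Disconnected sets are returned as multiple intervals; a set
#' touching the search bracket is flagged as possibly unbounded (the typical
#' AR outcome under irrelevant instruments).
#'
#' @param test `"ar"`, `"lm"` or `"clr"`.
#' @param ms An `fmr_moment_system`.
#' @param alpha Level (default 0.05).
#' @param bracket Numeric length-2 search interval; default
#'   `theta_hat +/- 20 * se` from a preliminary F-LIML fit.
#' @param resolution Number of grid points (default 2001).
#' @param ... Passed to the underlying test (e.g. `pvalue_method`).
#' @return Object of class `fmr_confset`: `intervals` (two-column matrix),
#'   `alpha`, `bracket`, `unbounded` flag.
#' @export
invert_test <- function(test = c("ar", "lm", "clr"), ms, alpha = 0.05,
                        bracket = NULL, resolution = 2001L, ...) {
  test <- match.arg(test)
  fun <- switch(test, ar = ar_test, lm = lm_test, clr = clr_test)
  pval <- function(theta) fun(theta, ms, ...)$p_value
  if (is.null(bracket)) {
    fit <- fit_fliml(ms)
    bracket <- fit$theta + c(-20, 20) * fit$se
  }
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  grid <- seq(bracket[1], bracket[2], length.out = resolution)
  pv <- vapply(grid, pval, numeric(1))
  if (any(!is.finite(pv))) stop("non-finite p-value on inversion grid",
                                call. = FALSE)
  inside <- pv >= alpha
  intervals <- matrix(numeric(0), ncol = 2,
                      dimnames = list(NULL, c("low", "high")))
  if (any(inside)) {
    run <- rle(inside)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (k in which(run$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      lo <- grid[i0]
      hi <- grid[i1]
      if (i0 > 1L) {
        a <- grid[i0 - 1L]; b <- grid[i0]
        for (i in 1:40) {
          mid <- (a + b) / 2
          if (pval(mid) >= alpha) b <- mid else a <- mid
          if (b - a < 1e-4) break
        }
        lo <- (a + b) / 2
      }
      if (i1 < resolution) {
        a <- grid[i1]; b <- grid[i1 + 1L]
        for (i in 1:40) {
          mid <- (a + b) / 2
          if (pval(mid) >= alpha) a <- mid else b <- mid
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
                 unbounded = unbounded, test = test),
            class = "fmr_confset")
}

#' @export
print.fmr_confset <- function(x, ...) {
  cat(sprintf("%s %d%% confidence set:", toupper(x$test),
              round(100 * (1 - x$alpha))))
  if (nrow(x$intervals) == 0) {
    cat(" empty\n")
  } else {
    apply(x$intervals, 1, function(row)
      cat(sprintf(" [%.4f, %.4f]", row[1], row[2])))
    cat(if (x$unbounded) " (touches search bracket; possibly unbounded)\n"
        else "\n")
  }
  invisible(x)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
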