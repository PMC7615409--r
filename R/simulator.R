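#' Generate a synthetic cis-region truth configuration
#'
#' Builds a block-structured region of p correlated variants driven by r
#' latent factors with idiosyncratic noise — the stylized LD pattern of a
#' single gene region. Variants are split into r contiguous blocks; each
#' block loads strongly and sign-coherently on its own factor, with small
#' cross-loadings. The implied correlation matrix has unit diagonal by
#' construction (loadings and idiosyncratic standard deviations are rescaled
#' variant-wise), and variant dosage variances are drawn from Hardy-Weinberg
#' frequencies.
#'
#' The exposure associations arise from a factor-level effect vector eta
#' (delta_x = Lambda Sigma_F eta): `eta_nonzero` of the r factors carry
#' signal (a mixture of relevant and irrelevant factors, which is what the
#' selective pre-test faces in practice), scaled so the factors explain
#' `genetic_var_x` of the unit exposure variance. Outcome associations are
#' proportional: delta_y = theta0 * delta_x.
#'
#' @param p Number of variants.
#' @param r Number of latent factors (`r < p`).
#' @param seed Integer seed; the returned truth is a deterministic function
#'   of the arguments.
#' @param theta0 True causal effect (default 0).
#' @param block_loading Range of within-block loadings before rescaling
#'   (default `c(0.75, 0.95)`).
#' @param cross_sd Standard deviation of cross-loadings (default 0.05).
#' @param idio_sd Idiosyncratic standard deviation before rescaling
#'   (default 0.15, leaving roughly 3% of each variant's variance
#'   idiosyncratic — comparable to the ~99% factor-explained share seen in
#'   real cis regions).
#' @param eta_nonzero Number of factors with non-zero exposure effects
#'   (default `ceiling(r * 0.6)`).
#' @param genetic_var_x Exposure variance explained by the factors
#'   (default 0.02).
#' @param freq_range Allele-frequency range for dosage variances
#'   (default `c(0.05, 0.5)`).
#' @return Object of class `fmr_truth`: `loadings`, `factor_cov`, `idio_sd`,
#'   `variant_variances`, `delta_x`, `delta_y`, `theta0`, `var_x`, `var_y`,
#'   plus derived `rho` (implied correlation) and `var_z` (implied
#'   covariance).
#' @export
synth_region <- function(p, r, seed, theta0 = 0,
                         block_loading = c(0.75, 0.95), cross_sd = 0.05,
                         idio_sd = 0.15, eta_nonzero = ceiling(r * 0.6),
                         genetic_var_x = 0.02, freq_range = c(0.05, 0.5)) {
  stopifnot(r < p, r >= 1, genetic_var_x > 0, genetic_var_x < 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  block <- rep(seq_len(r), length.out = p)[order(rep(seq_len(r),
                                                     length.out = p))]
  lam <- matrix(stats::rnorm(p * r, sd = cross_sd), p, r)
  for (j in seq_len(r)) {
    in_block <- block == j
    lam[in_block, j] <- stats::runif(sum(in_block), block_loading[1],
                                     block_loading[2])
  }
  sigma_f <- diag(1, r)
  idio <- rep(idio_sd, p)

  # rescale to unit diagonal (correlation scale)
  d <- rowSums(lam^2) + idio^2
  lam_c <- lam / sqrt(d)
  idio_c <- idio / sqrt(d)
  if (any(idio_c <= 0)) stop("idiosyncratic variance non-positive after ",
                             "rescaling", call. = FALSE)
  rho <- tcrossprod(lam_c) + diag(idio_c^2)

  variant_variances <- variance_from_frequency(
    stats::runif(p, freq_range[1], freq_range[2]))
  s <- sqrt(variant_variances)
  loadings <- lam_c * s
  idio_sd_vec <- idio_c * s
  var_z <- tcrossprod(loadings) + diag(idio_sd_vec^2)

  eta <- numeric(r)
  idx <- seq_len(min(eta_nonzero, r))
  eta[idx] <- stats::runif(length(idx), 0.5, 1) *
    sample(c(-1, 1), length(idx), replace = TRUE)
  delta_x <- drop(loadings %*% (sigma_f %*% eta))
  omega0 <- crossprod(loadings, var_z %*% loadings)
  qf <- drop(crossprod(crossprod(loadings, delta_x),
                       solve(omega0, crossprod(loadings, delta_x))))
  delta_x <- delta_x * sqrt(genetic_var_x / qf)

  out <- structure(list(loadings = loadings, factor_cov = sigma_f,
                        idio_sd = idio_sd_vec,
                        variant_variances = variant_variances,
                        delta_x = delta_x, delta_y = theta0 * delta_x,
                        theta0 = theta0, var_x = 1, var_y = 1,
                        rho = rho, var_z = var_z, tau = NULL),
                   class = "fmr_truth")
  # sanity: clear eigenvalue gap between factor and idiosyncratic spectrum
  ev <- eigen(var_z, symmetric = TRUE, only.values = TRUE)$values
  if (ev[r] / ev[r + 1] < 2) {
    warning("weak eigenvalue separation in synthetic region (ratio ",
            format(ev[r] / ev[r + 1], digits = 3), ")", call. = FALSE)
  }
  out
}

#' @export
print.fmr_truth <- function(x, ...) {
  cat("synthetic cis-region truth: p =", nrow(x$loadings),
      " r =", ncol(x$loadings), " theta0 =", x$theta0, "\n")
  invisible(x)
}

# population variance components and factor-level quadratic form of a truth
truth_components <- function(truth) {
  lam <- truth$loadings
  omega0 <- crossprod(lam, truth$var_z %*% lam)
  mx <- drop(crossprod(lam, truth$delta_x))
  my <- drop(crossprod(lam, truth$delta_y))
  qx <- drop(crossprod(mx, solve(omega0, mx)))
  qy <- drop(crossprod(my, solve(omega0, my)))
  list(omega0 = omega0, mx = mx, my = my,
       sigma_v2 = truth$var_x - qx, sigma_e2 = truth$var_y - qy, qx = qx)
}

#' Calibrate the GWAS sample size to a target first-stage F-statistic
#'
#' Solves `f_target = 1 + n * q / (r * sigma_v2)` for n (rounded up), where
#' q is the omega0-weighted quadratic form of the factor-exposure
#' associations — the population version of [factor_f_statistic()].
#'
#' @param truth An `fmr_truth`.
#' @param f_target Target F, must exceed 1.
#' @return Integer sample size.
#' @export
calibrate_n <- function(truth, f_target) {
  if (f_target <= 1) stop("f_target must exceed 1", call. = FALSE)
  tc <- truth_components(truth)
  if (tc$qx <= 0) stop("delta_x is zero: F cannot be calibrated",
                       call. = FALSE)
  r <- ncol(truth$loadings)
  as.integer(ceiling((f_target - 1) * r * tc$sigma_v2 / tc$qx))
}

#' Draw two-sample summary statistics from a region truth
#'
#' The factor-level associations are drawn from their asymptotic Gaussian
#' law: `Lambda' delta_hat_x ~ N(Lambda' delta_x, omega0 sigma_v2 / n_x)`,
#' independently for the outcome with `sigma_e2 / n_y` (two non-overlapping
#' samples). Draws are lifted back to variant space through the minimum-norm
#' solution `Lambda (Lambda'Lambda)^-1 m` plus an idiosyncratic residual
#' orthogonal to the loadings span; all downstream statistics depend on the
#' variant-level associations only through their factor projections, for
#' which the lift is exact.
#'
#' @param truth An `fmr_truth`.
#' @param n_x,n_y Sample sizes (>= 2).
#' @param seed Integer seed.
#' @return An `fmr_dataset`.
#' @export
draw_summary_stats <- function(truth, n_x, n_y, seed) {
  stopifnot(n_x >= 2, n_y >= 2)
  tc <- truth_components(truth)
  if (tc$sigma_v2 <= 0) stop("truth implies non-positive sigma_V^2",
                             call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  lam <- truth$loadings
  p <- nrow(lam); r <- ncol(lam)
  ch <- chol(tc$omega0)
  mx <- tc$mx + sqrt(tc$sigma_v2 / n_x) * drop(crossprod(ch, stats::rnorm(r)))
  my <- tc$my + sqrt(tc$sigma_e2 / n_y) * drop(crossprod(ch, stats::rnorm(r)))
  lift <- lam %*% solve(crossprod(lam))
  proj <- function(v) v - lam %*% solve(crossprod(lam), crossprod(lam, v))
  res_x <- drop(proj(stats::rnorm(p, sd = sqrt(tc$sigma_v2 / n_x) *
                                    truth$idio_sd)))
  res_y <- drop(proj(stats::rnorm(p, sd = sqrt(tc$sigma_e2 / n_y) *
                                    truth$idio_sd)))
  new_summary_dataset(paste0("v", seq_len(p)),
                      drop(lift %*% mx) + res_x,
                      drop(lift %*% my) + res_y,
                      n_x = n_x, n_y = n_y,
                      var_x = truth$var_x, var_y = truth$var_y,
                      variant_variances = truth$variant_variances)
}

#' Noisy measurement of per-variant variances
#'
#' Draws measured variances as independent truncated normals centered at the
#' true variances, with variance 1/n, truncated to the range of the true
#' variances across the region.
#'
#' @param truth An `fmr_truth`.
#' @param n Sample size driving the measurement noise (>= 2).
#' @param seed Integer seed.
#' @return Numeric p-vector of noisy variances within the truncation bounds.
#' @export
noisy_variant_variances <- function(truth, n, seed) {
  stopifnot(n >= 2)
  v <- diag(truth$var_z)
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-12) return(v)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  sd <- 1 / sqrt(n)
  # inverse-CDF truncated-normal sampling
  plo <- stats::pnorm(lo, mean = v, sd = sd)
  phi <- stats::pnorm(hi, mean = v, sd = sd)
  u <- stats::runif(length(v), plo, phi)
  stats::qnorm(u, mean = v, sd = sd)
}

#' Perturb a variant correlation matrix (mismeasured-LD designs)
#'
#' Model 4 subtracts a constant `kappa0` from every off-diagonal correlation
#' (feasible only when no entry is pushed below -1); Model 5 applies the
#' sign-preserving power transform `sign(rho) |rho|^kappa2`, which for
#' `kappa2 > 1` shrinks moderate correlations toward zero. The diagonal is
#' restored to 1 and the result is PSD-repaired.
#'
#' @param rho Correlation matrix (plain matrix or `fmr_ld`).
#' @param model 4 or 5.
#' @param kappa0 Offset for Model 4.
#' @param kappa2 Power for Model 5.
#' @return Perturbed correlation matrix (plain matrix).
#' @export
perturb_correlations <- function(rho, model, kappa0 = NULL, kappa2 = NULL) {
  if (inherits(rho, "fmr_ld")) rho <- rho$rho
  stopifnot(model %in% c(4, 5))
  off <- row(rho) != col(rho)
  if (model == 4) {
    if (is.null(kappa0)) stop("Model 4 requires kappa0", call. = FALSE)
    if (min(rho[off]) - kappa0 < -1) {
      stop("kappa0 = ", kappa0, " pushes correlations below -1 ",
           "(minimum observed ", format(min(rho[off]), digits = 3), ")",
           call. = FALSE)
    }
    out <- rho
    out[off] <- rho[off] - kappa0
  } else {
    if (is.null(kappa2)) stop("Model 5 requires kappa2", call. = FALSE)
    out <- sign(rho) * abs(rho)^kappa2
  }
  diag(out) <- 1
  out <- nearest_psd(out)
  # repair can nudge the diagonal; renormalize back to a correlation
  s <- sqrt(diag(out))
  out <- out / tcrossprod(s)
  diag(out) <- 1
  out
}

#' Add direct (pleiotropic) variant-outcome effects to a truth
#'
#' Local misspecification `delta_y = delta_x * theta0 + tau / sqrt(n)`.
#' Model 2 uses a constant direct effect `tau` for all variants; Model 3
#' draws each element of tau from U(-1, 1) once (fixed thereafter, not
#' redrawn per replication).
#'
#' @param truth An `fmr_truth`.
#' @param model 2 or 3.
#' @param tau Scalar direct effect (Model 2) or half-width multiplier of the
#'   uniform draw (Model 3, default 1).
#' @param n Sample size providing the `1/sqrt(n)` local scaling.
#' @param seed Seed for the Model-3 draw.
#' @return The modified `fmr_truth` (with the raw `tau` vector attached).
#' @export
apply_pleiotropy <- function(truth, model, tau, n, seed = 1L) {
  stopifnot(model %in% c(2, 3), n >= 2)
  p <- nrow(truth$loadings)
  tau_vec <- if (model == 2) {
    rep(tau, p)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    tau * stats::runif(p, -1, 1)
  }
  truth$tau <- tau_vec
  truth$delta_y <- truth$delta_x * truth$theta0 + tau_vec / sqrt(n)
  truth
}

#' Specify a Monte-Carlo simulation design
#'
#' Validates the parameter set of the five supported designs: Model 1
#' (correct specification, varying instrument strength), Models 2-3 (local
#' pleiotropy, constant or uniform direct effects), Models 4-5 (mismeasured
#' variant correlations). Exactly the parameters of the named model are
#' accepted.
#'
#' @param model Integer 1-5.
#' @param f_target Target first-stage F (alternative: give `n` directly).
#' @param n Optional explicit sample size.
#' @param theta_grid True effect values to simulate (default 0, i.e. a size
#'   study for the null H0: theta = 0).
#' @param tau Direct-effect parameter (Models 2-3 only).
#' @param kappa0 Correlation offset (Model 4 only).
#' @param kappa2 Correlation power (Model 5 only).
#' @param r_assumed Number of factors assumed in estimation (default the
#'   true r of the region).
#' @param reps Monte-Carlo replications.
#' @param seed Master seed.
#' @param methods Subset of `c("fliml", "far", "flm", "fclr", "sliml")`.
#' @param nu Pre-test level for S-LIML; default follows the F-adaptive rule
#'   (0.01 for F >= 10, 0.05 for 5 <= F < 10, 0.1 below).
#' @param p,r,region_args Region size, true factor count and extra arguments
#'   passed to [synth_region()].
#' @param theta0_test Null value tested (default 0).
#' @param alpha Test level (default 0.05).
#' @param sliml_draws Monte-Carlo draws inside each selective test
#'   (default 2e4).
#' @return Object of class `fmr_design`.
#' @export
simulation_design <- function(model = 1, f_target = 20, n = NULL,
                              theta_grid = 0, tau = NULL, kappa0 = NULL,
                              kappa2 = NULL, r_assumed = NULL, reps = 200,
                              seed = 1L,
                              methods = c("fliml", "far", "flm", "fclr",
                                          "sliml"),
                              nu = NULL, p = 60, r = 5,
                              region_args = list(),
                              theta0_test = 0, alpha = 0.05,
                              sliml_draws = 2e4) {
  stopifnot(model %in% 1:5, reps >= 1)
  methods <- match.arg(as.character(unlist(methods)),
                       c("fliml", "far", "flm", "fclr", "sliml"),
                       several.ok = TRUE)
  if (model %in% c(2, 3) && is.null(tau)) {
    stop("Models 2 and 3 require tau", call. = FALSE)
  }
  if (model == 4 && is.null(kappa0)) stop("Model 4 requires kappa0",
                                          call. = FALSE)
  if (model == 5 && is.null(kappa2)) stop("Model 5 requires kappa2",
                                          call. = FALSE)
  if (!model %in% c(2, 3) && !is.null(tau)) {
    stop("tau applies to Models 2 and 3 only", call. = FALSE)
  }
  if (model != 4 && !is.null(kappa0)) stop("kappa0 applies to Model 4 only",
                                           call. = FALSE)
  if (model != 5 && !is.null(kappa2)) stop("kappa2 applies to Model 5 only",
                                           call. = FALSE)
  structure(list(model = model, f_target = f_target, n = n,
                 theta_grid = theta_grid, tau = tau, kappa0 = kappa0,
                 kappa2 = kappa2, r_assumed = r_assumed, reps = reps,
                 seed = as.integer(seed), methods = methods, nu = nu,
                 p = p, r = r, region_args = region_args,
                 theta0_test = theta0_test, alpha = alpha,
                 sliml_draws = sliml_draws),
            class = "fmr_design")
}

# F-adaptive pre-test level
default_nu_rule <- function(f_target) {
  if (f_target >= 10) 0.01 else if (f_target >= 5) 0.05 else 0.1
}

#' Run a Monte-Carlo simulation design
#'
#' Per replication: perturb the researcher-visible correlation matrix
#' (Models 4-5), draw noisy variant variances, rebuild the measured
#' covariance, estimate loadings at the assumed r, draw two-sample summary
#' statistics from the truth, and apply the requested methods to the null
#' `theta0_test`. Results are deterministic given the design seed.
#'
#' @param design An `fmr_design`.
#' @return Object of class `fmr_simresult`: a data.frame with one row per
#'   (theta, method) cell carrying `rejection_rate`, `bias`, `rmse`,
#'   `median_r_star`, `reps_ok` and `mc_se`, plus the design as attribute.
#'   Per-replication failures are tolerated up to 5% per cell.
#' @export
run_design <- function(design) {
  stopifnot(inherits(design, "fmr_design"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(design$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 10L,
                          design$reps * length(design$theta_grid) + 10L)
  region_seed <- rep_seeds[length(rep_seeds)]
  rows <- list()

  for (ti in seq_along(design$theta_grid)) {
    theta_true <- design$theta_grid[ti]
    truth <- do.call(synth_region,
                     c(list(p = design$p, r = design$r, seed = region_seed,
                            theta0 = theta_true), design$region_args))
    n <- if (!is.null(design$n)) design$n else calibrate_n(truth,
                                                           design$f_target)
    if (design$model %in% c(2, 3)) {
      truth <- apply_pleiotropy(truth, design$model, design$tau, n,
                                seed = region_seed)
    }
    rho_measured <- if (design$model %in% c(4, 5)) {
      perturb_correlations(truth$rho, design$model,
                           kappa0 = design$kappa0, kappa2 = design$kappa2)
    } else truth$rho
    r_assumed <- if (!is.null(design$r_assumed)) design$r_assumed else design$r
    nu <- if (!is.null(design$nu)) design$nu else {
      default_nu_rule(if (!is.null(design$f_target)) design$f_target else 10)
    }
    ld <- ld_matrix(paste0("v", seq_len(design$p)), rho_measured)

    m <- design$methods
    rej <- matrix(NA, design$reps, length(m), dimnames = list(NULL, m))
    est <- matrix(NA_real_, design$reps, 2,
                  dimnames = list(NULL, c("fliml", "sliml")))
    r_star <- rep(NA_integer_, design$reps)
    fails <- 0L

    for (b in seq_len(design$reps)) {
      seed_b <- rep_seeds[(ti - 1L) * design$reps + b]
      res <- tryCatch(suppressWarnings(
        simulate_one(truth, n, seed_b, ld, r_assumed, nu, design)),
        error = function(e) NULL)
      if (is.null(res)) { fails <- fails + 1L; next }
      rej[b, ] <- res$reject[m]
      est[b, ] <- res$est
      r_star[b] <- res$r_star
    }
    if (fails > 0.05 * design$reps) {
      stop("more than 5% of replications failed (", fails, " of ",
           design$reps, ")", call. = FALSE)
    }
    for (meth in m) {
      rate <- mean(rej[, meth], na.rm = TRUE)
      n_ok <- sum(!is.na(rej[, meth]))
      point <- if (meth %in% colnames(est)) est[, meth] else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        model = design$model, theta = theta_true,
        f_target = if (!is.null(design$f_target)) design$f_target else NA,
        n = n, method = meth,
        rejection_rate = rate,
        bias = if (!is.null(point)) mean(point - theta_true, na.rm = TRUE)
               else NA_real_,
        rmse = if (!is.null(point))
                 sqrt(mean((point - theta_true)^2, na.rm = TRUE))
               else NA_real_,
        median_r_star = if (meth == "sliml")
                          stats::median(r_star, na.rm = TRUE)
                        else NA_real_,
        reps_ok = n_ok,
        mc_se = sqrt(rate * (1 - rate) / max(n_ok, 1)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "design") <- design
  class(out) <- c("fmr_simresult", "data.frame")
  out
}

# one replication of the design pipeline; returns rejection indicators,
# point estimates, and the S-LIML selected count
simulate_one <- function(truth, n, seed_b, ld, r_assumed, nu, design) {
  vhat <- noisy_variant_variances(truth, n, seed = seed_b)
  varz <- build_variant_covariance(ld, vhat)
  loadings <- estimate_loadings(varz, r_assumed)
  data <- draw_summary_stats(truth, n_x = n, n_y = n, seed = seed_b + 1L)
  ms <- build_moment_system(data, loadings, varz)
  theta0 <- design$theta0_test
  alpha <- design$alpha
  reject <- c(fliml = NA, far = NA, flm = NA, fclr = NA, sliml = NA)
  est <- c(fliml = NA_real_, sliml = NA_real_)
  r_star <- NA_integer_

  if ("fliml" %in% design$methods) {
    fit <- fit_fliml(ms, alpha = alpha)
    est["fliml"] <- fit$theta
    reject["fliml"] <- theta0 < fit$ci_low || theta0 > fit$ci_high
  }
  if ("far" %in% design$methods) {
    reject["far"] <- ar_test(theta0, ms)$p_value < alpha
  }
  if ("flm" %in% design$methods) {
    reject["flm"] <- lm_test(theta0, ms)$p_value < alpha
  }
  if ("fclr" %in% design$methods) {
    reject["fclr"] <- clr_test(theta0, ms)$p_value < alpha
  }
  if ("sliml" %in% design$methods) {
    sl <- tryCatch({
      selection <- pretest_factors(ms, nu = nu)
      fit_s <- fit_sliml(ms, selection, alpha = alpha)
      ct <- conditional_test(theta0, fit_s, alpha = alpha,
                             n_draws = design$sliml_draws,
                             seed = seed_b + 2L)
      list(reject = ct$reject, est = fit_s$theta_s,
           r_star = selection$r_star)
    }, error = function(e) NULL)
    if (!is.null(sl)) {
      reject["sliml"] <- sl$reject
      est["sliml"] <- sl$est
      r_star <- sl$r_star
    }
  }
  list(reject = reject, est = est, r_star = r_star)
}

#' @export
print.fmr_simresult <- function(x, ...) {
  cat("Monte-Carlo results (", attr(x, "design")$reps, "reps )\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
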