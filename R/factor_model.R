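#' Estimate rescaled factor loadings by principal components
#'
#' The loadings of an approximate factor model Z = Lambda f + e are estimated
#' from the variant variance-covariance matrix: the top-r eigenvectors of
#' var(Z), scaled by sqrt(p), give a preliminary Lambda_bar, which is then
#' rescaled so that p^-1 t(Lambda_hat) Lambda_hat = I_r. Loadings (and hence
#' the factors) are identified only up to an r x r rotation; every downstream
#' statistic in this package is rotation-invariant, so no rotation is chosen
#' beyond a reproducible sign convention (largest-magnitude entry of each
#' column positive).
#'
#' @param varz An `fmr_varz` variant covariance (see
#'   [build_variant_covariance()]) or a plain symmetric PSD matrix.
#' @param r Number of factors, `1 <= r < p`.
#' @return Object of class `fmr_loadings`: list with `loadings` (p x r),
#'   `eigenvalues` (all p, descending), `r`, and `explained_share`
#'   (cumulative share of variance carried by the top r eigenvalues).
#' @export
estimate_loadings <- function(varz, r) {
  v <- if (inherits(varz, "fmr_varz")) varz$matrix else as.matrix(varz)
  p <- nrow(v)
  if (r >= p || r < 1) stop("require 1 <= r < p", call. = FALSE)
  ed <- eigen((v + t(v)) / 2, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  if (vals[r] < 1e-12 * vals[1]) {
    warning("requested r exceeds the numerical rank of var(Z)", call. = FALSE)
  }
  lam_bar <- ed$vectors[, seq_len(r), drop = FALSE] * sqrt(p)
  # rescale so that p^-1 Lambda' Lambda = I_r (a no-op for exact
  # eigenvectors, but kept so any column scaling convention is immaterial)
  gram <- crossprod(lam_bar) / p
  gs <- eigen((gram + t(gram)) / 2, symmetric = TRUE)
  gram_inv_sqrt <- gs$vectors %*% (1 / sqrt(gs$values) * t(gs$vectors))
  lam <- lam_bar %*% gram_inv_sqrt
  # deterministic column signs across eigen-solvers
  for (j in seq_len(r)) {
    k <- which.max(abs(lam[, j]))
    if (lam[k, j] < 0) lam[, j] <- -lam[, j]
  }
  structure(list(loadings = lam, eigenvalues = vals, r = as.integer(r),
                 explained_share = sum(vals[seq_len(r)]) / sum(vals)),
            class = "fmr_loadings")
}

#' @export
print.fmr_loadings <- function(x, ...) {
  cat("factor loadings: p =", nrow(x$loadings), " r =", x$r,
      sprintf(" (%.1f%% of variance)\n", 100 * x$explained_share))
  invisible(x)
}

#' Choose the number of factors from the eigenvalue spectrum
#'
#' Advisory helpers mirroring scree-plot practice: `gap` returns the r
#' maximizing the eigenvalue ratio lambda_r / lambda_(r+1) over
#' `1 <= r <= r_max`; `variance_threshold` returns the smallest r whose
#' cumulative eigenvalue share reaches `threshold`.
#'
#' The number of factors is a modelling input for inference; these helpers
#' only assist its choice. Over-selecting r is generally safer than
#' under-selecting.
#'
#' @param eigenvalues Non-negative eigenvalues in descending order.
#' @param method `"gap"` or `"variance_threshold"`.
#' @param threshold Cumulative-share target for `variance_threshold`
#'   (default 0.99).
#' @param r_max Largest r considered by the gap method
#'   (default `min(p - 1, 30)`).
#' @return Integer r. The gap method signals a `"fmr_no_gap"` error when all
#'   eigenvalues are equal (no gap exists); supply r explicitly in that case.
#' @export
select_num_factors <- function(eigenvalues,
                               method = c("gap", "variance_threshold"),
                               threshold = 0.99,
                               r_max = min(length(eigenvalues) - 1L, 30L)) {
  method <- match.arg(method)
  p <- length(eigenvalues)
  stopifnot(p >= 2)
  if (any(diff(eigenvalues) > 1e-12 * max(eigenvalues))) {
    stop("eigenvalues must be in descending order", call. = FALSE)
  }
  if (any(eigenvalues < -1e-12 * max(abs(eigenvalues)))) {
    stop("eigenvalues must be non-negative", call. = FALSE)
  }
  if (method == "gap") {
    if (diff(range(eigenvalues)) <= 1e-12 * max(eigenvalues)) {
      cond <- structure(
        class = c("fmr_no_gap", "error", "condition"),
        list(message = "no-gap: all eigenvalues equal; supply r explicitly",
             call = sys.call(-1)))
      stop(cond)
    }
    idx <- seq_len(min(r_max, p - 1L))
    ratios <- eigenvalues[idx] / pmax(eigenvalues[idx + 1L], .Machine$double.eps)
    as.integer(which.max(ratios))
  } else {
    shares <- cumsum(eigenvalues) / sum(eigenvalues)
    as.integer(which(shares >= threshold - 1e-12)[1])
  }
}

#' Factor-level covariance of the variant covariance matrix
#'
#' Omega0_hat = t(Lambda_hat) var(Z) Lambda_hat, symmetrized. This r x r
#' matrix is the covariance of the estimated factors and the weighting
#' anchor for all moment-based statistics.
#'
#' @param loadings An `fmr_loadings` object.
#' @param varz An `fmr_varz` or plain symmetric matrix, same p.
#' @return Object of class `fmr_moments` with element `omega0`.
#' @export
factor_moments <- function(loadings, varz) {
  v <- if (inherits(varz, "fmr_varz")) varz$matrix else as.matrix(varz)
  stopifnot(nrow(v) == nrow(loadings$loadings))
  om <- crossprod(loadings$loadings, v %*% loadings$loadings)
  structure(list(omega0 = (om + t(om)) / 2), class = "fmr_moments")
}

# symmetric inverse square root via eigendecomposition; errors with the
# matrix name when not positive definite
sym_inv_sqrt <- function(m, name = deparse(substitute(m))) {
  ed <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (any(ed$values <= 0)) {
    stop(name, " is not positive definite", call. = FALSE)
  }
  ed$vectors %*% (1 / sqrt(ed$values) * t(ed$vectors))
}

# principal angles between column spans of two matrices (radians)
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1))
}
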