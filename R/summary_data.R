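#' Read GWAS summary associations from a TSV file
#'
#' Parses a tab- (or general whitespace-) delimited summary-statistics file
#' into per-variant records. The canonical column names are `variant_id`,
#' `position`, `effect_allele`, `other_allele`, `beta`, `se`, `n`; files with
#' different headers are accommodated through `column_map`.
#'
#' Rows with a missing `beta` or `se` are dropped; the number of dropped rows
#' is reported via a message and attached as the `"n_dropped"` attribute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   names used in the file, e.g. `c(beta = "b", se = "se_b")`. Unmapped
#'   canonical names are looked up verbatim.
#' @param sep Field separator, default `"\t"`.
#'
#' @return A `data.frame` with canonical columns, one row per retained
#'   variant, of class `fmr_records`.
#' @export
read_summary_associations <- function(path, column_map = character(0),
                                      sep = "\t") {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  canonical <- c("variant_id", "position", "effect_allele", "other_allele",
                 "beta", "se", "n")
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  lookup <- function(canon) {
    if (canon %in% names(column_map)) column_map[[canon]] else canon
  }
  cols <- vapply(canonical, lookup, character(1))
  missing_req <- required[!cols[required] %in% names(raw)]
  if (length(missing_req) > 0L) {
    stop("missing required column(s): ",
         paste(cols[missing_req], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(variant_id = as.character(raw[[cols["variant_id"]]]),
                    stringsAsFactors = FALSE)
  out$position <- if (cols["position"] %in% names(raw)) {
    as.integer(raw[[cols["position"]]])
  } else NA_integer_
  out$effect_allele <- toupper(as.character(raw[[cols["effect_allele"]]]))
  out$other_allele <- toupper(as.character(raw[[cols["other_allele"]]]))
  out$beta <- as.numeric(raw[[cols["beta"]]])
  out$se <- as.numeric(raw[[cols["se"]]])
  out$n <- if (cols["n"] %in% names(raw)) as.integer(raw[[cols["n"]]]) else NA_integer_

  bad_allele <- !out$effect_allele %in% c("A", "C", "G", "T") |
    !out$other_allele %in% c("A", "C", "G", "T")
  if (any(bad_allele)) {
    stop("non-ACGT allele code in row(s): ",
         paste(utils::head(which(bad_allele), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(out$effect_allele == out$other_allele)) {
    stop("effect and other allele identical for some variants", call. = FALSE)
  }
  if (any(out$se < 0, na.rm = TRUE)) {
    stop("negative standard errors present", call. = FALSE)
  }

  keep <- !is.na(out$beta) & !is.na(out$se)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) dropped for missing beta/se")
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("fmr_records", "data.frame")
  out
}

#' Read an LD (variant correlation) matrix
#'
#' Accepts either a square matrix layout with a header row of variant IDs, or
#' a long format with columns `id1`, `id2`, `r`. Long-format input is
#' symmetrized; missing pairs default to correlation 0 and the diagonal is set
#' to 1.
#'
#' @param path Path to the matrix file.
#' @param format `"auto"` (default), `"matrix"` or `"long"`.
#' @return An object of class `fmr_ld`: list with `variant_ids` and the
#'   correlation matrix `rho`.
#' @export
read_ld_matrix <- function(path, format = c("auto", "matrix", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("LD matrix file not found: ", path, call. = FALSE)
  header <- scan(path, what = character(), nlines = 1, quiet = TRUE,
                 sep = if (grepl(",", readLines(path, n = 1L))) "," else "")
  if (format == "auto") {
    format <- if (length(header) == 3L &&
                  tolower(header[3]) %in% c("r", "rho", "cor", "correlation")) {
      "long"
    } else "matrix"
  }
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else ""
  if (format == "long") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    ids <- unique(c(tab[[1]], tab[[2]]))
    p <- length(ids)
    rho <- diag(1, p)
    dimnames(rho) <- list(ids, ids)
    i <- match(tab[[1]], ids); j <- match(tab[[2]], ids)
    rho[cbind(i, j)] <- tab[[3]]
    rho[cbind(j, i)] <- tab[[3]]
    diag(rho) <- 1
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE)
    rho <- as.matrix(tab)
    ids <- colnames(rho)
    dimnames(rho) <- list(ids, ids)
  }
  ld_matrix(ids, rho)
}

#' Construct an LD matrix object
#'
#' @param variant_ids Character vector of variant identifiers.
#' @param rho Symmetric correlation matrix with unit diagonal, entries in
#'   `[-1, 1]`, one row/column per variant.
#' @return An object of class `fmr_ld`.
#' @export
ld_matrix <- function(variant_ids, rho) {
  rho <- as.matrix(rho)
  p <- length(variant_ids)
  stopifnot(nrow(rho) == p, ncol(rho) == p)
  if (max(abs(rho - t(rho))) > 1e-8) {
    stop("LD matrix is not symmetric", call. = FALSE)
  }
  rho <- (rho + t(rho)) / 2
  if (max(abs(diag(rho) - 1)) > 1e-6) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  if (max(abs(rho)) > 1 + 1e-8) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  structure(list(variant_ids = as.character(variant_ids), rho = rho),
            class = "fmr_ld")
}

# palindromic = strand-ambiguous allele pair (A/T or C/G)
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics against an LD matrix
#'
#' Restricts both association tables to the variants shared with the LD
#' matrix (kept in LD-matrix order), aligns the outcome effect allele to the
#' exposure effect allele (flipping the outcome beta sign where the allele
#' pair is swapped), drops strand-ambiguous palindromic variants, and drops
#' variants whose allele pairs can be reconciled neither by match nor by swap.
#'
#' @param exposure,outcome `fmr_records` data frames
#'   (see [read_summary_associations()]).
#' @param ld An `fmr_ld` object.
#' @return List of class `fmr_harmonized` with elements `exposure`,
#'   `outcome` (aligned records), `ld` (subset LD matrix), and counts
#'   `n_palindromic`, `n_irreconcilable`.
#' @export
harmonize <- function(exposure, outcome, ld) {
  common <- intersect(ld$variant_ids,
                      intersect(exposure$variant_id, outcome$variant_id))
  if (length(common) == 0L) {
    stop("no variants shared between exposure, outcome and LD matrix",
         call. = FALSE)
  }
  ids <- ld$variant_ids[ld$variant_ids %in% common]
  ex <- exposure[match(ids, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(ids, outcome$variant_id), , drop = FALSE]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele) |
    is_palindromic(ou$effect_allele, ou$other_allele)
  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  irrec <- !pal & !same & !swapped
  if (any(irrec)) {
    warning(sum(irrec), " variant(s) dropped: allele pairs irreconcilable",
            call. = FALSE)
  }
  keep <- !pal & !irrec
  ids <- ids[keep]
  if (length(ids) == 0L) {
    stop("no variants remain after harmonization", call. = FALSE)
  }
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  flip <- swapped[keep]
  ou$beta[flip] <- -ou$beta[flip]
  tmp <- ou$effect_allele[flip]
  ou$effect_allele[flip] <- ou$other_allele[flip]
  ou$other_allele[flip] <- tmp
  sel <- match(ids, ld$variant_ids)
  rownames(ex) <- rownames(ou) <- NULL
  structure(list(exposure = ex, outcome = ou,
                 ld = ld_matrix(ids, ld$rho[sel, sel, drop = FALSE]),
                 n_palindromic = sum(pal),
                 n_irreconcilable = sum(irrec)),
            class = "fmr_harmonized")
}

#' Convert per-allele regression coefficients to the covariance scale
#'
#' A univariable (marginal) regression coefficient beta_j relates to the
#' variant-trait covariance delta_j through delta_j = beta_j * var(Z_j).
#'
#' @param beta Numeric vector of per-allele marginal coefficients.
#' @param variant_variances Positive numeric vector of variant (dosage)
#'   variances, same length.
#' @return Numeric vector of covariances delta.
#' @export
beta_to_covariance <- function(beta, variant_variances) {
  stopifnot(length(beta) == length(variant_variances))
  if (any(variant_variances <= 0)) {
    stop("variant variances must be strictly positive", call. = FALSE)
  }
  beta * variant_variances
}

#' Allele-dosage variance under Hardy-Weinberg equilibrium
#'
#' var(Z_j) = 2 f_j (1 - f_j) for effect-allele frequency f_j.
#'
#' @param freq Numeric vector of allele frequencies in (0, 1).
#' @return Numeric vector of dosage variances.
#' @export
variance_from_frequency <- function(freq) {
  if (any(freq <= 0 | freq >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  2 * freq * (1 - freq)
}

#' Approximate linear-model coefficients from logistic coefficients
#'
#' For a binary outcome with case fraction mu, a small-effect univariable
#' logistic coefficient approximates the linear-regression coefficient of
#' the 0/1 outcome after scaling by the Bernoulli variance:
#' beta_lin = beta_logit * mu * (1 - mu).
#'
#' @param beta_logit Numeric vector of log-odds-ratio coefficients.
#' @param case_fraction Scalar case fraction in (0, 1).
#' @return Numeric vector of approximate linear coefficients.
#' @export
logit_to_linear <- function(beta_logit, case_fraction) {
  if (length(case_fraction) != 1L || is.na(case_fraction) ||
      case_fraction <= 0 || case_fraction >= 1) {
    stop("case_fraction must be a scalar strictly in (0, 1)", call. = FALSE)
  }
  beta_logit * case_fraction * (1 - case_fraction)
}

#' Nearest positive semi-definite repair by eigenvalue clipping
#'
#' Clips eigenvalues of a symmetric matrix at a small floor relative to the
#' largest eigenvalue (1e-8 * lambda_max, or 0 when all eigenvalues are
#' non-positive). If the input is already PSD it is returned unchanged.
#'
#' @param m Symmetric numeric matrix.
#' @param tol Symmetry tolerance, default `1e-8` (relative).
#' @return Symmetric PSD matrix of the same dimension.
#' @export
nearest_psd <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > tol * scale) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  ed <- eigen(m, symmetric = TRUE)
  floor_val <- 1e-8 * max(ed$values[1], 0)
  if (ed$values[length(ed$values)] >= floor_val) return(m)
  vals <- pmax(ed$values, floor_val)
  out <- ed$vectors %*% (vals * t(ed$vectors))
  (out + t(out)) / 2
}

#' Build the variant variance-covariance matrix from LD and variances
#'
#' Combines a variant correlation matrix with per-variant variances into
#' cov(Z)_jk = rho_jk * sqrt(var_j var_k), followed by a PSD repair
#' (eigenvalue clipping) so that downstream eigen-analysis is well posed.
#'
#' @param ld An `fmr_ld` object.
#' @param variant_variances Positive numeric vector, one entry per variant in
#'   LD-matrix order.
#' @return Object of class `fmr_varz`: list with `variant_ids` and the PSD
#'   covariance `matrix`.
#' @export
build_variant_covariance <- function(ld, variant_variances) {
  p <- length(ld$variant_ids)
  if (length(variant_variances) != p) {
    stop("variant_variances length does not match LD matrix dimension",
         call. = FALSE)
  }
  if (any(variant_variances <= 0)) {
    stop("variant variances must be strictly positive", call. = FALSE)
  }
  s <- sqrt(variant_variances)
  v <- ld$rho * tcrossprod(s)
  structure(list(variant_ids = ld$variant_ids, matrix = nearest_psd(v)),
            class = "fmr_varz")
}

#' Assemble a harmonized summary dataset on the covariance scale
#'
#' @param harmonized An `fmr_harmonized` object from [harmonize()].
#' @param variant_variances Positive vector of dosage variances in LD order;
#'   alternatively supply `freq` and variances are derived under
#'   Hardy-Weinberg equilibrium.
#' @param var_x,var_y Trait variances (exposure, outcome).
#' @param n_x,n_y Sample sizes; default to the per-file medians when present.
#' @param freq Optional effect-allele frequencies (used when
#'   `variant_variances` is missing).
#' @param case_fraction Optional case fraction for a binary outcome; when
#'   given, outcome betas are first mapped from the logit to the linear scale
#'   via [logit_to_linear()].
#' @return Object of class `fmr_dataset` holding `delta_x`, `delta_y` on the
#'   covariance scale together with sample sizes, trait variances, variant
#'   variances and variant IDs.
#' @export
summary_dataset <- function(harmonized, variant_variances = NULL,
                            var_x = 1, var_y = 1,
                            n_x = NULL, n_y = NULL,
                            freq = NULL, case_fraction = NULL) {
  stopifnot(inherits(harmonized, "fmr_harmonized"))
  ids <- harmonized$ld$variant_ids
  p <- length(ids)
  if (is.null(variant_variances)) {
    if (is.null(freq)) {
      stop("supply variant_variances or allele frequencies", call. = FALSE)
    }
    variant_variances <- variance_from_frequency(freq)
  }
  stopifnot(length(variant_variances) == p)
  beta_x <- harmonized$exposure$beta
  beta_y <- harmonized$outcome$beta
  if (!is.null(case_fraction)) {
    beta_y <- logit_to_linear(beta_y, case_fraction)
  }
  if (is.null(n_x)) n_x <- stats::median(harmonized$exposure$n, na.rm = TRUE)
  if (is.null(n_y)) n_y <- stats::median(harmonized$outcome$n, na.rm = TRUE)
  if (!is.finite(n_x) || !is.finite(n_y) || n_x < 2 || n_y < 2) {
    stop("sample sizes n_x, n_y must be >= 2 (supply explicitly if absent ",
         "from the input files)", call. = FALSE)
  }
  new_summary_dataset(ids,
                      beta_to_covariance(beta_x, variant_variances),
                      beta_to_covariance(beta_y, variant_variances),
                      n_x = n_x, n_y = n_y, var_x = var_x, var_y = var_y,
                      variant_variances = variant_variances)
}

# low-level constructor used by the simulator and by summary_dataset()
new_summary_dataset <- function(variant_ids, delta_x, delta_y, n_x, n_y,
                                var_x, var_y, variant_variances) {
  p <- length(variant_ids)
  stopifnot(length(delta_x) == p, length(delta_y) == p,
            length(variant_variances) == p,
            var_x > 0, var_y > 0, n_x >= 2, n_y >= 2)
  structure(list(variant_ids = as.character(variant_ids),
                 delta_x = as.numeric(delta_x),
                 delta_y = as.numeric(delta_y),
                 n_x = round(as.numeric(n_x)), n_y = round(as.numeric(n_y)),
                 var_x = var_x, var_y = var_y,
                 variant_variances = as.numeric(variant_variances)),
            class = "fmr_dataset")
}

#' @export
print.fmr_dataset <- function(x, ...) {
  cat("cis-MR summary dataset:", length(x$variant_ids), "variants\n")
  cat("  n_x =", x$n_x, " n_y =", x$n_y,
      " var(X) =", format(x$var_x), " var(Y) =", format(x$var_y), "\n")
  invisible(x)
}

#' Write a summary dataset as a TSV bundle with a JSON sidecar
#'
#' The vectors go to `<path>.tsv` (variant_id, delta_x, delta_y,
#' variant_variance); the scalars (n_x, n_y, var_x, var_y) go to
#' `<path>.json`.
#'
#' @param dataset An `fmr_dataset`.
#' @param path Output stem (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_summary_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fmr_dataset"))
  tsv <- paste0(path, ".tsv"); json <- paste0(path, ".json")
  utils::write.table(
    data.frame(variant_id = dataset$variant_ids,
               delta_x = dataset$delta_x, delta_y = dataset$delta_y,
               variant_variance = dataset$variant_variances),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset[c("n_x", "n_y", "var_x", "var_y")],
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}

#' Read a summary dataset written by [write_summary_dataset()]
#'
#' @param path Stem used when writing.
#' @return An `fmr_dataset`.
#' @export
read_summary_dataset <- function(path) {
  tab <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_summary_dataset(tab$variant_id, tab$delta_x, tab$delta_y,
                      n_x = sc$n_x, n_y = sc$n_y,
                      var_x = sc$var_x, var_y = sc$var_y,
                      variant_variances = tab$variant_variance)
}

#' Restrict records to a cis window around a gene
#'
#' Keeps variants with 1-based positions inside the closed interval
#' `[gene_start - window_kb*1000, gene_end + window_kb*1000]`.
#'
#' @param records An `fmr_records` data frame with a `position` column.
#' @param gene_start,gene_end Gene boundaries (1-based basepairs).
#' @param window_kb Flank width in kilobases (default 100).
#' @return The filtered records.
#' @export
cis_window <- function(records, gene_start, gene_end, window_kb = 100) {
  stopifnot(gene_start <= gene_end, window_kb >= 0)
  lo <- gene_start - window_kb * 1000
  hi <- gene_end + window_kb * 1000
  keep <- !is.na(records$position) & records$position >= lo &
    records$position <= hi
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
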