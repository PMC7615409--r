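# shared fixtures: all built in code, no stored data

# a random but internally consistent moment system (direct construction,
# bypassing the estimation pipeline) for property tests of the test statistics
random_moment_system <- function(seed, r = 4) {
  set.seed(seed)
  a <- matrix(rnorm(r * r), r)
  omega0 <- crossprod(a) + diag(r) * 0.5
  structure(list(g_y = rnorm(r, sd = 0.05), G_hat = rnorm(r, sd = 0.3),
                 omega0 = omega0,
                 sigma_v2 = runif(1, 0.5, 1.5),
                 sigma_e2 = runif(1, 0.5, 1.5),
                 n_x = sample(2000:20000, 1), n_y = sample(2000:20000, 1),
                 r = as.integer(r), var_x = 1, var_y = 1),
            class = "fmr_moment_system")
}

# moment system derived from a synthetic region through the full pipeline
pipeline_moment_system <- function(seed, p = 40, r = 3, f_target = 20,
                                   theta0 = 0, exact_varz = FALSE) {
  truth <- synth_region(p = p, r = r, seed = seed, theta0 = theta0)
  n <- calibrate_n(truth, f_target)
  varz <- if (exact_varz) {
    structure(list(variant_ids = paste0("v", seq_len(p)),
                   matrix = truth$var_z), class = "fmr_varz")
  } else {
    ld <- ld_matrix(paste0("v", seq_len(p)), truth$rho)
    build_variant_covariance(ld, noisy_variant_variances(truth, n, seed))
  }
  loadings <- estimate_loadings(varz, r)
  data <- draw_summary_stats(truth, n, n, seed = seed + 1L)
  suppressWarnings(build_moment_system(data, loadings, varz))
}

# write a small summary-statistics TSV; returns the path
write_sumstats_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# canonical 5-variant exposure/outcome/LD fixture used by the io tests
toy_region_files <- function(dir = tempfile()) {
  dir.create(dir)
  ids <- paste0("rs", 1:5)
  exposure <- data.frame(
    variant_id = ids, position = c(100, 200, 300, 400, 500) + 1e6,
    effect_allele = c("A", "C", "G", "T", "A"),
    other_allele = c("G", "T", "A", "C", "T"),  # rs5 is A/T palindromic
    beta = c(0.10, -0.05, 0.08, 0.02, 0.04),
    se = c(0.01, 0.01, 0.02, 0.01, 0.01), n = 5000)
  outcome <- exposure
  outcome$beta <- c(0.02, -0.01, 0.015, 0.005, 0.01)
  outcome$n <- 8000
  # rs3 alleles swapped in the outcome file
  outcome$effect_allele[3] <- "A"; outcome$other_allele[3] <- "G"
  outcome$beta[3] <- -outcome$beta[3]
  set.seed(99)
  m <- matrix(runif(25, -0.2, 0.2), 5); m <- (m + t(m)) / 2; diag(m) <- 1
  m <- factormr::nearest_psd(m)
  s <- sqrt(diag(m)); m <- m / tcrossprod(s); diag(m) <- 1
  ld_path <- file.path(dir, "ld.tsv")
  write.table(setNames(as.data.frame(m), ids), ld_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(exposure = write_sumstats_tsv(exposure, file.path(dir, "exp.tsv")),
       outcome = write_sumstats_tsv(outcome, file.path(dir, "out.tsv")),
       ld = ld_path, ids = ids, dir = dir)
}
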