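Package: factormr
Title: Factor-Based Conditional Inference for cis-Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("factormr", "developers", email = "factormr@example.org",
           role = c("aut", "cre"))
Description: Conditional inference for cis-Mendelian randomization with many
    correlated genetic variants from a single gene region. Latent genetic
    factors are estimated from a variant variance-covariance matrix by
    principal components and used as instrumental variables for a causal
    effect on the trait-covariance scale. Provides the factor-LIML point
    estimator with Wald inference, identification-robust factor tests
    (Anderson-Rubin, Lagrange multiplier, conditional likelihood ratio) with
    confidence sets by test inversion, a selective-inference test that
    adjusts for pre-screening of factors on relevance, a Sargan-Hansen
    heterogeneity diagnostic, GWAS summary-statistic harmonization helpers,
    and a Monte-Carlo engine for synthetic cis regions under weak, invalid,
    or mismeasured-correlation instrument designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
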