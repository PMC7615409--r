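---
title: "factormr: models, numerical choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{factormr: models, numerical choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical content: the
models it fits, the approximations it makes, the tunable parameters that
matter, and the design decisions taken where more than one reasonable
implementation existed. It states no empirical numbers beyond what the test
suite and the worked example in the README themselves compute.

## 1. Model and estimands

A *cis* region supplies `p` mean-centered variant dosages
`Z = (Z_1, …, Z_p)'` assumed to follow an approximate factor model
`Z = Λ f + e` with `r` latent factors (`r` fixed and small, `p` large),
`Σ_F = E(ff')` positive definite, and weakly dependent idiosyncratic errors
`e`. The causal effect `θ₀` of exposure `X` on outcome `Y` is encoded on the
covariance scale through the proportionality `δ_Y = δ_X θ₀`, where
`δ_Xj = cov(Z_j, X)` and `δ_Yj = cov(Z_j, Y)`.

Everything the estimators consume is a **covariance-scale** quantity:
per-allele GWAS coefficients are converted by `δ_j = β_j · var(Z_j)`, with
variant variances either supplied directly or derived from effect-allele
frequencies under Hardy–Weinberg equilibrium (`2f(1−f)`). This keeps the
objects of the summary-data sampling model exact and makes the variant
variances an explicit, auditable input. For binary outcomes measured by
univariable logistic regression, the package applies the first-order
small-effect approximation `β_lin ≈ β_logit · μ(1−μ)` with `μ` the case
fraction; this is the standard linearization (the Bernoulli variance of the
outcome), accurate for the small per-variant effects typical of GWAS and
unit-tested against a logistic simulation at 10% relative tolerance.

### Two-sample summary-data law

The factor-level associations are treated as Gaussian:

    Λ'δ̂_X ~ N(Λ'δ_X, Ω₀ σ_V²/n_X),   Λ'δ̂_Y ~ N(Λ'δ_Y, Ω₀ σ_ε²/n_Y),

independent across the two (non-overlapping) samples, with
`Ω₀ = Λ' var(Z) Λ`, `σ_V² = var(X) − (Λ'δ_X)'Ω₀⁻¹(Λ'δ_X)` and analogously
`σ_ε²`. This homoscedastic-error approximation is what justifies large-n
GWAS summary inference; it is also exactly the law the simulator draws from.

## 2. Loadings estimation

`estimate_loadings()` takes the top-`r` eigenvectors of `var̂(Z)` scaled by
`√p` and rescales them so `p⁻¹Λ̂'Λ̂ = I_r`. The factor-analysis literature
describes the preliminary columns as eigenvectors "multiplied by p"; since
the subsequent rescaling makes any column scaling immaterial, we scale by
`√p` for numerical hygiene and unit-test the invariance. Loadings are
identified only up to an `r×r` rotation; no rotation is chosen. Instead:

- every downstream statistic (LIML objective, AR/LM/CLR, Sargan–Hansen,
  selective machinery) is invariant to `Λ̂ → Λ̂Q` for orthogonal `Q`, which
  is unit-tested to 1e−8;
- a reproducible sign convention (largest-magnitude entry of each column
  positive) removes eigen-solver sign ambiguity from printed output.

`r` is a required analysis input. `select_num_factors()` offers the two
scree-style heuristics actually used in practice — the eigenvalue-gap ratio
`argmax_r λ_r/λ_{r+1}` (capped at `r_max = min(p−1, 30)`) and the smallest
`r` reaching a cumulative-share threshold (default 0.99) — as *advisory*
tools. When all eigenvalues are equal the gap rule raises a typed
`fmr_no_gap` error rather than guessing. Mis-specification simulations in
the engine (Model 5, `r_assumed`) mirror the finding that over-selecting
`r` is safer than under-selecting.

## 3. F-LIML and its closed form

Because `Ω̂(θ) = Ω̂₀·(σ̂_ε²/n_Y + θ²σ̂_V²/n_X)` is a scalar multiple of
`Ω̂₀`, the LIML objective is a ratio of quadratics in `θ`:

    Q(θ) = (a θ² + 2bθ + c) / (σ̂_ε²/n_Y + θ² σ̂_V²/n_X),

with `a = Ĝ'Ω̂₀⁻¹Ĝ`, `b = ĝ_Y'Ω̂₀⁻¹Ĝ`, `c = ĝ_Y'Ω̂₀⁻¹ĝ_Y`. Its
stationary points solve a quadratic equation; `fit_fliml()` evaluates both
real roots and returns the one with the smaller objective. A 200k-point
bracketed grid is the fallback for degenerate coefficients (e.g. `b ≈ 0`).
This avoids iterative-optimizer fragility entirely and is validated against
a dense grid oracle to 1e−4 in the acceptance suite. The Wald variance is
`V̂ = (Ĝ'Ω̂(θ̂)⁻¹Ĝ)⁻¹`.

Plug-in variance components can go negative in finite samples (the
literature does not address this); they are clipped at a floor of
`1e−10 · var(trait)` with a warning, and the first-stage F is flagged
unreliable when the clip triggers.

The first-stage F-statistic of the factors is reported in the
expected-F/concentration form `F = 1 + n_X·a/(r·σ̂_V²)`; its functional form
is a package definition (documented here because the simulation designs
calibrate `n` through it) and it is validated against an individual-level
regression F within 15%.

## 4. Identification-robust tests

`st_statistics()` forms `S̄ = Ω̂(θ₀)^{−1/2} ĝ(θ₀)` and
`T̄ = {Δ̂_GG − Δ̂_G Ω̂(θ₀)⁻¹Δ̂_G}^{−1/2}{Ĝ − Δ̂_G Ω̂(θ₀)⁻¹ĝ(θ₀)}` with
`Δ̂_GG = Ω̂₀σ̂_V²/n_X`, `Δ̂_G = Δ̂_GG θ₀`. Inverse square roots are
symmetric (eigendecomposition), which is what makes the statistics
rotation-invariant. From `Q_S, Q_ST, Q_T`:

- F-AR `= Q_S` ~ χ²_r;
- F-LM `= Q_ST²/Q_T` ~ χ²₁;
- F-CLR `= [Q_S − Q_T + √{(Q_S+Q_T)² − 4(Q_S Q_T − Q_ST²)}]/2`, whose null
  law is evaluated **conditional on** `Q_T`.

The CLR discriminant is the standard conditional-likelihood-ratio form; it
is non-negative by Cauchy–Schwarz and clipped at 0 within a −1e−10
tolerance. Two structural identities pin the implementation down: at
`r = 1` the three statistics coincide exactly, and as `Q_T → ∞` the CLR
p-value converges to the LM p-value. Both are tested.

The conditional p-value `P(CLR(χ²₁, χ²_{r−1}; q_T) ≥ m)` is computed by
one-dimensional adaptive quadrature: on the event boundary
`s₂* = (m − s₁)(1 + q_T/m)`, so
`p = P(χ²₁ > m) + ∫₀^m f_{χ²₁}(s₁) P(χ²_{r−1} > s₂*(s₁)) ds₁`,
with a seeded Monte-Carlo path as a cross-check (they agree within 0.002 at
1e6 draws in the acceptance suite).

Confidence sets come from inversion over a 2001-point grid (default bracket
`θ̂ ± 20·se` from a preliminary F-LIML fit), endpoints refined by bisection
to 1e−4. Disconnected sets are reported as multiple intervals; sets touching
the bracket are flagged possibly unbounded — the expected AR behavior under
irrelevant instruments.

## 5. Selective inference (S-LIML)

Pre-tests screen each estimated factor with `T̂_j = Ĝ_j/√(Δ̂_GG)_jj`
against `c_ν = Φ⁻¹(1−ν/2)`; the threshold is strict (`|T̂_j| = c_ν` is not
selected), and the published threshold expression is read as the
standard-normal quantile (the CDF reading is a typo: a CDF value cannot
threshold a |t|-statistic). The default `ν = 0.01` matches applied practice
at strong instruments; the F-adaptive rule (0.1 at F≈2, 0.05 at F≈5, 0.01 at
F≥10) is the simulator default. When nothing passes, the package refuses to
fit S-LIML and points to the identification-robust tests.

S-LIML is F-LIML on the projected system (`Ω̂₀`, `ĝ_Y`, `Ĝ` restricted to
the selected block; the scalar variance components are kept from the full
system, which estimates the same population scalars). The selective test of
`H₀: θ = θ₀` conditions on the selection event and on
`U = T̂ − Ĉ_G V̂_S⁻¹ θ̂_S`, the sufficient statistic for the nuisance mean
vector; `U` is uncorrelated with `θ̂_S` under the working joint Gaussian
approximation, so the conditional law of `θ̂_S` is its unconditional
`N(θ₀, V̂_S)` truncated to the set of `θ` values whose reconstructed
pre-test vector `ū(θ) = u + Ĉ_G θ/V̂_S` reproduces the observed selection.

**A consistency choice:** the textbook display writes
`ū = u + C_G V_S^{−1/2}𝒦`, which is only compatible with the definitions of
`U` and the draw `θ(𝒦) = θ₀ + V_S^{1/2}𝒦` when `θ₀ = 0`. The package
implements the algebraically consistent `ū = u + C_G V_S⁻¹ θ(𝒦)` — required
for confidence-interval inversion at `θ₀ ≠ 0` — and keeps the literal
display form behind `form = "display"` for audit.

Monte-Carlo details: `K ~ N(0,1)` draws (default 2e5, minimum 1e4), type-7
empirical quantiles, a floor of 100 kept draws below which the test aborts
with advice to report a robust interval instead, and a single K-stream
reused across the inversion grid (common random numbers) so CI endpoints
are smooth and nested across levels. Identical seed and inputs give
identical results; this determinism is tested.

The working approximation deliberately ignores the estimation-error term of
the pre-test statistics, as in its source. The regression tests reflect its
consequences honestly: selective size is controlled at the generator
defaults, and the conditional-vs-naive contrast is demonstrated on the exact
joint-Gaussian model in a winner's-curse configuration (a borderline factor
strongly correlated with the estimate), where the unadjusted Wald test
over-rejects and the conditional test holds level. At the synthetic-region
defaults selection is nearly deterministic, so naive Wald happens to be
mildly conservative there — a green selective-size test therefore does *not*
establish that naive post-selection Wald is safe in general; the toy shows
it is not.

## 6. The synthetic-region generator

`synth_region()` states the world the calibration tests live in:

- `r` contiguous equal blocks of variants, each loading `U(0.75, 0.95)`
  (sign-coherent) on its own factor, `N(0, 0.05²)` cross-loadings —
  a stylized block-LD pattern;
- idiosyncratic scale 0.15 before unit-diagonal rescaling, leaving ≈3% of
  each variant's variance idiosyncratic, comparable to real gene regions
  where a dozen factors explain ~99% of hundreds of variants;
- dosage variances `2f(1−f)` with `f ~ U(0.05, 0.5)`;
- exposure effects at the factor level: `eta_nonzero = ⌈0.6r⌉` of the `r`
  factors carry signal (`|η| ~ U(0.5, 1)`, random signs), scaled so the
  region explains `genetic_var_x = 0.02` of the exposure variance — a
  realistic single-locus heritability for a lipid trait; instrument
  strength is then set *not* by this share but by calibrating `n` to a
  target F, exactly as in the study design the engine reproduces;
- `var(X) = var(Y) = 1`, `δ_Y = θ₀ δ_X`.

Sampling happens at the factor level (the Gaussian law above) and is lifted
to variant space by the minimum-norm solution plus an idiosyncratic residual
orthogonal to the loadings span. The lift is sufficient because every
statistic in the package depends on `δ̂` only through `Λ̂'δ̂`; the
projection identity is unit-tested. What the generator does **not** emulate:
allele-coding errors, sample overlap between the two GWAS, population
stratification, and finite-sample non-Gaussianity of `δ̂` — a green
calibration establishes correctness of the inferential machinery under the
stated sampling law, not robustness to those artifacts.

Measurement realism knobs: `noisy_variant_variances()` draws truncated
normals (variance `1/n`, bounded by the observed range);
`perturb_correlations()` implements the constant-offset (feasibility-checked
against the minimum correlation) and sign-preserving power transforms;
`apply_pleiotropy()` adds fixed local direct effects `τ/√n`, constant or
`U(−1,1)`-drawn once. Default grids: `τ ∈ {0, 0.08, 0.16, 0.32, 0.64}` and
`F ∈ {2, 5, 10, 20, 50}` are conventional anchors, configurable in
`simulation_design()`.

`run_design()` derives per-replication seeds from the master seed up front,
so results are reproducible and independent of execution order;
replication-level failures (e.g. empty selection) are tolerated up to 5%
per cell and surface as reduced `reps_ok`, never silently.

## 7. Other numerical choices and degenerate inputs

- **PSD repair** is eigenvalue clipping at `1e−8·λ_max` (not a Higham-style
  nearest-correlation iteration): downstream use is purely eigen-based, so
  the cheap repair is adequate; the Frobenius perturbation bound
  `|λ_min|·√p` is tested.
- **Sargan–Hansen degrees of freedom**: `r − 1` when evaluated at the LIML
  minimizer (one parameter estimated); `r` when evaluated at a substituted
  value such as a robust-interval midpoint, where no parameter is estimated
  — substituting costs no degree-of-freedom correction and is conservative.
  Both conventions are exposed through the `df` argument since published
  practice is ambiguous.
- **Harmonization** drops strand-ambiguous palindromic (A/T, C/G) variants
  unconditionally — no frequency-based rescue, simpler and conservative —
  flips outcome betas for swapped allele pairs, drops irreconcilable pairs
  with a warning, and is idempotent. Positions are 1-based; the *cis* window
  is the closed interval `[gene_start − W, gene_end + W]`, default
  `W = 100 kb`.
- **Variant variances for real data**: both a frequency-derived route (HWE)
  and a user-supplied route exist, because published analyses rarely state
  which was used; the choice is an explicit argument, never silent.
- Near-singular `Ω̂₀` (condition number > 1e12) aborts with advice to
  reduce `r`; `Q_T = 0` aborts the LM test (irrelevant instruments);
  a negative CLR discriminant beyond tolerance aborts rather than clips.

## 8. Known limitations

- Single exposure only; no multivariable MR, no sample-overlap correction.
- The selective test inherits the approximation error of the working joint
  Gaussian; under very weak instruments and nulls far from zero its
  selective size can drift above nominal (the identification-robust tests
  are the fallback the package recommends in exactly that regime).
- No formally consistent factor-number estimator is included; the two
  heuristics are advisory and `r` remains the analyst's call.
- LD must come as a correlation matrix; no PLINK/VCF parsing, no
  multi-ancestry LD handling, no allele-frequency imputation.
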