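---
title: "Decomposing psychiatric GWAS liability into shared and disorder-differentiating components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing psychiatric GWAS liability into shared and disorder-differentiating components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Common-variant liabilities to schizophrenia, bipolar disorder (BD) and
major depressive disorder (MDD) are strongly but incompletely correlated.
`liabsem` decomposes the three liabilities into one *shared* component and
three *disorder-differentiating* components with a common-factor structural
equation model fitted to GWAS summary statistics, and then asks whether
symptom heterogeneity among BD cases (psychosis, mood-incongruent psychosis,
mania, depression, measured on BADDS-like ordinal scales) tracks these
components via polygenic risk scores (PRS).

The pipeline is:

1. **sumstats** — read, harmonize and filter the three GWAS to one aligned
   panel (reference-allele orientation, strand resolution, removal of
   palindromic variants; MAF > 1%, info ≥ 0.7 in every study, extended MHC
   chr6:25–35 Mb excluded, positions 1-based and the interval closed).
2. **ldsc** — LD score regression: per-study SNV heritabilities (slope of
   χ² on *N*ℓ/*M*), cross-trait genetic covariances (slope of *z₁z₂* on
   √(*N₁N₂*)ℓ/*M*), free intercepts absorbing confounding and
   sample-overlap, and a 200-block delete-one jackknife giving the joint
   sampling covariance **V** of the 6 unique elements of the genetic
   covariance matrix **S**.
3. **gsem** — the common-factor model σ_kl(θ) = λ_k λ_l (+ ψ_k on the
   diagonal), fitted by diagonally weighted least squares (DWLS),
   F(θ) = (s − σ(θ))ᵀ diag(V)⁻¹ (s − σ(θ)), with sandwich standard errors
   using the full **V**. Per variant, the covariance is bordered with the
   standardized SNV effects β_k = z_k/√n_k and two models are fitted: the
   SNV→factor regression (the *shared effect*) and, for each disorder, a
   model with simultaneous SNV→factor and SNV→disorder-residual paths
   whose direct path is the *differentiating effect*. Cross-study error
   covariances of β are taken from the LDSC intercept matrix,
   I_kl/√(n_k n_l).
4. **prs** — greedy LD clumping against target-cohort genotypes
   (r² ≤ 0.2 within ±500 kb, target MAF ≥ 0.1, info ≥ 0.7) and
   unthresholded scores Σ β_j g_ij, standardized.
5. **assoc** — logistic models for the dichotomous phenotypes (psychosis =
   BADDS-P ≥ 10; MIPS = BADDS-I ≥ 20, defined only where psychosis is
   present), proportional-odds models for the ordinal scales, all adjusted
   for age, genotyping platform and 10 principal components; conditional
   analyses (psychosis given mania, mania given psychosis), ordinal
   sensitivity analyses, a schizoaffective-exclusion sensitivity subset,
   and polychoric correlations between the BADDS scales with a
   permutation-bootstrap p value.

## Identification and numerical choices

* The factor variance is fixed at 1 in the baseline model and in per-SNV
  models (the factor's residual variance absorbs b², keeping loadings
  comparable across variants); the first loading is sign-fixed
  non-negative. A negative residual variance (Heywood case) is clamped at
  zero and flagged, never silently accepted.
* The K = 3 baseline model is just-identified (df = 0): the fitted model
  reproduces **S** exactly, and the DWLS objective at the optimum is 0 to
  numerical precision. The per-SNV shared model has df = 2 and the
  differentiating models df = 1.
* Optimization is quasi-Newton (`nlminb`) from a closed-form start
  (λ₁ = √(s₂₁s₃₁/s₃₂) and its analogues) followed by a projected
  Gauss–Newton polish; the baseline fit additionally tries the loading
  sign-pattern variants, an eigenvector start and two scaled grid starts,
  because random covariances can have local optima differing in loading
  signs. Convergence tolerance is 1e-9 on F; per-variant failures fall
  back to the closed-form two-step estimate and are flagged (fatal if more
  than 1% of fits).
* The jackknife uses 200 contiguous equal-count variant blocks;
  V = (n−1)/n · Σᵢ (θ₍₋ᵢ₎ − mean)(θ₍₋ᵢ₎ − mean)ᵀ over delete-one-block
  estimates. V is projected to the nearest positive-semidefinite matrix
  (eigenvalue flooring) when sampling noise makes it indefinite; the
  adjustment magnitude is recorded.
* LDSC applies the standard χ² cap (variants with χ² > max(80, 0.001 N)
  removed), one reweighting pass with weights
  1/(max(ℓ,1)(1 + N h̃² ℓ/M)²), and reports observed-scale heritability;
  `h2_liability_scale()` converts via the liability-threshold
  transformation but is not in the main path.
* LD scores use a ±1 Mb window, the small-sample adjustment
  r²−(1−r²)/(n−2) on every cross term, a self term fixed at 1, and a floor
  of 1 (the regression weights use max(ℓ,1) regardless).
* Clumping ties on p are broken by chromosome, position, then variant id,
  so results are independent of input row order. r² is computed on the
  target sample's genotypes with mean imputation; scores mean-impute
  missing genotypes up to a 5% per-individual cap, beyond which the score
  is set missing.
* Ordinal models use `MASS::polr`; a two-category outcome is the logistic
  likelihood and is fitted with `glm` directly. Conditioning on mania
  enters as BADDS-M category indicators rather than a linear score, to
  avoid imposing linearity on an ordinal conditioner; conditioning on
  psychosis enters as the binary flag. PRS are re-standardized within each
  analysis sample (subsets change the scale).
* The polychoric estimator is two-step (thresholds from inverse-normal
  margins, then the latent correlation by maximizing the bivariate-normal
  table likelihood). The bivariate normal CDF uses 48-point Gauss–Legendre
  quadrature of the conditioning integral (absolute error ≲ 1e-7). The p
  value is a permutation bootstrap under independence; the default
  iteration count is 10,000 (a desk-scale default — larger counts only
  sharpen small p values).

## What the generator emulates — and what it does not

`sim_config()` defines the synthetic study. Defaults are the desk-scale
design: m = 20,000 variants in LD blocks (AR(1) haplotype correlation
drawn per block from U(0.2, 0.9), block size 20, block-level allele
frequencies in U(0.05, 0.5) with small within-block jitter — LD partners
share frequencies, which is what makes high r² attainable), three
case-control studies of 5,000 cases + 5,000 controls drawn from a single
population, 50% of controls shared across studies (the source of the
positive cross-trait LDSC intercepts the model must absorb), and a
5,000-case BD target cohort.

Choices the underlying study design leaves open, fixed here once:

* **Prevalence 0.25 per disorder.** Real lifetime prevalences (~1% for
  schizophrenia) would require simulating millions of individuals to
  ascertain 5,000 cases. 0.25 keeps the liability-threshold nonlinearity
  and case ascertainment in play while a single ~21,000-person population
  supplies every study's cases and the shared control pool.
* **Liability architecture.** Shared-path coefficients (0.45, 0.40, 0.35)
  and disorder-specific variances of 0.10, i.e. liability h² of
  0.30/0.26/0.22 — inside the 7–35% observed-scale band typical of
  psychiatric GWAS after the Lee transformation at these prevalences.
  20% of variants are causal.
* **Symptom weights.** The 4×4 matrix W maps the standardized
  (shared, scz, bd, mdd) genetic scores to the four latent symptom
  scales with the cross-disorder sign pattern under test: psychosis
  +shared/+scz, incongruence +scz only, mania +shared/+bd/−mdd,
  depression +mdd/−bd, at |w| = 0.25–0.30. An a-priori power calculation
  (PRS–score correlation ≈ 0.35–0.6 at these GWAS sizes; ordinal/logistic
  SE ≈ 0.03 at n = 5,000) puts every nonzero entry at |z| ≈ 4.5–5.5, so
  sign recovery at α = .05 is expected, not marginal.
* **BADDS marginals.** Category probabilities give ~60% psychosis among BD
  cases and ~35% MIPS among the psychotic, with BADDS-I generated only
  where BADDS-P ≥ 10 (the instrument's rating rule).

The generator does **not** emulate realistic human LD maps, demography,
assortative mating, rare variants, genotyping error or imputation
uncertainty (info is 1 everywhere; the info filters are exercised by unit
fixtures). Passing tests therefore demonstrate internal statistical
correctness of the estimators under a known forward model — not robustness
to the ascertainment and technological artifacts of real cohorts.

## Validation study designs

The test suite's simulation studies (sizes chosen as the package's
desk-scale validation conditions):

* **LDSC recovery** uses prevalence = case fraction = 0.5 and liability
  h² = 0.3·π/2 ≈ 0.471, so the observed-scale target is exactly 0.30 by
  the Lee transformation; the point estimate is the mean of two forward
  replicates at m = 20,000, N = 20,000, and jackknife calibration uses 100
  forward replicates at m = 2,000, N = 2,000 (so real LD enters the
  comparison of jackknife SE with the empirical SD).
* **Null calibration** of the differentiating effects sets the specific
  variances to zero at m = 5,000. The KS uniformity check runs on p
  values thinned to one variant per LD block, because the test assumes
  independent draws and per-SNV statistics are correlated within blocks.
  The differentiating-PRS null rejection rate pools the suite over
  independently regenerated symptom noise.
* **Sign-pattern recovery** runs the full pipeline at m = 5,000 with
  3 × (3,000 + 3,000) studies and the default W, and additionally checks
  the conditional structure: the bd-differentiating association with
  mania survives conditioning on psychosis, and the scz-differentiating
  association with psychosis survives conditioning on mania.
* **Optimizer-equivalence** instances are factor-structured covariances
  with symmetric perturbation (eigenvalues kept ≥ 0.05). On arbitrary
  random covariances the DWLS objective can be nearly flat in some
  parameter directions, where agreement between two optimizers at 1e-6 is
  numerically meaningless; the factor-structured family is the regime the
  model addresses and is well-conditioned.

One generator property worth knowing when designing validation studies:
within a strong LD block, every variant's association statistic reflects
essentially one draw of the block's causal effects, so the realized
per-block polygenic signal is heavy-tailed (few effective degrees of
freedom per block). With few blocks, a single realization's χ²-vs-ℓ
relationship can deviate far from its expectation — and the block
jackknife, which resamples the realized blocks, understates that
across-realization variability. Validation studies that assert recovery in
a single realization therefore use many smaller LD blocks and a denser
causal fraction, or average replicates.

## Known limitations

* Effective sample size for the derived summary-statistic sets is recorded
  as the median per-study n — a metadata convention, not an estimate; the
  derived sets are consumed by the PRS module, which only uses betas and
  p values.
* The per-variant error covariance across studies is approximated from
  the cross-trait LDSC intercepts; this is accurate for the
  shared-control overlap the generator produces but is still an
  approximation to the full finite-sample error structure.
* Whether the differentiating models should include the SNV→factor path
  simultaneously (as here) or orthogonalize first is a modeling choice;
  the simultaneous parameterization nests the shared model and makes the
  "fully shared variant ⇒ zero differentiating effect" property exact.
* The logistic/ordinal betas are reported on the log-odds scale
  throughout. Small published effect sizes with extreme significance in
  comparable analyses suggest other scales are sometimes reported; no
  attempt is made to match any particular reporting scale.
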