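---
title: "Set-based mixed-effects score tests of gene-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-based mixed-effects score tests of gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
model, the two interaction components and their combination, the choices
made where the design was genuinely open, the synthetic cohort the tests
run on, and the numerical details that make the pipeline reproducible.

## Model and components

For a case-control outcome $y_i$, exposure $E_i$ (BMI per 5 kg/m² or a 0/1
diabetes indicator), covariates $z_i$ (age, study indicators, principal
components, optionally sex) and a gene with eQTL dosages $G_{ij}$ and
external expression weights $w_j$, the predicted expression is
$\hat{x}_i = \sum_j w_j G_{ij}$. The null logistic model is

$$\operatorname{logit} P(y_i = 1) = \alpha + \gamma' z_i + \beta_E E_i +
\beta_g \hat{x}_i .$$

The gene-by-exposure interaction is split into two parts:

1. **Fixed (burden) component.** The score for the single added term
   $\hat{x}_i E_i$ under the null fit is $U = \sum_i (y_i - \mu_i)
   \hat{x}_i E_i$, with variance $V$ the efficient information of that
   column after projecting out all null-model columns under the IRLS
   weights $\mu_i(1-\mu_i)$. $p_{fix}$ is the upper $\chi^2_1$ tail of
   $U^2/V$. This component is powerful when the per-SNP interaction effects
   line up with the expression weights — the interaction acts "through"
   predicted expression.
2. **Random (variance-component) component.** The model is refit *with*
   the $\hat{x}E$ term, and the residual per-SNP interaction columns
   $C_{ij} = G_{ij}E_i$ are tested SKAT-style:
   $Q = \sum_j\big[\sum_i (y_i-\mu_i) C_{ij}\big]^2$, whose null law is
   $\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of $C'PC$,
   $P = W - WX(X'WX)^{-1}X'W$. Conditioning on the fitted burden term is
   what makes $p_{ran}$ asymptotically independent of $p_{fix}$ — the
   prerequisite for combining them as independent uniforms. This component
   catches interactions dispersed across SNPs or misaligned with the
   weights.

Per-SNP *main* effects are deliberately not in the null model: with large
eQTL sets (95 SNPs is realistic) they would destabilize the fit, and the
$\hat{x}$ term summarizes the gene-level main effect. This mirrors
burden-style mixed-effects interaction tests and is the package's recorded
choice where the design was open.

## Adaptive combination

With $p_{fix}, p_{ran}$ independent uniforms under the null,
$T_w = -2\{w \ln p_{fix} + (1-w)\ln p_{ran}\}$ is a $w$-weighted
convolution of two $\chi^2_2$ variates, whose survival function is closed
form ($(a e^{-t/2a} - b e^{-t/2b})/(a-b)$ for weights $a=w$, $b=1-w$;
exponential at the endpoints; $\chi^2_4$ at $w=\tfrac12$). Over the grid
$w \in \{0, 0.25, 0.5, 0.75, 1\}$ the combiner takes the smallest per-$w$
p-value and reports the exact null probability that this grid minimum is as
small as observed. That probability is computed without simulation: the
complement event is the intersection of half-planes
$\{wX + (1-w)Y < t_w\}$ for $X, Y$ iid $\chi^2_2$, a convex region whose
probability reduces to a one-dimensional integral of
$\tfrac12 e^{-x/2}\,F_Y(y_{\max}(x))$; the piecewise-linear boundary
$y_{\max}$ is integrated segment by segment between its kinks so the
quadrature (`stats::integrate`, rel.tol $10^{-10}$) never straddles a
non-smooth point. The grid is the minimal symmetric one containing the
pure-fixed and pure-random endpoints; the reported `chosen_weight` is the
grid point attaining the minimum. Under simulated independent uniforms the
combined p-value is itself uniform (property-tested with a KS check), and
Fisher's $\chi^2_4$ rule is available as `method = "fisher"`.

## Mixture-of-chi-squares tail

`mixture_chisq_pvalue()` inverts the characteristic function using
Imhof's integrand. Naive adaptive quadrature over $[0, \infty)$ is
unreliable here — the integrand oscillates with asymptotic half-period
$2\pi/q$ while decaying only polynomially — so the implementation first
rescales by $\lambda_{max}$ (the tail is scale-invariant), then integrates
half-period segments one at a time and applies iterated averaging (Euler
acceleration) to the alternating partial sums, giving absolute accuracy
around $10^{-6}$ or better at a few milliseconds per call. Equal-weight
spectra short-circuit to the exact $\chi^2_k$ tail. When the result falls
below the integrator's absolute accuracy (deep tails, $p < 10^{-10}$) or
the quadrature fails, a Liu–Tang–Zhang four-moment approximation is used
instead. Eigenvalues below $10^{-8}\lambda_{max}$ are truncated to zero;
p-values are clipped to $(10^{-300}, 1]$ so downstream logarithms stay
finite. Accuracy is validated against closed forms and against
$10^7$-draw Monte-Carlo tails (agreement within 3 MC standard errors).

## Data handling choices

* **Tiered imputation QC.** Variants are kept when imputation $R^2$
  strictly exceeds the cutoff of their MAF tier: $>0.3$ above 1% MAF,
  $>0.5$ between 0.5% and 1%, $>0.99$ below. Tiers are matched half-open
  from common to rare so every variant falls in exactly one tier; MAF is
  pooled across studies (a study-specific variant would need per-study
  dosage files). Directly typed variants (no imputation $R^2$) always
  pass; an optional exact-test Hardy–Weinberg filter on hard-called
  genotypes in controls ($P < 10^{-4}$) is provided but off by default,
  because HWE on fractional imputed dosages is ill-defined.
* **Allele harmonization.** Weights whose effect/other alleles are swapped
  relative to the dosage file have their weight negated; the weighted sum
  then equals the correctly oriented one up to an additive constant (twice
  the sum of negated weights) absorbed by the intercept, and both score
  tests are exactly invariant to the coding because the exposure column is
  itself in the null design. Strand flips (A↔T, C↔G) are resolved the same
  way; strand-ambiguous pairs in non-identical orientation are dropped
  (configurable), since swap and strand flip are indistinguishable for
  them.
* **Heritability filter.** Genes enter the scan when predictive
  $R^2 \ge 0.01$, boundary inclusive.
* **Predicted expression is not re-standardized.** Any rescaling of the
  weights leaves $p_{fix}$ unchanged (score and information scale
  together), which is property-tested; keeping the raw scale preserves the
  interpretation of follow-up ORs per unit predicted expression.
* **BMI handling.** Raw BMI below 18.5 kg/m² is excluded from BMI
  analyses; the analysis scale is per 5 kg/m². Diabetes analyses keep all
  rows.
* **Scan layout.** BMI scans run separately in men and women (the
  BMI–disease association differs by sex) with BH-FDR applied within each
  exposure-by-stratum scan; diabetes scans pool the sexes with sex as a
  covariate. FDR within stratum matches per-analysis gene lists; the
  threshold defaults to 0.2.

## Follow-up analyses

Sequential conditional selection starts from the most significant
SNP-by-exposure Wald term, then repeatedly adds the next most significant
candidate conditional on everything already selected (main effects plus
interactions), stopping when the best remaining conditional p-value
reaches 0.05. Selection is forward-only (no removal step), ties go to the
smaller variant index, and non-converging candidate fits are skipped and
logged; the procedure trivially terminates within the eQTL count. No
selection-inference correction is applied — the report is descriptive.
Exposure-stratified expression associations cut BMI at control-only
quartiles (controls approximate the source population under case-control
sampling) and fit covariate-adjusted logistic models of outcome on
predicted expression within each stratum.

## The synthetic cohort

The generator exists so that every stage is testable without any external
genotype or expression resource. One scenario object holds all generative
knobs; everything flows from a single seed.

* **Genotypes**: per gene, two haplotypes from a latent Gaussian AR-1
  process (correlation `ld_rho`, default 0.5) thresholded at each
  variant's MAF (uniform on `maf_range`, default 0.05–0.5); dosage = sum.
  This produces blocky, decaying LD — not a realistic human LD map, which
  is out of the generator's scope.
* **Weights**: a `weight_sparsity` fraction of SNPs (default 0.3) get
  Gaussian weights (sd `weight_sd` = 0.15), emulating elastic-net
  selection; predictive $R^2$ is the empirical
  $\mathrm{Var}(Gw)/(\mathrm{Var}(Gw)+\sigma^2_e)$ with expression noise
  $\sigma^2_e = 1$, which lands typical $R^2$ values in the 1–15% range
  seen for real expression models.
* **Cohort**: age $\sim N(60, 8)$, sex Bernoulli(½) with a 0.2 log-OR male
  effect (toggleable), study uniform over `n_studies` = 3 with intercepts
  spanning ±0.2, `n_pcs` = 3 standard-normal PCs with 0.05 log-OR effects;
  BMI normal (27, 4.5²) truncated at 18.5 by inverse-CDF sampling;
  diabetes Bernoulli with logit $-2.2 + 0.1(\mathrm{BMI}-27)$, coupling
  the two exposures as in reality.
* **Disease**: logit = study intercept + covariate effects +
  $\beta_E E$ (default $\ln 1.25$, near reported BMI-scale main effects) +
  $\beta_g \hat{x}$ + $\tau\,\hat{x}E$ + $\sum_j u_j G_j E$ with
  $u_j \sim N(0, \theta)$ on one designated causal gene (or a fixed
  per-SNP log-OR vector when a single driving SNP is wanted). The
  intercept is calibrated by root-finding so the population prevalence
  hits its target (default 0.1, chosen for sampling efficiency rather than
  any disease's true prevalence), and cases/controls are then drawn
  retrospectively to the requested counts — matching how case-control
  consortia are actually assembled.

**Study conditions used by the validation suite** (chosen once, sized for
a desk-scale machine): null calibration uses one 10-SNP gene at 1000
cases / 1000 controls over 500 replicates (1200 for the independence
estimate, which needs more precision than a rejection rate); burden
attribution uses $\tau = 1.2$ (typical $-\log_{10} p_{fix} \approx 2$, a
moderate signal); dispersed attribution uses $\theta = 0.003$; ranking and
the worked example use dense small weights (`weight_sparsity` 1,
`weight_sd` 0.08) so the predicted-expression scale is stable across genes
and the burden term cannot saturate the logit — with sparse weights an
unlucky gene can draw a large-variance $\hat{x}$ and push fitted risks to
the boundary; sequential selection plants a single SNP×E log-OR of 0.3 in
a 6-SNP gene at 2000/2000. Main-effect recovery uses OR 1.25 at
10000/10000 and CI coverage 400 null replicates at 500/500.

What passing these simulations does *not* show: robustness to realistic
LD structure, imputation error processes, cross-study exposure
harmonization artifacts, phenotype misclassification, or population
stratification beyond simple PC adjustment — real-data analyses inherit
those caveats.

## Numerical choices and degenerate inputs

* IRLS via `stats::glm.fit` with deviance tolerance $10^{-10}$, 100
  iterations; the score vector is re-checked at the optimum.
* Rank-deficient designs (duplicated covariates) are an error naming the
  collinear columns; *constant* columns are silently absorbed by the
  intercept first, so a zero-variance exposure degrades gracefully into
  the degenerate fixed test ($V \le 10^{-12} \Rightarrow p = 1$ with a
  flag) rather than an opaque failure.
* Separation is flagged when a fitted log-OR exceeds 30 *per standard
  deviation of its column*. The guard is scale-invariant on purpose: a
  low-heritability gene has predicted expression with sd of order 0.03,
  so raw coefficients of 30+ are legitimate there and a raw-scale guard
  would discard healthy fits.
* Eigenvalue truncation at $10^{-8}\lambda_{max}$; an all-zero spectrum
  (e.g. a single column already in the null design) returns $p = 1$ with
  a degenerate flag.
* Scan determinism: given input files the entire pipeline is
  deterministic; reruns produce byte-identical result files. Result TSVs
  round-trip numerics to at least 12 significant digits.
* Out-of-range dosages are clipped to [0, 2] on load with a logged count;
  duplicate variant ids and malformed headers are errors.

## Known limitations

* The adaptive grid is a five-point stand-in where the underlying
  combination family is continuous; a finer grid changes p-values only
  marginally but costs proportionally.
* Component independence is asymptotic. At the validation sample size
  (n = 2000) the measured correlation of the two component p-values is
  indistinguishable from zero, but very small samples or near-degenerate
  genes may show finite-sample dependence.
* Exposure-permutation reference distributions are *not* used anywhere:
  permuting an uncentered exposure conditions on the residual-dosage
  correlations and systematically inflates the variance-component
  statistic, so empirical-null checks use parametric resampling of case
  status from the fitted null instead.
* PredictDB SQLite databases are not read directly; weights are consumed
  through the documented TSV dialect.
* The sequential follow-up applies no selective-inference correction, by
  design.
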