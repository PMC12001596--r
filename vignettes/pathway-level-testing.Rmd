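---
title: "Pathway-level mixed-model testing for longitudinal metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level mixed-model testing for longitudinal metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathlmm)
```

## The problem

Longitudinal metabolomic studies quantify the same set of metabolites in
the same individuals at several time points, usually under two or more
experimental conditions. Two questions recur: which metabolic functions
change over time, and which differ between conditions? Testing
metabolites one at a time and post-processing the calls with an
enrichment test answers these questions only indirectly — it ignores the
correlation between metabolites of a pathway, and it cannot detect a
pathway whose members all move a little but none significantly.

`pathlmm` tests *pathways*: named, possibly overlapping sets of
metabolites. It is a multivariate functional-class-scoring approach: a
pathway score is computed from the full quantification sub-matrix of the
pathway, and the longitudinal structure is handled by a mixed model on
that score.

## The procedure

For a study with $n$ individuals, $T$ time points (so up to $nT$
observations; incomplete designs are fine) and $m$ metabolites, with
quantification matrix $X$ and pathways $\mathcal{M}_\ell$:

1. **Scores.** For each pathway, the columns of
   $Z_\ell = (X_{ij})_{j \in \mathcal{M}_\ell}$ are centered and scaled,
   and a PCA retains the scores $A_\ell$ of the first
   $m^*_\ell = \min(F, |\mathcal{M}_\ell|)$ components, $F$ being the
   number of fixed effects under study (time and condition: $F = 2$).
   Keeping one component per fixed effect retains enough directions for
   every effect to load somewhere while keeping the multiplicity per
   pathway fixed and small.
2. **Mixed model.** Each score column $a$ is modelled as
   $a = \beta_t + \theta_d + u_i + \varepsilon$, with categorical fixed
   effects of time $\beta_t$ and condition $\theta_d$, a random
   intercept $u_i \sim N(0, \sigma_u^2)$ per individual absorbing the
   repeated-measures dependency, and i.i.d. Gaussian residuals. Each
   fixed effect is tested by a likelihood-ratio test against the model
   without it, on a $\chi^2$ reference with (levels − 1) degrees of
   freedom.
3. **Aggregation.** The $m^*_\ell$ component p-values of a pathway are
   combined with Simes' rule, $\min_j m^*_\ell\, p_{(j)} / j$, which
   controls the intersection-null type-I error under independence/PRDS
   and is robust to moderate deviations. Pathway p-values are then
   BH-adjusted per effect across pathways.

### The partial-PCA (MFA-style) variant

A global PCA ignores that observations of the same individual are more
alike than observations of different individuals. `method = "mfa"`
instead splits $Z_\ell$ into per-time-point blocks $Z^{(t)}_\ell$, runs
one PCA per block, rescales each block's scores by
$1/\sqrt{\lambda_1^{(t)}}$ (its first eigenvalue) so no time point
dominates — the standard block-balancing step of Multiple Factor
Analysis — and stacks the weighted block scores back in row order.
Only this partial-PCA first step of MFA is used; the global compromise
analysis is not needed because the stacked scores go straight into the
mixed model.

Two consequences matter in practice:

* Per-block PCAs are sign-indeterminate, so each block component is
  sign-aligned to the corresponding global-PCA loading vector (flipped
  when their dot product is negative). Without this the stacked column
  would mix arbitrary signs and be meaningless.
* Per-block centering removes the block means, i.e. exactly the
  between-time signal. The variant is therefore well suited to test the
  condition effect but structurally unable to test the time effect;
  `pathway_test()` flags those rows `mfa_block_effect_not_recommended`
  (the time coefficients on such scores are ~0 and their LRT p-values
  ~1).

## Choices the data do not dictate

* **Center + scale before every PCA.** Metabolite quantifications span
  orders of magnitude; unscaled PCA would be dominated by the most
  abundant metabolite. In the MFA variant, standardization happens
  within each block, so every partial PCA is a self-contained PCA of its
  block.
* **Block weight.** "Weighting by the first eigenvalue" can be read as
  $1/\lambda_1$ or $1/\sqrt{\lambda_1}$; the package defaults to the
  standard MFA convention $1/\sqrt{\lambda_1}$ (balances the first
  singular value of each block) and exposes
  `mfa_weight = "inv_lambda1"` for the other reading. The LRT is
  invariant to a common rescaling of a score column, so the choice only
  matters through the relative balance of blocks.
* **ML, not REML.** Both the full and the restricted models are fitted
  by maximum likelihood (`lme4::lmer(REML = FALSE)`): REML likelihoods
  of models with different fixed effects are not comparable, so a
  REML-based LRT of a fixed effect would be invalid.
* **Deterministic signs.** Every loading column is flipped so its
  largest-magnitude entry is positive, making score matrices
  reproducible across platforms. P-values are invariant to these flips.
* **Degenerate inputs.** Zero-variance metabolites are removed per
  pathway; a pathway left with fewer than two usable metabolites is
  skipped and listed in the skip report rather than silently dropped.
  Component p-values of unconverged fits are removed before Simes (with
  the multiplicity reduced accordingly); LRT statistics are clipped at 0
  (optimizer noise can make a truly-absent effect's statistic marginally
  negative); the optimizer restarts from perturbed initializations
  before a fit is flagged unconverged.
* **BH per effect.** Time and condition p-value lists are corrected
  independently: the two effects answer separate questions with
  separate significant-pathway lists.
* **Raw vs adjusted p-values.** Results carry both. Type-I error
  experiments threshold the raw Simes p-value (under a global null, BH
  would report trivial rates); power experiments threshold the
  BH-adjusted one, which is what a practitioner would use.

## The over-representation comparator

`ora_test()` implements the classical enrichment baseline with the same
mixed model at the metabolite level: each metabolite is LRT-tested
individually, significant metabolites (BH-corrected at level 0.05 by
default) are crossed with pathway membership, and each pathway gets the
one-sided Fisher exact (hypergeometric upper-tail) p-value, BH-corrected
across pathways. The background defaults to the quantified metabolites
and can be widened to a larger identifiable-metabolite list. For null
experiments `adjust_metabolites = FALSE` skips the metabolite-level
correction — with no signal present, BH would empty the significant set
and make the null rate trivially zero.

## The simulation framework

Semi-synthetic benchmarks transform a base dataset (`quant_table`) whose
null behaviour is known:

* `permute_condition()` erases the condition effect by permuting
  condition labels **across individuals** (each individual keeps one
  label, every time point follows). Permuting at the sample level would
  assign one individual two conditions, destroying the
  within-individual correlation the benchmark is supposed to preserve.
* `erase_time()` replaces each later-time observation by the
  individual's first-time observation and adds
  $b \sim N(0,\sigma_b^2)$ to all rows, with
  $\sigma_b^2 = 0.05\,(\max X - \min X)$ — a variance set to a
  range-scaled quantity, taken literally. Negative post-noise values
  are floored at 0 to keep quantifications valid; with
  quantifications spanning orders of magnitude this truncates the noise
  for near-zero metabolites and is one reason the time null is harder
  than the condition null (see Limitations).
* `inject_condition_effect()` multiplies target metabolites by a
  per-condition factor $\gamma_d$; `inject_time_effect()` rebuilds
  targets from the repeated first-time block times $\gamma_t$ plus the
  same range-scaled noise. Scenario tables `condition_gamma()` (γ = 10,
  3, 2 for the treated condition) and `time_gamma()` ((1,5,10),
  (1,2,3), (1,1.5,2), (1,1.2,1.5)) grade the effect from strong to
  weak. In the time-injection mode non-target metabolites are also
  rebuilt from the repeated first block plus same-law noise, so that
  *only* target pathways carry time signal; `nontargets = "keep"`
  leaves them untouched for users who want the stricter reading where
  the transformation is defined for targets only.
* `make_h1_dataset()` draws k = 3 pathways and injects their member
  union; `make_vsize_dataset()` injects only $\tilde p$ members of the
  largest pathway (plus k − 1 full pathways), mapping power against the
  fraction of differential members.

Because pathways overlap, injecting 3 pathways also touches members of
others. `categorize()` therefore partitions pathways into
*differential*, *overlapping* (share ≥ 1 injected metabolite — no clean
truth label) and *non-differential*; `confusion()` counts TP/FP/FN/TN on
the two clean categories only and tallies overlapping calls separately,
with PPV reported as `NA` (not 0) when nothing is called positive.
`overlap_diff_fraction()` reports, per overlapping pathway, the fraction
of its members that were injected.

## The synthetic base generator

`generate_dataset()` builds a fully synthetic stand-in for a small
longitudinal NMR study: 16 individuals in two conditions, 3 time
points, 120 metabolites, 40 overlapping pathways of size 2–32 with mean
size ≈ 6, mean pathways-per-metabolite ≈ 4 among pathway metabolites,
and one pathway pinned at size 32 so pathway-size experiments have a
well-defined target. On the log scale each value is
`mu_j + u_i + c_{obs, p(j)} + e`: uniform baselines over `(0, 3)` spread
abundances over orders of magnitude as relative quantifications are; a
random intercept (`individual_sd = 0.1`) creates the repeated-measures
dependency; a per-observation fluctuation shared within each
metabolite's home pathway calibrates the within-pathway correlation to
`pathway_corr = 0.3`, a moderate value typical of co-regulated
metabolites, on top of a residual SD of 0.2. Exponentiation makes values
positive and makes the multiplicative injected effects additive on the
log scale. The base contains **no** time or condition effect, so it
doubles as its own null calibration check.

What the generator does *not* emulate: heavy-tailed or zero-inflated
abundance distributions, quantification error correlated across
metabolites (as spectral deconvolution produces), drift over time, or
pathway catalogues with hub metabolites in dozens of pathways. Passing
benchmarks on this generator shows the machinery behaves as designed
under its own assumptions, not that the method is calibrated on any
particular real dataset.

## Problem sizes used by the shipped experiments

The packaged tests and the acceptance script run the benchmark at
deliberately modest sizes — 20 replicate bases for the type-I and
power experiments, 10 for the pathway-size curve, the default
40-pathway/120-metabolite generator throughout — chosen so a full run
completes in minutes on a single core while keeping Monte-Carlo error
small enough for the directional claims being checked (rates are pooled
over replicates and compared with allowances of twice their replicate-
level Monte-Carlo standard error).

## Known limitations

* With 16 individuals and ~46–48 observations, the $\chi^2$ reference
  for the ML likelihood-ratio test is an asymptotic approximation; it
  runs slightly hot at the nominal 5% level, which is visible mostly in
  the time test (2 numerator df, and the time-erasure noise floor adds
  non-Gaussianity). No Satterthwaite or Kenward–Roger correction is
  applied — the procedure tested is the plain LRT.
* Simes' rule is exact under independence/PRDS; principal-component
  scores carry no formal PRDS guarantee. The aggregation is used for
  its documented robustness, not a proven guarantee.
* The random structure is a single intercept per individual; random
  slopes or serial (e.g. AR1) correlation are out of scope.
* Two time points are enough to fit the model but leave the random
  intercept poorly estimated; three or more are recommended.

## A worked run

```{r example, eval = FALSE}
spec <- generator_spec(seed = 42)
base <- generate_dataset(spec)

res <- pathway_test(base$qt, base$pathways, method = "pca")
head(res)

# inject a strong condition effect into 3 pathways and re-test
sp <- scenario_spec("condition", "H1",
                    gamma_d = condition_gamma(1, c("control", "treated")),
                    seed = 7)
h1 <- make_h1_dataset(base$qt, base$pathways, sp)
res1 <- pathway_test(h1$qt, base$pathways, test_effects = "condition")
truth <- categorize(base$pathways, h1$selected_pathways,
                    h1$target_metabolites)
confusion(res1, truth, alpha = 0.05)
```
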