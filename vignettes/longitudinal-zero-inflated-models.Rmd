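---
title: "Mixed models for longitudinal microbiome abundance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed models for longitudinal microbiome abundance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal and multilevel microbiome studies collect repeated samples
per subject and measure, for every sample, counts (or relative
abundances) of hundreds of taxa together with the total sequencing
depth. Three data features dominate the analysis: library sizes vary by
orders of magnitude, counts are over-dispersed relative to the Poisson,
and many taxa show far more zeros than any count distribution predicts.
`taxamix` fits three per-taxon model families that address these
features while accounting for within-subject correlation, and wraps them
in a screening workflow over all taxa.

## Models

**NB mixed model (NBMM).** For taxon counts \(C_{ij}\) of subject \(i\)
at sample \(j\),
\[
C_{ij} \sim \mathrm{NB}(\mu_{ij}, \theta), \qquad
\log \mu_{ij} = \log T_{ij} + X_{ij}\beta + G_{ij} b_i, \qquad
b_i \sim N(0, \Psi),
\]
with dispersion \(\theta\) (variance \(\mu + \mu^2/\theta\); the Poisson
is the limit \(\theta \to \infty\)) and the log library size
\(\log T_{ij}\) as an offset. Random effects are a subject intercept and
optionally one slope; residual correlation within subject can be AR(1)
(on observation order) or compound symmetry.

**Zero-inflated NB mixed model (ZINBMM).** A structural-zero component
with probability \(p_{ij}\) is mixed with the NBMM;
\(\operatorname{logit}(p_{ij}) = Z_{ij}\alpha\;(+\,G_{ij}a_i)\) is a
logistic (optionally mixed) model.

**Zero-inflated Gaussian mixed model (ZIGMM).** Counts are transformed
to \(y = \log_2(C+1)\), proportions to
\(y = \arcsin\sqrt{C/T}\); both map zero abundance to exactly zero. The
model mixes a point mass at zero (probability \(p_{ij}\)) with a
Gaussian linear mixed model \(N(\mu_{ij}, \sigma^2)\). For transformed
counts the library-size offset lives on the response scale
(\(\log_2 T\)); for proportions an offset is meaningless and is
rejected.

## Fitting algorithms

All three fitters reduce to repeated weighted linear mixed model solves
(`nlme::lme`, with prior weights carried as a fixed variance function).

* **NBMM (penalised quasi-likelihood).** Starting from a Poisson fit,
  each sweep forms the standard log-link working response
  \(z = \eta - \mathrm{offset} + (y - \mu)/\mu\) and weights
  \(w = \mu\theta/(\theta+\mu)\), solves the working LMM, and refreshes
  \(\theta\) by Newton–Raphson on the conditional NB likelihood at the
  current fitted means (with a bracketed search fallback and clipping to
  \([10^{-3}, 10^5]\)). Iteration stops when coefficients and
  \(\log\theta\) move less than `tol` (default `1e-5`, at most 50
  sweeps). Standard errors come from the final working LMM, the usual
  PQL convention; they are not sandwich estimates.
* **ZINBMM (EM-IWLS).** The E-step computes posterior structural-zero
  responsibilities \(\xi = p / (p + (1-p)(\theta/(\theta+\mu))^\theta)\)
  at observed zeros (exactly zero at positive counts). The M-step fits
  the zero part as a fractional-response binomial IWLS (responsibilities
  are probabilities, not 0/1) — or a short PQL loop when the zero part
  has a random intercept — and refits the count part by a capped run of
  the NB sweeps with prior observation weights \(1-\xi\) multiplying the
  IWLS weights; the dispersion update is responsibility-weighted.
  Convergence is `em_tol = 1e-4` on the largest linear-scale parameter
  change, at most 100 EM iterations, 5 inner sweeps per M-step (full
  inner convergence is wasteful and the fixed point is identical).
* **ZIGMM (EM).** Identical structure with the Gaussian density in the
  E-step. On instances without random effects every M-step is an exact
  maximiser (weighted least squares for \(\beta\); \(\sigma^2\) updated
  as the weighted residual sum of squares over \(\sum(1-\xi)\), the
  EM-consistent denominator; closed-form intercept for the zero part),
  so the observed-data log-likelihood is non-decreasing to machine
  precision — this is asserted in the tests. With random effects the
  M-step is PQL-approximate and small decreases can occur.

Degenerate inputs are handled deliberately: an all-zero response is an
error naming the condition; a zero-free response collapses ZINBMM onto
the NBMM (and ZIGMM onto the plain weighted LMM, bit-identically); when
every subject contributes one sample and no correlation is requested the
random intercept is unidentifiable and the inner solver uses closed-form
weighted least squares. Aliased design columns are dropped with a
warning, fitted NB means are clipped to \([10^{-8}, 10^8]\), and
zero-inflation probabilities to \([10^{-6}, 1-10^{-6}]\) (the zero-part
linear predictor saturates at the corresponding logits when the
responsibilities degenerate).

## Inference choices

Wald p-values use a standard normal reference by default; a Student-t
reference with containment-style denominator degrees of freedom
\(N - n_{\text{subjects}} - \mathrm{rank}(X) + 1\) is available. Exact
replication of `nlme`'s inner/outer degrees-of-freedom bookkeeping is
out of scope. The inner LMM uses REML by default (`lmm_method` switches
to ML); the dispersion update uses the conditional likelihood at the
fitted means, mirroring the classical `glm.nb` construction — both are
approximations and documented as such. The dispersion is refreshed once
per sweep rather than to convergence; the fixed point is the same.

Across taxa, `screen_taxa` filters by the strict rule
"nonzero proportion > min_p" (default `min_p = 0`, so all taxa with at
least one nonzero sample are analysed), optionally sorts by decreasing
nonzero proportion, fits each retained taxon independently inside its
own error handler, and records failures without aborting. Per-taxon
parameters are estimated independently; nothing is shared across taxa.
Benjamini–Hochberg adjustment is offered per (term, part) across taxa;
raw p-values are the default.

## What the simulator emulates — and what it does not

`simulate_nbmm` / `simulate_zinbmm` / `simulate_zigmm` draw a
subject-level binary group, a sample-level time covariate on \([0,1]\),
a subject-level continuous nuisance covariate, per-sample totals uniform
on \([5\times10^3, 5\times10^4]\), subject random intercepts (optionally
slopes), and unbalanced panel sizes uniform over a range — the shape of
a typical case–control longitudinal study. Defaults are
100 subjects × 5 samples, \(\beta = (1.0, 0.5)\), \(\theta = 2\),
random-intercept SD 0.5; the ZIG generator default follows an unbalanced
98-subject, 1–6-samples design with \(\sigma = 0.6\) and
random-intercept SD 0.3. Structural zeros are added independently with
constant or logistic-model probability, and the latent indicators are
returned for E-step tests.

The simulator does **not** emulate compositionality (taxa are drawn
independently), taxonomic correlation, phylogenetic signal, or
covariate-dependent sequencing depth. Passing recovery and calibration
tests therefore demonstrates correctness of the estimators under the
stated generating models, not robustness to those real-data features.

## Verification problem sizes

The test suite checks, among others: equivalence of the degenerate
singleton-subject NBMM with a direct-likelihood NB GLM oracle (20
datasets of n = 200, within 0.1% relative); recovery of the group effect
and dispersion over a 100-seed grid (mean \(\hat\beta_1 \in
[0.45, 0.55]\), mean \(\hat\theta \in [1.6, 2.4]\)); type-I error of the
group test over 500 null replicates (within \([0.03, 0.08]\) at nominal
0.05); ZINB zero-part recovery over 50 replicates; ZIG EM monotonicity
over 50 fixed-effects-only instances at \(10^{-10}\); and agreement of
tiny random-intercept NBMMs with a Gauss–Hermite marginal-likelihood
oracle (mean relative deviation under 10% across 20 eight-observation
instances — a per-instance relative bound is not meaningful because a
random instance can have a coefficient arbitrarily close to zero, and
PQL carries a documented bias at that size). `scripts/acceptance.R`
recomputes scaled versions of these quantities (30–200 replicates).

## Known limitations

* PQL standard errors and the conditional dispersion update are
  approximations; at very small counts or very few subjects the
  estimates can deviate from the exact marginal MLE by more than a few
  percent (quantified in the tests).
* The ZIG mixture identifies the structural-zero mass only when the
  Gaussian density at zero is small relative to the zero fraction. When
  transformed means sit near zero (rare taxa transformed to small
  values), the likelihood is maximised by absorbing zeros into the
  Gaussian component, attenuating effect estimates — the same mechanism
  behind the inflated false-positive behaviour reported for ZIG-type
  models in the literature. The ZIG type-I behaviour should therefore be
  interpreted cautiously; the NB families are preferable for counts.
* Only two-level designs (samples in subjects), one random slope at
  most, and AR(1)/compound-symmetry residual correlation are supported.
  AR(1) uses within-subject observation order, not continuous time gaps.
* Rows with missing values in any model variable are dropped per run
  with a logged count; categorical covariates use the first-observed
  level as reference.

## Worked example

```{r, eval = FALSE}
library(taxamix)

sim <- simulate_zinbmm(sim_truth(n_subjects = 50, p_zero = 0.3, m = 20,
                                 seed = 1))
spec <- model_spec(~ group + time + age, ~ 1 | subject, method = "zinb")
scr <- screen_taxa(sim$table, sim$meta, spec, min_p = 0.2)
tab <- adjust_pvalues(fixed_table(scr), "BH")
head(get_fixed(scr, "group"))
plot_fixed(tab, terms = "group")
heat_p(tab)
```
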