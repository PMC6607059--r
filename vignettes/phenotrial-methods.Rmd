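---
title: "Models and methods behind phenotrial"
author: "phenotrial authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenotrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phenotrial implements the statistical backbone of a controlled-environment
plant phenotyping study: a balanced trial of genotypes (maize inbred lines
in the motivating setting) grown under a control and several stress
treatments (nitrogen limitation, water limitation, and their combination),
with many replicate plants per genotype x treatment cell and a panel of
image-derived and manually measured traits per plant. This vignette
documents the models, the numerical choices, and the places where the
design was genuinely open and a decision had to be made.

## The mixed model and its variance components

Each trait is analysed separately under the Gaussian linear mixed model

$$ y_{ijk} = \mu + r_k + t_j + g_i + (gt)_{ij} + \varepsilon_{ijk}, $$

with fixed replicate effects $r_k$, and independent random effects
$t_j \sim N(0, \sigma^2_T)$, $g_i \sim N(0, \sigma^2_G)$,
$(gt)_{ij} \sim N(0, \sigma^2_{GT})$ and residuals
$\varepsilon_{ijk} \sim N(0, \sigma^2_E(j))$. Two residual structures are
fit for every trait — a pooled $\sigma^2_E$ and a per-treatment
$\sigma^2_E(j)$ — and the one with the lower AIC
($-2\log \mathrm{REML} + 2k$, $k$ = number of variance parameters) is kept,
with ties going to the pooled model. Treatment is modelled as random so its
variance appears in the variance-contribution decomposition, but with only
four levels $\sigma^2_T$ is poorly identified; it is therefore **excluded
from heritability**, which uses the printed sample-basis form

$$ h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GT} + \sigma^2_E}. $$

Under heterogeneous residuals, the $\sigma^2_E$ entering $h^2$ is the
unweighted mean of the per-treatment residual variances; this is a
documented convention (a weighted mean would differ only when the design
is unbalanced, which this package does not target).

### REML implementation

`fit_reml()` maximizes the restricted log-likelihood directly over
log-variance parameters (L-BFGS-B, bounds $10^{-10}$–$10^{12}$,
convergence tolerance $10^{-8}$ on the log-likelihood by default, 500
iterations maximum). The likelihood is evaluated through the
mixed-model-equation identity

$$ -2\,\ell_R = (n-p)\log 2\pi + \log|R| + \log|G| + \log|C| + y'Py, $$

with $C$ the MME coefficient matrix, so each evaluation costs one Cholesky
factorization of a $(p+q) \times (p+q)$ matrix ($q = T + G + GT$ random
levels, 104 at design scale) rather than anything of order $n$. Two
numerical details matter:

* $y'Py$ is computed in the stable residual form
  $(y - W\hat\theta)'R^{-1}(y - W\hat\theta) + \hat u'G^{-1}\hat u$ — a sum
  of non-negative terms. The algebraically equivalent
  $y'R^{-1}y - \hat\theta'W'R^{-1}y$ loses about six significant digits to
  cancellation when residual variances are small, which is visible as
  jitter in the optimum.
* After quasi-Newton convergence the fit is polished: coordinate-wise exact
  1-D maximizations when any parameter sits on its bound (the surface is
  stiff there and line searches stall), and a damped Newton refinement with
  numeric derivatives when a tight tolerance (below $10^{-9}$) is
  requested. With these, REML agrees with the closed-form balanced-design
  estimator to better than $10^{-6}$ relative on interior fixtures.

A quasi-Newton ascent was chosen over EM-style fixed-point updates because
EM's linear convergence rate degrades badly when one variance ratio is
small — exactly the regime the no-noise and full-shrinkage unit tests
exercise. Only the estimand (the REML optimum) is prescribed; the route to
it is an implementation choice.

`fit_moments()` provides the independent expected-mean-squares oracle for
balanced data ($\hat\sigma^2_G = (MS_G - MS_{GT})/(RT)$, etc., truncated at
zero with a `boundary` flag), and the test suite additionally checks the
REML fit against a dense GLS solve assembled from scratch and against an
established general mixed-model fitter on the homogeneous case.

Genotype predictions ("BLUPs", $\hat\mu + \hat t_j + \hat g_i +
\widehat{gt}_{ij}$, fixed part at the average replicate) are the substrate
for every downstream stage — correlations, penalized selection, stress
indices and AMMI all consume the genotype x treatment BLUP table, not raw
cell means. Anomalous observations are flagged (never removed) when their
studentized conditional residual, using model-based standard errors
$\sqrt{\mathrm{diag}(R - WC^{-1}W')}$, exceeds 3.

The likelihood-ratio test for a random term uses the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, the standard correction when the
null pins a variance at zero. The replicate fixed effect gets a plain
z-test on its MME contrast; no small-sample degrees-of-freedom correction
is attempted.

### What AIC selection can and cannot deliver

When the truth is homogeneous, the heterogeneous model adds three
*interior* parameters (four equal positive residual variances against one),
so the likelihood-ratio statistic is asymptotically $\chi^2_3$ and AIC
picks the simpler model with probability $1 - P(\chi^2_3 > 6) \approx
0.888$ — by construction, not by defect of the fit. The acceptance suite
measures this rate empirically (about 0.88 at design scale) alongside the
power side (a 4x residual inflation in one treatment is detected
essentially always). Readers calibrating expectations for the selection
step should anchor on those numbers.

## Summaries and correlation networks

Per trait x treatment: mean, sample standard deviation, $CV = 100\,
sd/|mean|$, and percent reduction relative to the control mean (undefined
and flagged when the control mean is zero). Pearson correlations are
computed across genotype BLUPs within one treatment ($n$ = genotypes), with
two-sided p-values from the exact $t$ transform on $n-2$ degrees of
freedom. Network edges connect pairs with $p < \alpha$; $\alpha = 0.05$
two-sided and unadjusted by default, with an optional Holm flag, because
the motivating analysis reports only "significant correlations" without a
multiplicity rule. Edge width equals $|r|$; layout is deliberately not
computed — the module emits nodes and signed weighted edges, and rendering
is a presentation concern.

## Penalized trait selection

Ridge and lasso are fit in the study's printed parameterization,

$$ \hat\beta = \arg\min_\beta \; \mathrm{RSS}(\beta) + \lambda
   \textstyle\sum_j \beta_j^2
   \quad\text{and}\quad
   \hat\beta = \arg\min_\beta \; \mathrm{RSS}(\beta) + \lambda
   \textstyle\sum_j |\beta_j|, $$

**without** the $1/(2n)$ rescaling common in software; cross-validation
makes the two conventions equivalent up to a relabelling of $\lambda$
(the test suite verifies coefficient-level agreement with an established
penalized-regression library at the matched $\lambda$). Predictors are
standardized to unit sample standard deviation and the response centered —
the penalty is meaningless across traits with different units otherwise —
and this is flagged as an assumption, since the original analysis does not
state it. Coefficients are reported on the standardized scale with exact
zeros blanked, plus a back-transformed copy.

Ridge has the closed form $(X'X + \lambda I)^{-1}X'y$ (a gradient-descent
route is kept as an independent check); lasso uses cyclic coordinate
descent with the soft-threshold update $S(x_j'r_{(j)}, \lambda/2)/x_j'x_j$,
glmnet-style active-set sweeps, convergence at a maximum coefficient change
below $10^{-8}$, and a compiled inner loop. All coefficients are exactly
zero once $\lambda \ge 2\max_j |x_j'y|$, which anchors the default grid:
100 log-spaced values from $\lambda_{max}$ down to $10^{-4}\lambda_{max}$.

Fivefold cross-validation shuffles fold labels with a caller-supplied seed
(recorded in the fit), scores by held-out mean squared error, and picks
the minimizing $\lambda$, breaking exact ties toward the stronger penalty.
A one-standard-error rule sits behind a flag; the default is the plain
minimizer. A consequence worth knowing: on a pure-noise response the
minimizer frequently retains a few spurious coefficients (empirically only
about a quarter of runs end with an empty model, and the reference
implementation behaves the same at its `lambda.min`); the one-SE rule on a
short path is what delivers mostly-empty null fits. Fits are per treatment
x response on genotype BLUPs, so $n$ equals the number of genotypes — with
25 predictors this is a genuinely high-dimensional regression, and
selection behavior (not coefficient inference) is the deliverable.

## Stress indices, scoring and the A–D classification

From non-stress and stress dry-biomass performance ($Y_p$, $Y_s$, both
positive; population stress intensity $SI = 1 - \bar Y_s/\bar Y_p$ must be
positive or the stage refuses to run):

| index | formula | better |
|---|---|---|
| SSI | $(1 - Y_s/Y_p)/SI$ | lower |
| TOL | $Y_p - Y_s$ | lower |
| MP  | $(Y_p + Y_s)/2$ | higher |
| GMP | $\sqrt{Y_p Y_s}$ | higher |
| STI | $Y_p Y_s/\bar Y_p^2$ | higher |

These satisfy checkable identities — $GMP \le MP$ with equality iff
$Y_p = Y_s$, $STI = GMP^2/\bar Y_p^2$, and a genotype with exactly the
population-average loss ratio has $SSI = 1$ — which the acceptance suite
asserts to $10^{-12}$ on random yield vectors.

The 10-grade scoring map is a **reconstruction**: the cited scoring method
is not reproduced formula-by-formula in the motivating text. The default
maps each index linearly to $[1, 10]$ by min–max binning with half-up
rounding ($\lfloor x + 0.5\rfloor$, so 5.5 scores 6), reversing SSI and TOL
first so that 10 always means better; constant input maps everyone to the
neutral score 5. A decile-rank variant is provided behind the same
interface so the two conventions can be compared; scores are invariant
under increasing affine transforms of the index in both. RCI (resilience)
averages the SSI and TOL scores; PCI (productivity) averages MP, GMP and
STI scores. Genotypes are classified by quadrants around the population
means of RCI and PCI: A (both at or above the mean), D (both below), with
values exactly on a mean assigned to the "high" side for determinism. The
productive-but-not-resilient quadrant is labelled B and the
resilient-but-not-productive one C, matching the description of group C as
performing relatively better only under stress; a flag swaps the two if
the opposite convention is wanted. Classification runs separately per
stress treatment. Group A versus D trait comparisons use Welch's
unequal-variance t-test (the source says only "t-test"; Welch is the safer
default for groups of 4–5 genotypes) with `*`/`**` flags at 0.05 and 0.01.

Derived indices (specific plant weight, water-use efficiency,
physiological nitrogen-use efficiency) are configurable formulas evaluated
against the table's columns — their exact definitions live in supplementary
material that is not available, so standard forms are defaults and the
applied formula is recorded in the output metadata.

## AMMI stability analysis

The genotype x treatment dry-weight table (BLUP-based by default) is
double-centered, $tg_{ij} = y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j} +
\bar y_{\cdot\cdot}$, leaving a matrix whose rows and columns sum to zero,
and decomposed by SVD. Variance explained per interaction principal
component is $100\,\lambda_k^2/\sum\lambda^2$. Two conventions are fixed
for reproducibility: **symmetric biplot scaling** (both sides scaled by
$\sqrt{\lambda_k}$, so score inner products reconstruct $tg_{ij}$; the
source does not state its scaling), and a deterministic resolution of the
SVD sign ambiguity (the largest-magnitude genotype loading on each
component is made positive). Stability is summarized as the Euclidean
distance of each genotype from the biplot origin over IPC1–2 (small =
stable, the quantitative analogue of "short vectors, no acute angles"),
plus the cosine of the angle with each treatment vector (positive =
interaction favoring that treatment). Dry weights are not standardized per
treatment before centering; that choice was left open in the source and
unstandardized is the default.

## The synthetic-trial generator

No per-plant data are deposited with the motivating study, so the
generator is a first-class module: it *is* the study conditions for every
test. Defaults: 20 genotypes x 4 treatments (C, N, W, N+W) x 8 replicates
= 640 plants; global mean 20 (a dry-weight-like scale in grams); fixed
treatment effects scaled to reduce the control mean by 3.2%, 19.3% and
21.8% for N, W and N+W — the reported average stress reductions;
$\sigma^2_G = 2$, $\sigma^2_{GT} = 0.5$, $\sigma^2_E = 1$ (scalar
broadcast, or a per-treatment vector for heterogeneity), which puts $h^2$
near 0.57 and within-treatment CVs in the reported 5–10% band. Since
within-cell variances per trait are not reported, those magnitudes are a
calibration to the printed CV ranges, chosen once. Replicate effects
default to zero but can be injected to exercise the fixed term. Traits
that must be positive can be generated by exponentiating a log-scale
trial (`log_normal`).

The multi-trait panel adds block-correlated predictor traits — one latent
factor per block mixed as $\sqrt{\rho_b}\,f + \sqrt{1-\rho_b}\,e$ at both
the genotype and observation level, giving within-block correlation
$\rho_b$ and cross-block 0 — on a positive baseline (default 10) so CVs
and reductions are meaningful, plus two biomass responses (`BFw` on a 10x
scale, `BDw`) built at replicate level as baseline + $X\beta$ + optional
planted archetype profile + noise. The archetype profiles (A: high
control, small stress loss; B: high control, large loss; C: low control,
small loss; D: low on both) give classification a planted truth that the
vanishing-noise tests recover exactly.

What the generator does **not** emulate — and hence what passing tests do
not establish about real platform data: spatial and temporal structure
(conveyor position, imaging day), non-Gaussian trait distributions and
measurement-pipeline artifacts, missing plants and unbalance, genuinely
nonlinear trait-biomass relationships, and any time-course dynamics. The
generator's Gaussian, balanced, linear world is exactly the world the
fitted models assume; real-data robustness is out of scope.

## Problem sizes and runtime posture

The test and acceptance workloads were sized so a full run stays
comfortable on a single CPU: 200 simulated trials for the
variance-component recovery and each AIC-calibration arm, 50 balanced
fixtures for the oracle-equivalence sweep, 100 seeded cross-validation
runs for each lasso calibration arm, 1000 draws for the stress-index
identities and the Welch type-I check, and a reduced 12-genotype
configuration for the byte-identity pipeline rerun. These sizes are stated
here as the package's chosen study sizes; the underlying functions take
their dimensions from configuration and scale beyond them.

## Known limitations

* Balanced complete designs only; the method-of-moments oracle refuses
  unbalanced data and REML assumes complete cells. No spatial models,
  pedigrees or marker-based relationship matrices.
* The treatment variance rests on four levels; treat its contribution
  share as descriptive.
* Penalized coefficients come without inference; the module's contract is
  selection and presentation, not standard errors.
* The scoring map and the B/C quadrant orientation are reconstructions of
  under-specified conventions, isolated behind flags so either choice can
  be swapped without touching the rest of the pipeline.
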