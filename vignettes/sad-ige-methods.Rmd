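---
title: "Structured antedependence models with indirect genetic effects: methods and design"
author: "sadige package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured antedependence models with indirect genetic effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadige)
```

## The model

`sadige` analyses longitudinal records of group-housed animals — the
motivating case is weekly average daily gain (ADG, g/d) of growing
rabbits housed eight to a cage under restricted feeding — with a linear
mixed model in which an animal's phenotype depends on its own genes and
on the genes of its cage mates:

$$
y_{ilm}(w_j) = \mu_i(w_j) + DGE_i(w_j) + \sum_{k \in K_i} IGE_k(w_j)
             + l_l(w_j) + g_m(w_j) + p_i(w_j).
$$

Here $DGE_i$ is the direct genetic effect of animal $i$ on itself,
$IGE_k$ the indirect (social) genetic effect of cage mate $k$ on every
one of its $n-1$ mates, and $l$, $g$, $p$ are litter, group (cage) and
pseudo-permanent animal effects. Two structural choices matter:

* **No residual term.** The pseudo-permanent effect is an animal-level
  effect with a free $J \times J$ covariance, so a separate residual
  would not be identifiable from it; $p$ absorbs the residual. In the
  implementation this is exploited directly: $p$ enters the likelihood
  as a block-diagonal "residual" covariance with one
  $\Sigma_p[\mathrm{obs},\mathrm{obs}]$ block per animal, which makes
  the standard sparse mixed-model-equation identities applicable even
  though the model has no conventional residual.
* **Correlated direct and indirect effects.** $[DGE, IGE]$ is
  multivariate normal with covariance $A \otimes \Sigma_{GE}$, $A$ the
  pedigree relationship matrix and $\Sigma_{GE}$ a $2J \times 2J$
  matrix.

## Structured antedependence (SAD) covariances

Each random effect's within-animal covariance over the $J$ weeks is not
left unstructured but generated by an antedependence recursion,

$$
u(w_j) = \sum_{s=1}^{\alpha} \theta_{s,j}\, u(w_{j-s}) + e(w_j),
\qquad e(w_j) \sim N(0, \sigma^2(w_j)),
$$

with the regression coefficients $\theta_{s,j}$ polynomial in time and
$\log \sigma^2(w_j)$ polynomial in time. The implied covariance is
$\Sigma = (L' D^{-1} L)^{-1}$, with $L$ unit lower-triangular holding
$-\theta_{s,j}$ and $D$ the innovation variances; `sigma_from_LD()`
symmetrizes the inverse as $(M + M')/2$ to remove round-off asymmetry.
A structure of order $\alpha$ with antedependence degrees
$\beta_1\ldots\beta_\alpha$ and innovation degree $\gamma$ is named
`SAD<alpha>-<beta...><gamma>`; the package default, retained for all
effects, is SAD1-11 (4 parameters per effect). For the genetic pair the
direct effect additionally regresses on the *same-week* indirect
effect through a cross-antedependence function $\delta_j$ (degree 1 by
default): internally the joint system is ordered IGE-before-DGE within
week so the joint $L$ stays lower-triangular, and the resulting
$2J \times 2J$ covariance is reordered to DGE-block-first. With
$\delta \equiv 0$ the construction is exactly block-diagonal.

Conventions worth stating because the data do not force them:

* Polynomials are evaluated at the raw week indices $1\ldots5$. A
  `time_grid(weeks, transform = c(a, b))` argument exposes an affine
  recoding for users who prefer centred or rescaled time; all defaults
  use the identity.
* For early weeks $j \le \alpha$ the recursion is truncated to the
  available lags, which is what the $L$-matrix construction implies.
* $\delta_j$ applies at every week including week 1 (the cross term
  references the same-week value, so no lag is missing).
* The parameter vector $\omega$ is packed per effect as antedependence
  coefficients, then (for the genetic pair) cross coefficients, then
  log-innovation coefficients; the full five-effect model of the data
  analysis has 22 parameters, the litter-free simulation model 18.

## Estimation

REML is computed through the mixed-model equations, never through the
dense phenotypic covariance: with $R$ the permanent-effect block
diagonal and $G$ the remaining effect covariances,
$\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$ and
$y'Py = y'R^{-1}y - \hat\theta' W'R^{-1}y$. The coefficient matrix $C$
has a fixed sparsity pattern across parameter values, so the package
precomputes week-pair cross-products of the design matrix once and
re-fills a cached symbolic Cholesky factorization (CHOLMOD) at each
likelihood evaluation; $\log|A|$ comes for free from the Mendelian
sampling variances of the pedigree. On the 4800-record base population
of the selection study one evaluation takes a few tens of milliseconds.

The likelihood is maximized by finite-difference L-BFGS-B over $\omega$
(step `1e-5`, convergence factor `1e9`, i.e. relative function change
about `2e-7`). The default `init = "ladder"` first fits the model with
every polynomial reduced to a constant and expands the estimates as
starting values — the step-up strategy that is standard for getting
complex SAD models to converge. Starting values for the first rung are
data-driven: per-week phenotypic variances of fixed-effect residuals
are split into fixed shares (permanent 0.5, genetic 0.2, group 0.15,
litter 0.1, indirect 0.01), each share converted to a flat
antedependence of 0.3 and a least-squares log-linear innovation
variance; cross-dependence starts at zero.

The with-IGE likelihood surface is genuinely multi-modal: besides the
mode with a strong direct–indirect antagonism there is an inferior mode
in which the indirect genetic variance collapses toward zero, and
quasi-Newton searches from neutral starts frequently land there (the
replicated fits in the original study design likewise failed to
converge in about half of the strong-antagonism replicates). Starting
values therefore matter more than optimizer settings. For fits where
plausible covariance values exist — literature estimates, or the
generating values of a simulation study — `approx_sad_params()`
converts covariance matrices into the model's SAD parameters by
sequential-regression decomposition plus least-squares polynomial
projection, and the replicated studies (`recovery_study()`,
`selection_study()`, `run_scenario()`) start their REML fits there, the
analogue of starting REML at literature values. The retained mode is
always the one the optimizer's likelihood prefers, and on test
replicates the antagonism mode beats the collapsed mode by several log
units. Convergence is flagged from the optimizer status; replicated
studies exclude flagged replicates and report the percentage used.

The observed information is a central finite-difference Hessian at the
estimates (relative step `1e-4`); its inverse feeds the sampling-based
standard errors. `identifiability_diagnostics()` reports the condition
number $\sqrt{\lambda_{\max}/\lambda_{\min}}$ of the information matrix
and the parameter-estimate correlation matrix, the practical check for
whether the data separate indirect genetic from group effects.

Nested models are compared by likelihood ratio with degrees of freedom
equal to the literal difference in free-parameter counts; under the
default structures the with/without-IGE comparison has 6 df (10 genetic
parameters against 4).

## Quantitative-genetic summaries

For groups of $n$ with mean cage-mate relatedness $r$ (an input;
computable from the pedigree, or set to 0.16, the value reported for
the motivating population):

$$
\sigma^2_{Tj} = \sigma^2_{DGEj} + (n{-}1)\sigma^2_{IGEj}
 + (n{-}1) r\,[\,2\sigma_{DGEj,IGEj} + (n{-}2)\sigma^2_{IGEj}\,]
 + \sigma^2_{lj} + \sigma^2_{gj} + \sigma^2_{pj},
$$

with total heritable variance
$\sigma^2_{TBVj} = \sigma^2_{DGEj} + 2(n{-}1)\sigma_{DGEj,IGEj} +
(n{-}1)^2\sigma^2_{IGEj}$; at $n = 8$ these are the familiar
7/6/14/49-coefficient forms. Direct, indirect and total heritabilities
are these variances relative to $\sigma^2_{Tj}$; indirect and total
ratios are reported unclamped even when pathological samples push them
outside $[0, 1]$.

Standard errors come from multivariate-normal sampling of
$\tilde\omega \sim N(\hat\omega, H(\hat\omega))$: every draw rebuilds
all $\Sigma$ matrices and heritabilities, draws with any non-PSD
reconstruction are discarded (smallest eigenvalue below
$-10^{-8}\times$ trace; rejection never alters retained draws), and
estimates/SEs are means/SDs over retained draws (default 10,000).
Correlations among the unique (co)variance elements across draws — a
$100 \times 100$ matrix for the five-effect model — flag estimability
problems at $|\rho| > 0.6$.

## The selection simulation

`simulate_base()` builds the closed nucleus: 30 unrelated sires each
mated to 4 unrelated dams, 8 offspring per mating with exactly half of
each sex (960 offspring, 4800 records), cages of 8 composed of 2
progeny from each of 4 full-sib families. Offspring breeding values are
parent averages plus a Mendelian deviation drawn from
$N(0, \tfrac12\Sigma_{GE})$ — deliberately without the inbreeding
correction, matching the stated simulation rule (the pedigree-aware
sampler used by the synthetic-data generator *does* apply the
$d_i$-scaled correction). Phenotypes add week means, own DGE, the seven
mates' IGE, a cage effect and a correlated permanent effect; the truth
covariances are **unstructured** matrices while estimation uses SAD
structure, preserving the deliberate model misspecification of the
study design.

Three strategies are compared at fixed variance components estimated
once from the base cohort: (1) a SAD model without IGE, selecting on
the summed weekly direct EBV; (2) the with-IGE model, selecting on the
week-1 total EBV ($TEBV_j = DGE\text{-}EBV_j + 7\, IGE\text{-}EBV_j$);
(3) the with-IGE model, selecting on the summed weekly TEBV. Each
generation the best male per sire family and the best 120 females are
kept (ties broken by lowest animal id), mated at random 1:4 avoiding
matings within a sire family, and EBVs are predicted from all records
accumulated so far together with the full pedigree (the data window is
not pinned down by the study description; cumulative records are the
standard practice). Within a replicate the scenarios share the base
population (common random numbers); subsequent generations use
replicate-specific seeds.

### Default truth parameters

The unstructured truth matrices shipped as defaults are synthetic
approximations assembled from the published point estimates and
qualitative correlation ranges of the rabbit analysis, not published
matrices: direct genetic variances (8.03, 11.0, 13.47, 10.0, 6.20),
indirect (0.44, 0.35, 0.28, 0.22, 0.31), group variances rising 5.7 to
16.4, permanent 23.1 to 52.8, litter falling 8.7 to 4.2, week means
(26.51, 37.54, 42.02, 40.11, 41.20) g/d, with interpolated mid-range
correlations. The direct-indirect cross-block is built as
$-L_D K L_I'$ with $L$ the Cholesky factors of the marginal
correlation matrices and $K$ a fixed coupling matrix with largest
singular value below 1 — positive definiteness is therefore guaranteed
by construction. $K$ was calibrated once against the published anchor
statements: within-week direct-indirect correlations near $-0.73$
(reported range $-0.57$ to $-0.89$), correlations of the week-1 total
breeding value with weeks 2–5 of about $(-0.30, -0.07, 0.00, 0.05)$,
and a near-zero covariance between the direct-EBV-sum criterion and
the total breeding value (the reported absence of response to
IGE-blind selection under strong antagonism). The antagonism levels
divide the cross-block by 1 (strong), 2 (moderate) or 4 (weak); the
rescaling is a convex combination with the block-diagonal part and so
preserves positive definiteness, which is re-verified at construction.

## The synthetic-data generator

`generate_dataset()` emulates the field design for testing and demos: a
two-generation pedigree (each founder sire serving 4 dams; full-sib
litters of 1–5 recorded kits, ~1100 litters by default), weaned kits
mixed randomly into cages of 8, all effects drawn from their
multivariate normals (genetic trajectories via the linear-cost
pedigree-aware sampler), and cage-level attrition: each cage survives
week $j$ with probability (0.87, 0.977, 0.869, 0.852, 0.885),
whole-cage from the failed week onward, reproducing the declining
weekly record counts of the motivating dataset (relative counts 1,
0.98, 0.85, 0.72, 0.64). What the generator does **not** emulate:
per-animal missingness inside surviving cages (available behind
`per_animal_attrition`, in which case absent animals still contribute
IGE to their mates' phenotypes while the fitted model counts only
recorded mates), the real management factors (batches, parity, litter
size as fixed effects — the default fixed structure is a week-factor
mean), and any growth-curve mechanism. Passing tests on these data
therefore show correctness of the estimation machinery under the
model's own assumptions, not robustness to the unmodelled structure of
real husbandry data.

## Problem sizes used by the shipped checks

The replicated studies in the package's tests and in
`scripts/acceptance.R` keep the full base-population design (960
offspring, 4800 records, 7 generations) but use small replicate counts
chosen as the package's standard quick-check sizes: 2 replicates at
strong antagonism (all three scenarios, plus the parameter-recovery
summary reusing the same base fits) and 1 replicate at weak antagonism
(scenarios 1 and 3). All quantitative bands in those checks are
Monte-Carlo bands at the reduced replicate count: a mean over $R$
replicates of a quantity with cross-replicate coefficient of variation
$c$ carries a standard error of $c/\sqrt{R}$, and checks use 3 such
SEs around the reference values (so, e.g., the direct-genetic-variance
bias check at $R = 2$ with $c \approx 18\%$ uses a ±38-point band).
Dispersion estimates at $R = 2$ have a single degree of freedom, so
only upper bounds are asserted for them. Larger replicate counts — the
replicated studies report stable summaries from roughly 30 replicates
— are a matter of calling `recovery_study()` / `selection_study()`
with `replicates = 30`.

Other fixed numerical choices: PSD tolerance $-10^{-8}\times$ trace;
L-BFGS-B steps and factors as above; information-matrix step `1e-4`;
ties in selection broken by lowest id; week-pair cross-products cached
per observation pattern so unbalanced (attrition) data cost no extra
factorizations.

## Known limitations

* The likelihood surface with indirect effects can be multi-modal; the
  ladder start mitigates but does not eliminate sensitivity to starting
  values, and the convergence flag should be respected.
* Analytic REML gradients are not implemented; gradient costs scale
  with the parameter count, which keeps very high-order SAD structures
  slow.
* The breeding simulator ignores inbreeding in Mendelian sampling
  variances (by design, to match the stated simulation rule), slightly
  overstating late-generation genetic variance.
* `mean_cage_relatedness()` and the heritability formulas assume a
  single group size; mixed group sizes require per-group computation.
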