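---
title: "Methods: SEM analysis of perturbed pathway modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SEM analysis of perturbed pathway modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsem)
```

## The model and its assumptions

`pathsem` treats a pathway module as a *path diagram*: a mixed graph whose
vertices are observed expression variables and whose edges encode two kinds
of assumptions. A directed edge $j \to i$ frees the path coefficient
$\beta_{ij}$ — the expected change in gene $i$ per unit change in gene $j$
with the other parents held fixed; a bidirected edge $i \leftrightarrow j$
frees the error covariance $\psi_{ij}$, representing a hidden common cause.
Every *absent* edge is the strong assumption that the corresponding
parameter is exactly zero. Stacking the equations gives

$$Y = BY + U, \qquad \mathrm{Cov}(U) = \Psi,
\qquad \Sigma(\theta) = (I-B)^{-1}\,\Psi\,(I-B)^{-\top},$$

with $\theta = (\beta; \psi)$ of dimension $t$. Estimation assumes the
observed variables are jointly Gaussian and complete (incomplete rows are
removed listwise with a message). Total, direct and indirect effects obey
$TE = (I-B)^{-1} - I$, $DE = B$, $IE = TE - DE$, which requires the
spectral radius of $B$ to stay below one
(`effects_decomposition()` refuses divergent feedback).

## From pathway to initial model

`extract_module()` connects every ordered pair of differentially expressed
genes (DEGs) by one minimum-hop *directed* path and fuses all paths into a
single subgraph. Choices made here, and why:

* **Directed traversal.** Curated pathways are converted to directed
  graphs, and regulatory reachability is inherently asymmetric; an
  undirected fallback would invent reverse routes. Unreachable ordered
  pairs are recorded in `skipped_pairs`, never an error.
* **Both orientations per DEG pair** are attempted, since $i \leadsto j$
  and $j \leadsto i$ may differ or exist only one way; fusing both loses
  nothing and keeps reciprocal motifs.
* **Deterministic tie-break.** Among equally short paths the BFS explores
  neighbours in lexicographic order of node ids, so results are identical
  across platforms and reruns.

Connector genes (non-DEGs on the paths) can be grouped into protein
superfamilies and replaced by composite variables: the first principal
component of the member expression profiles, computed on the *correlation*
matrix so the acceptance rule — PC1 must explain at least 50% of the total
variance (`min_variance = 0.5`) — is invariant to per-gene scale. PC1 signs
are fixed by forcing the largest-magnitude loading positive, making scores
reproducible across linear-algebra backends. Rejected families simply stay
as individual genes. Collapsing members can create self-loops and duplicate
edges; both are dropped.

`build_initial_model()` frees one path coefficient per module edge and one
error variance per variable; *all* error covariances, including those
between exogenous variables, are fixed at zero. This is the only convention
under which $t$ equals "edges + variables" and a 17-variable, 31-edge model
has $d = 153 - 48 = 105$ degrees of freedom, matching the df conventions
used throughout. Two identifiability criteria are enforced at construction
and re-checked at every refinement step: *bow-freeness* (no pair with both
a free directed edge and a free error covariance) and *block-recursiveness*
(strongly connected components of at most two equations).

## Fitting, fit indices and their conventions

`fit_ml()` minimises the ML discrepancy
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - \log|S| - p$
by BFGS with analytic gradients; error variances are optimised on the log
scale to enforce positivity, and up to `n_restarts = 5` jittered restarts
(deterministic under `fit_config(seed = )`) recover from bad starts. Start
values come from equation-wise least squares. The sample covariance uses
the divisor implied by the chi-square convention below.

* **Chi-square and RMSEA sample-size convention.** `fit_config()` defaults
  both to total $N$: $\chi^2 = N\,F$ and
  $\mathrm{RMSEA} = \sqrt{\max(0, (\chi^2-d)/(d\,N))}$. The $N-1$ variant
  is available (`"N_minus_1"`), but the total-$N$ form is the one that
  reproduces the reference value 0.288 from $\chi^2 = 339.410$, $d = 105$,
  $N = 27$, so it is the default.
* **Close fit.** The close-fit P is the upper tail of the noncentral
  $\chi^2(\lambda, d)$ at the observed statistic, with
  $\lambda = (n-1)\,d\,\varepsilon^2$ and $\varepsilon = 0.05$
  (`close_fit_epsilon`); close fit is not rejected when $P > 0.05$.
* **SRMR** averages squared correlation-scale residuals over all
  $p(p+1)/2$ distinct moments, diagonal included (the diagonal residuals
  vanish at most optima, and including them keeps the denominator equal to
  the moment count). Values below `srmr_adequate = 0.10` count as adequate,
  below 0.05 as good.
* **Standard errors** are square roots of the inverse *observed*
  information (numerical Hessian of the negative log-likelihood at the
  optimum) — simpler than expected information and adequate at these
  sample sizes. An information matrix with reciprocal condition number
  below $10^{-8}$ is reported as empirical under-identification rather
  than silently inverted.
* **Modification indices** are univariate score (Lagrange-multiplier)
  statistics: for a fixed parameter $\theta_j$,
  $MI_j = \tfrac{m}{2}\, g_j^2 / (H_{jj} - H_{jf}H_{ff}^{-1}H_{fj})$ with
  $g$ and $H$ the gradient and Hessian of $F$ over free parameters plus
  the candidate. This is a quadratic approximation to the exact refit
  chi-square drop; it is accurate for mild misspecification and
  systematically overshoots for large ones, which is why the test suite
  validates it at small planted effects.

## Refinement

`stepwise_refine()` frees one parameter at a time, taking candidates in
descending MI order, but a candidate is only *admissible* when external
evidence supports it: an interaction-database pair for either parameter
kind, or a directed route in the original pathway for path coefficients
only (covariances represent hidden common causes, which a directed route
does not license). An accepted parameter must also keep the model bow-free
and block-recursive and survive a one-sided z test
($|z| \ge 1.64$, i.e. one-sided $P < 0.05$); otherwise it is removed and
permanently blacklisted. The loop stops as soon as the model reaches a
non-significant likelihood-ratio test ($P > 0.05$), a non-rejected close
fit, or an adequate SRMR. Two guards guarantee termination, since the bare
stopping rule can otherwise loop on a model that never reaches adequacy:
the loop also exits when no admissible candidate remains, and a
configurable step cap (`max_steps = 50`) bounds the worst case. The log
records every attempt with its MI, evidence source, z and the fit indices
after the step, and `replay_refinement()` rebuilds the final specification
from the initial model and the log exactly.

Ties between equal MIs are broken lexicographically by (target, source) so
refinement paths are reproducible.

## Two-group analysis

Groups are coded experimental = 1, control = 0, and compared by joint ML
with the mean structure on (`fit_two_group()`), means parameterised as
intercepts (conditional means given parents). Two omnibus
likelihood-ratio tests come first: equal means under a shared covariance
structure (df = number of variables) and equal covariance structure with
free means (df = number of free path coefficients and error
(co)variances). Three Wald screens follow:

* **Node screen ($t_C$).** The group difference in each variable's
  intercept from the shared-covariance fit. This equals the path
  coefficient a 1/0 group-indicator node would get, but the two-group form
  reuses the omnibus machinery and keeps the indicator out of the
  refinement search space. The SE uses the full joint parameter
  covariance (intercepts are correlated through the shared structure).
* **Edge screen ($t_D$).** $d_{ij} = b_{ij}^{(1)} - b_{ij}^{(2)}$ from the
  unconstrained fit, with $SE(d_{ij}) = \sqrt{SE_1^2 + SE_2^2}$ — exact
  here because with no shared parameters the groups are independent.
  Free error covariances are screened the same way (labelled
  up/down-associated rather than up/down-regulated).
* **On/off screen ($t_1, t_2$).** Per edge and per group, a one-sided test
  of $\beta = 0$ in the direction implied by the a-priori interaction
  type: positive for activation and phosphorylation, negative for
  inhibition, and the sign of the pooled estimate for untyped edges
  (binding, indirect, evidence-derived). An edge is ON in a group when the
  one-sided $P$ falls below `alpha = 0.05`.

P-values are asymptotic normal by default; `pvalue_method = "bootstrap"`
replaces the SE of a difference by a within-group nonparametric bootstrap
SE with `bootstrap_reps` replicates (default 1000; 100 is a reasonable
quick setting). Tables are reported unadjusted, matching common practice
for these screens; `adjust_pvalues(..., "bh")` appends a
Benjamini–Hochberg column when many edges are screened at once.

Exact antisymmetry holds by construction: swapping the group labels
negates every difference, leaves every two-sided P unchanged and mirrors
the ON/OFF labels — the test suite checks this to numerical tolerance.

## The synthetic scenario generator

`make_scenario()` defines the study conditions used throughout the tests.
Its truth is two independent gene chains ("branches") with all error
variances 1 and chain coefficients `beta_base = 0.6` — comfortably inside
the stable region and typical of standardized expression data — plus one
cross-branch edge (`extra_beta = 0.8`) present in the generating model and
the evidence set but *not* in the pathway graph. Because the branches are
otherwise independent, no within-pathway directed route can proxy for the
missing edge, so its recovery isolates the evidence-gated refinement
mechanism; the coefficient is set high enough that the initial model
clearly fails all three adequacy checks at the default sample size, which
is what lets the refinement loop engage at all. Group differences follow
the generator defaults of `delta_mu = 1` residual SD on two genes and
`delta_beta = 0.5` on one coefficient at `n_per_group = 150` — moderate
effects detectable with conventional power at this n. Decoy genes are
attached as a strictly-longer detour and dead ends, so they pad the
pathway without entering any geodesic. Superfamily pairs are chosen among
chain-adjacent connectors (so members are correlated and collapsing them
cannot create long feedback cycles) and never overlap planted-effect
genes.

What the generator emulates: jointly Gaussian expression with a sparse
causal structure, group differences in means and in regulatory strengths,
incomplete pathway knowledge, and noisy-but-relevant external evidence.
What it does not emulate: heavy tails and outliers, measurement batch
effects, feedback loops longer than two genes, probe-level noise, and
pathway graphs whose edge semantics are wrong rather than merely
incomplete. Passing the recovery suites therefore demonstrates that the
machinery works under its own assumptions, not that real microarray data
meet them.

## Numerical choices and degenerate inputs

* Sample covariances must be positive definite; $n \le p$ draws a warning
  (and will usually fail the PD check).
* `I - B` singular or $\Sigma$ not positive definite during optimisation
  is handled by a large finite objective value, steering the line search
  away instead of aborting.
* Saturated models report SRMR and chi-square below $10^{-6}$ and have no
  RMSEA (df = 0 is an error for `rmsea()` itself).
* Hessians are central finite differences of the analytic gradient
  (step $10^{-5}$ relative for SEs, $10^{-4}$ for MI Schur complements).
* Non-convergent refinement refits blacklist the candidate and continue;
  non-convergent bootstrap replicates are skipped and counted in a
  `failure_rate`.
* All randomness (restart jitter, bootstrap, simulation) flows through
  explicit seeds, and seeded code restores the caller's RNG state.

## Problem sizes used by the validation suite

The test suite exercises the operating characteristics at sizes chosen to
make Monte-Carlo error small while keeping a laptop-scale run: type-I
error of the LRT and of both omnibus tests at 500 replicates (5-variable
chain, n = 200 or 100 per group), parameter recovery at n = 5000,
MI-versus-refit accuracy at n = 1000 with a planted coefficient of 0.1,
and planted-edge refinement recovery over 100 generator seeds at the
default scenario. The acceptance bands (rejection rates within 0.03–0.07,
recovery at least 90/100) are stated in `tests/testthat/test-acceptance.R`.

## Known limitations

* Observed variables only: no latent constructs beyond PC1 composites,
  and composites ignore their measurement error downstream.
* Two groups only; no covariates, no more-than-two-group invariance
  testing.
* The refinement search is greedy and univariate; it inherits the usual
  caveats of stepwise model search, mitigated but not removed by the
  evidence gate.
* Asymptotic P-values at small n (tens of samples) are approximate; the
  bootstrap option is the conservative alternative.
* Equivalent models: a freed covariance and a freed path coefficient can
  fit identically; the evidence gate arbitrates, but direction claims
  ultimately rest on the pathway/evidence priors, not the data.
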