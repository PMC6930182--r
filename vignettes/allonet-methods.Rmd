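---
title: "Methods: functional mapping of allometry QTLs and ODE-based QTL control networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional mapping of allometry QTLs and ODE-based QTL control networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

# The scientific problem

Shoot height and shoot diameter do not grow independently: how height gains
scale with diameter gains (and vice versa) is a heritable developmental
property. `allonet` implements two connected analyses for longitudinal
height/diameter data from a full-sib mapping family:

1. **Functional mapping of allometry QTLs.** A likelihood-ratio scan over
   SNP markers that tests, marker by marker, whether genotype classes differ
   in the parameters of a height–diameter allometry equation. Direction
   `PI` (height as a function of diameter) detects *pioneering* QTLs
   (piQTLs); direction `MI` (diameter as a function of height) detects
   *maintaining* QTLs (miQTLs).
2. **QTL control-network reconstruction.** Each detected QTL carries a
   time-indexed genetic-effect curve. The time derivative of a focal QTL's
   curve is decomposed, through a system of ordinary differential
   equations, into an *independent* component (a function of the focal
   QTL's own effect) and *dependent* components contributed by other QTLs.
   Nonzero dependent components define signed, weighted, directed edges of
   a QTL–QTL network.

A simulation study (the `build_eq10_network()` / `run_scenarios()` pair)
quantifies how well the network reconstruction recovers a known 14-QTL
topology under four sampling/noise scenarios.

# The allometry equation

The bidirectional height–diameter model is

$$H(t) = H_0 + \exp\!\big(a + d/(b + D(t))\big), \qquad
  D(t) = \frac{d}{a - \ln(H(t) - H_0)} - b,$$

two algebraically inverse forms of one scaling law (matched by the sign
convention $d_{H\leftarrow D} = -d_{D \leftarrow H}$). $a$ controls the
late-stage asymptote ($H \to H_0 + e^a$ as $D \to \infty$), $b$ the
early-stage behaviour, and $d$ is a relative rate that spreads the curve
along the predictor axis. `fit_allometry()` fits either direction by
derivative-free simplex (Nelder–Mead) least squares, started from a
log-scale linearisation (for fixed $b$, $\ln(H - H_0)$ is linear in $a$ and
$d$) plus five jittered restarts; convergence tolerance is `1e-10` on the
relative RSS with at most 2000 iterations per start. `compare_models_aic()`
ranks the equation against a power law and a straight line with
$AIC = n\ln(RSS/n) + 2k$, ties broken toward fewer parameters.

$H_0$ is a *fixed input* in the scan — each individual's first height
observation — not a fitted parameter; `fit_allometry(fit_h0 = TRUE)`
frees it for the mean-curve use case. For the `MI` direction the baseline
appears inside $\ln(H - H_0)$ evaluated at every occasion including the
first, where a per-individual first-observation baseline would give
$\ln 0$; the scan therefore uses a single global baseline (default 0,
`h0_global`) for that direction, while `PI` keeps the per-individual
baseline.

# The functional-mapping likelihood

For marker genotype class $j$, individual $i$, occasion $t$, the response
trait's mean is the allometry equation evaluated at that individual's
*observed* co-trait value; residual vectors are modelled as mean-zero
multivariate normal with a stationary AR(1) covariance
$\sigma^2 \rho^{|s-t|}$ shared across genotypes. The AR(1) log-density is
computed in closed form via the Markov factorisation (equivalently, the
closed-form determinant $\sigma^{2T}(1-\rho^2)^{T-1}$ and tridiagonal
inverse); no generic $O(T^3)$ solve appears in the scan's hot path.
Missing occasions contribute their observed sub-vector under the exact
marginal law (conditional correlations $\rho^{\delta}$ across a gap
$\delta$).

Maximisation is by block alternation: for fixed $\rho$ the genotype groups
decouple, so each group's $(a, b, d)$ is updated by a 3-parameter simplex
minimising its AR(1) quadratic form; $\sigma^2$ then has a closed-form
profile and $\rho$ a 1-D profile search. The alternative (genotype-specific)
fit starts from the null solution, which enforces the likelihood nesting
$\ell_1 \ge \ell_0$ by construction. The likelihood-ratio statistic
$2(\ell_1 - \ell_0)$ is referred to $\chi^2$ with $3(J-1)$ degrees of
freedom — only the $(a,b,d)$ triple is genotype-specific, baselines are
data and the AR(1) pair is shared. Genome-wide significance uses a
Bonferroni correction within marker cross type by default (testcross and
intercross markers each get their own threshold, mirroring the two
threshold lines of a two-type Manhattan plot); `correction = "combined"`
pools them.

Genotype classes below a minimum count (default 10) make a marker
unusable; such markers are skipped with a logged reason rather than
scanned.

## Effect curves

For a significant testcross QTL the effect curve is the difference of the
two genotype mean curves, averaged over individuals within genotype at each
occasion (an average, not a bare sum — a sum would scale with group size
and break the genotype-difference interpretation). Intercross QTLs
additionally decompose into an additive curve (first homozygote minus
heterozygote) and a dominant curve (heterozygote minus the homozygote
mid-point); the additive curve doubles as the QTL's overall effect curve
when it enters the network stage. Curves are indexed by measurement
occasion and annotated with the population-mean predictor value, so they
can be plotted against diameter/height or fed to the ODE module against
time.

# The ODE decomposition

For effect curves $P_k(t)$ on a common grid, the model is

$$\frac{dP_k}{dt} = U_k(P_k(t)) + \sum_{k' \ne k} U_{kk'}(P_{k'}(t)),$$

with every $U$ a Legendre polynomial expansion of order $r$ (default 4) in
its own argument, rescaled to $[-1,1]$ over the argument's observed range.
The independent function $U_k$ carries a constant term; the dependent
basis functions are anchored to vanish at argument zero
($U_{kk'}(0) = 0$), which fixes the gauge between the components — with
unanchored bases, constant parts of a regulator's contribution migrate
into the independent term and the decomposition (and its edge signs) is
not identified. An all-zero regulator thus contributes exactly nothing
and "zero weight" coincides with "absent edge".

**Identifiability is the central design issue.** If a focal trajectory is
monotone, its derivative is exactly some function of its own value, so the
independent component can absorb any regulator's contribution and edges
are unrecoverable in principle. Information about *which* QTL regulates a
focal QTL comes from *folds* — occasions where the trajectory revisits a
value with a different derivative. Along a fold the self-term cancels and
the needed correction, as a function of time, pins down the regulator.
This observation shaped both the reconstruction defaults and the
simulation design below.

## Regulator selection

`select_regulators()` regresses the numerically differentiated focal curve
(central differences inside, one-sided at the ends) on the candidates'
basis expansions under a group-sparsity penalty — one coefficient group per
candidate, solved by block coordinate descent after groupwise
orthonormalisation — with the focal's own basis unpenalized. The penalty
path is 20 log-spaced values; the per-focal operating point is the
extended-BIC minimum ($\gamma = 0.5$) over path positions whose model
degrees of freedom stay below the series length, with the RSS floored at a
relative `1e-10` so near-interpolating fits cannot drive the criterion to
$-\infty$.

Curves are presmoothed before differencing with a smoothing spline at
`min(10, T - 2)` equivalent degrees of freedom — enough flexibility for
the one or two turning points an effect curve shows while suppressing
measurement noise; `df = NULL` in `smooth_curve()` selects smoothness by
GCV instead, which we found under-smooths serially correlated residuals.

## Network assembly

`build_network()` reconstructs the whole network in two passes:

* **Pass 1 — marginal scores and source propensity.** For every ordered
  pair, the *marginal score* is the fraction of the focal's residual
  derivative (after the unpenalized independent-component fit) explained
  by the candidate's basis alone. Because these networks are sparse with a
  few hub regulators, a QTL's evidence of regulating *many* targets is
  itself informative: the per-QTL *source propensity* is the row mean of
  the score matrix, and the per-pair ROC score is
  `marginal * propensity^cooperation` (default exponent 2).
* **Pass 2 — coordinated sparse selection.** The per-focal group-lasso
  paths are run with adaptive, pair-specific penalty multipliers aligned
  with the cooperative score (exponent `pf_exponent = 2.5`, clamped to
  `[0.1, 10]`); a candidate never admitted at an identifiable path
  position (model degrees of freedom below the series length) is screened
  out. The operating point is then score-based and coordinated across the
  network: selected pairs must score at or above the global
  75th-percentile of all ordered-pair scores
  (`score_floor_quantile = 0.75`) and above a chance-anchored floor on the
  raw marginal score (1.25 times the `r/(T - r - 1)` fraction a rank-`r`
  basis explains of pure noise, applied in the informative regime), and a
  sparse in-degree prior retains at most `max_in_degree = 3` regulators
  per focal, ranked by the cooperative score. Per-focal BIC alone proved
  badly calibrated here: co-regulated curves are so collinear that each
  focal's own criterion either over-selects proxies or drops true
  regulators; the cooperative, network-coordinated operating point is the
  package's answer, with `select_regulators()` retaining the plain
  per-focal extended-BIC behaviour for standalone use.

Edges are quantified from the refitted ODE (`fit_qdode()`): each focal's
coefficients minimise the squared distance between its observed curve and
the 4th-order Runge–Kutta solution of its equation started at the first
observation, regulator curves held at their observed (linearly
interpolated, smoothed) values — per-focal fitting is exact because the
equations decouple given observed regulator curves. The estimator is
integral-matching least squares: because the trajectory is linear in the
coefficients when every `U` is evaluated along the observed curves, the
observed increments are regressed on cumulatively integrated basis
columns. This is far better conditioned than matching finite-difference
derivatives and leaves the component decomposition stable; an optional
Nelder–Mead refinement of the exact RK4 trajectory objective
(`polish = TRUE`) can lower the trajectory error slightly but perturbs
the decomposition along weakly identified directions, so it is off by
default. Trajectories that blow up return a large finite penalty rather
than NaN, and unstable initialisations are damped toward zero until they
integrate. Edge weight is the mean absolute derivative contribution
$\mathrm{mean}_t\,|U_{kk'}(P_{k'}(t))|$; edge sign is the sign of the
time-averaged dependent curve, with an exact-zero tie broken by comparing
positive and negative areas (ties to `+`). The integrator accumulates each
component with the same Runge–Kutta stage weights, so
*initial value + independent + dependents = total* holds to machine
precision (`decompose_effects()` asserts it), and halving the step changes
fitted trajectories by well under `1e-6`.

Interaction types label every unordered pair from the two directed edge
signs (absent = 0): symmetric positive epistasis (+/+), symbiosis (0/0),
negative epistasis (−/−), directional positive (+/0), directional negative
(0/−), and altruistic/repressive (+/−). A hub is a node whose total degree
exceeds the network's mean total degree. Networks can be inferred
separately for piQTL, miQTL, and pooled curve sets; intercross QTLs enter
through their additive effect curve.

# The synthetic mapping population

`simulate_population()` generates full-sib data with planted causal QTLs.
Genotypes segregate 1:1 (testcross) or 1:2:1 (intercross), independently
across markers — linkage adds nothing to testing the scan machinery. The
predictor trait grows *mechanistically* (per-individual logistic curves
with jittered asymptote, rate and midpoint), not from the allometry
equation, so the two scan directions are not trivially symmetric — as in
real data, where both directions are informative. The response trait is
the genotype-specific allometry of the individual's observed predictor
plus stationary AR(1) noise.

Defaults are sized to the motivating materials: 180 progeny, 12 roughly
biweekly occasions, mixed testcross/intercross markers, baseline
parameters ($a = 4.2$, $b = 1$, $d = -21$ for the height-from-diameter
direction) chosen so the height increment is negligible at the first
occasion (the first observation then really is the baseline, making the
planted parameters recoverable) and rises to a few tens of centimetres
over a season of diameters growing from about 1 to 25 mm. Response noise
defaults to sd 1.5 cm with lag-1 correlation 0.5 — about 5% of the height
range. One allometric direction of causal specs per population: mixing
planted piQTLs and miQTLs in one call is rejected, and when several causal
specs are given the first applicable one sets an individual's parameters.

What the generator does *not* emulate: linkage and interval structure,
segregation distortion, errors in the predictor variable (the likelihood
treats predictors as fixed covariates, as the mean model does),
year-to-year environmental structure, and selective genotyping. Passing
tests therefore demonstrate correctness of the machinery under the model's
own assumptions, not robustness to violations of them.

# The 14-QTL simulation study

`build_eq10_network()` draws a "true" 14-node system with 18 directed
edges: a hub (`Q2`, in-degree 0) regulating nine targets, and two
secondary regulators (`Q10`, `Q13`) with four and five targets. True
component functions are bistable cubic self-dynamics
$U_k(Q) = \alpha_k Q (1 - (Q/K_k)^2)$ — genetic effects may rise, fall and
change sign during ontogeny — with signed linear couplings
$\beta_{kk'} Q'$. The true coefficient values are not published for the
original estimates this study emulates, so they are drawn once from
declared ranges under a fixed seed, chosen to satisfy two structural
requirements:

* curve magnitudes of order 1–5 trait units; and
* *fold-rich* dynamics: regulating nodes are slow and sustained
  ($\alpha \in [0.15, 0.35]$, $K \in [3.5, 6]$), regulated nodes fast with
  smaller attractors ($\alpha \in [2, 4]$, $K \in [2, 5]$,
  $|\beta| \in [0.3, 0.6]$), and each regulated node starts in the basin
  its net incoming push will eventually overcome. Draws are rejected
  unless at least 11 of the 13 regulated trajectories fold (both rise and
  fall by more than 15% of their range), no curve is nearly flat, and the
  solution stays within a declared band.

Without folds the edges would be unidentifiable for *any* method (see
above); with sharp folds, dense sampling ($T = 30$, grid spacing 0.34 on a
span of 10) resolves them while sparse sampling ($T = 10$) aliases them —
reproducing the qualitative regime the study design probes: recovery is
strong at dense sampling and low noise and approaches chance as sampling
thins and noise grows.

Each scenario replicate adds stationary AR(1) noise (variance $\nu^2 \in
\{0.05, 0.5\}$, lag-1 correlation 0.5 — the correlation is a package
default, configurable) to the coupled solution at $T \in \{10, 30\}$
occasions. `evaluate_network()` scores directed-edge recovery over the
$14 \times 13 = 182$ ordered pairs: $TPR = TP/18$, $FPR = FP/164$ (the
printed summary states these denominators, which cannot be reconciled with
every combination in the original report), and ROC-AUC by sweeping a
threshold over the cooperative pair scores (Mann–Whitney form via `pROC`).
`run_scenarios()` averages over seeded replicates (default 100;
`fit_ode = FALSE` skips the per-edge ODE refit, which does not change
detection), records failures, and flags a scenario invalid past 20%
replicate failures.

# Numerical choices, in one place

* Simplex tolerance `1e-10` (plain least squares) / `1e-9` (profile
  likelihood alternation, max 8 outer iterations, convergence `1e-8` on
  the log-likelihood).
* $\rho$ profiled on $(-0.99, 0.99)$, $\sigma^2$ in closed form, both
  re-estimated under null and alternative.
* RK4 with 8 substeps per grid interval by default (truth solving in the
  simulator uses 20); blow-up guard at $|P| > 10^6$ with a `1e10`
  objective penalty.
* Group-lasso BCD: tolerance `1e-5`, 80 sweeps max, warm starts along the
  20-point path, `lambda_min_ratio = 1e-3`.
* Degenerate inputs: constant response → $d = 0$ closed form; degenerate
  basis range → zero basis; zero focal derivative → empty regulator set;
  monomorphic or under-filled markers → skipped with reason.
* Problem sizes in the test suite and acceptance script: scan power uses
  100 replicates of an $n = 180$, $T = 12$, 50-marker population;
  type-I calibration uses 500 null replicates at $n = 120$, $T = 10$;
  network recovery uses 30 replicates per scenario. These sizes give
  stable Monte-Carlo estimates of the quantities asserted while keeping a
  full run in the minutes range on one core.

# Known limitations

* The AR(1) structure is stationary; antedependence, ARMA or
  nonparametric covariances are not implemented (the covariance interface
  is a single pluggable kernel, so they could be added).
* The scan tests markers directly; there is no interval mapping between
  markers and no multi-family meta-analysis.
* Regulator selection inherits the identifiability ceiling discussed
  above: edges into QTLs whose effect curves are monotone are ambiguous,
  and co-regulated siblings of a true regulator are its natural
  confounders. The cooperative (hub-aware) weighting mitigates but cannot
  remove this; reported false-positive edges concentrate there. Relative
  to the motivating study's reported degradation, this implementation
  retains more accuracy under sparse sampling and high noise; since the
  original true parameters are unpublished, the adverse-scenario gap
  cannot be attributed to method versus test-bed differences.
* Eq.-style intercross QTLs enter the network via their additive curve
  only; dominance dynamics are not modelled in the ODE stage.
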