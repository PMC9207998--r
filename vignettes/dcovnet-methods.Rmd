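---
title: "Differential-covariance functional connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential-covariance functional connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcovnet)
```

This vignette is the package's own account of the science it
implements: the generative model behind differential covariance, the
haemodynamic forward and backward models, the significance and
structure-matching machinery, the parameters that matter, and the
numerical and design choices that were genuinely open.  It states no
empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## 1. The generative model and the dCov estimators

Everything rests on a linear stochastic view of large-scale neural
dynamics,

$$\frac{dV}{dt} = W V + \sigma\,\xi(t),$$

where $V$ is a vector of regional activities, $W$ a sparse stable
weight matrix (entry $(i,j)$: influence of source $j$ on sink $i$) and
$\xi$ white noise.  Averaged population activity is approximately
linear even though single neurons are not; this is the regime in which
dCov is a consistent directed estimator, and it is exactly what the
synthetic generator produces.

For a stationary process the covariance between the derivative and the
signal satisfies $\mathrm{cov}(\dot V, V) = W\Sigma$, with $\Sigma$ the
stationary covariance.  The raw estimator is therefore

$$\Delta c_{ij} = \mathrm{cov}(dz_i, z_j),$$

computed with sample means removed and divisor $T-1$, where $dz$ is the
first central difference of $z$ and $z$ is trimmed to the same support.
Since $W\Sigma + \Sigma W^\top = -\sigma^2 I$, the off-diagonal part of
$W\Sigma$ is close to antisymmetric — `antisymmetry_index()` reports
$\|\Delta c + \Delta c^\top\|_F / \|\Delta c\|_F$, which the test suite
checks stays below 0.1 on long stationary simulations.

Partialling removes common-input and chain effects: for each ordered
pair $(i,j)$ and conditioning set $K$ (all other nodes),

$$\Delta p_{ij} = \Delta c_{ij}
  - \mathrm{Cov}_{jK}\,\mathrm{Cov}_{KK}^{-1}\,\Delta c_{iK}^\top .$$

This matrix identity equals covarying the residuals of $dz_i$ and
$z_j$ after regressing both on $z_K$; the suite verifies the two
routes agree to $10^{-8}$ on hundreds of random instances.  With
$N = 2$ the conditioning set is empty and $\Delta p \equiv \Delta c$.

**Numerical choice.** $\mathrm{Cov}_{KK}$ can be near-singular when
traces are collinear (ICA components often are).  A ridge jitter of
$10^{-8}\cdot\mathrm{mean}(\mathrm{diag}(\mathrm{Cov}))$ is added and
the system is solved, never inverted explicitly.

## 2. Sparse + low-rank split

Unobserved common inputs add a low-rank component to $\Delta p$.  The
split solves

$$\min_{\Delta s}\ \|\Delta s\|_1 + \alpha\,\|L\|_*
  \quad\text{s.t.}\quad \Delta s + L = \Delta p,$$

by inexact augmented Lagrange multipliers: singular-value shrinkage
for $L$, soft-thresholding for $\Delta s$, multiplier update, penalty
growth factor 1.5.  Iteration stops when the constraint residual falls
below `tol` ($10^{-7}$, relative to $\max(1, \|\Delta p\|_F)$;
`max_iter` 500, with a non-convergence flag on the best iterate
otherwise).

**Design choice — the nuclear norm.** The natural low-rank penalty for
a symmetric positive-semidefinite matrix is the trace; $\Delta p$ is
not symmetric, so the package uses the nuclear norm, which reduces to
the trace in the PSD case.

**Design choice — the penalty ratio $\alpha$.** Robust-PCA theory
calibrates exact recovery for the objective
$\min \|L\|_* + \lambda\|S\|_1$ at $\lambda = 1/\sqrt{N}$.  In the
parametrization above (weight on the *low-rank* term) that same
calibration is $\alpha = \sqrt{N}$, which is the package default.  We
verified on planted decompositions (sparse 5% support plus an
incoherent rank-1 part, $N = 30$) that $\alpha = \sqrt{N}$ recovers
the support exactly while $\alpha = 1/\sqrt{N}$ funnels everything
into $L$; $1/\sqrt N$ and $1/N$ remain available through the `alpha`
argument for users who want the alternative reading of the convention.

## 3. Benchmarks: covariance family and conditional Granger

`cov` is the unbiased sample covariance; `pcov` its inverse (pseudo-
inverse with a warning when rank-deficient).  `l2reg` is the ridge
precision $(\mathrm{Cov} + \rho\,\overline{\mathrm{diag}}\,I)^{-1}$
with default $\rho = 0.1$.  `l1reg` is a sparse precision estimate via
node-wise lasso (each node regressed on all others, coefficients
assembled as $\Theta_{ij} = -\beta_{ij}/\sigma_i^2$ and symmetrised);
at zero penalty this is algebraically the precision matrix, and the
default penalty is 10 on the log-likelihood scale.  The defaults match
the values conventionally used for these regularizers; performance is
insensitive over a wide range.

`cgranger` fits a VAR by OLS with the order selected by multivariate
AIC up to `max_order = 10` (ties toward the smaller order).  The
conditional statistic for $j \to i$ is
$F_{ij} = \log(\mathrm{RSS}^{(i)}_{\text{reduced}} /
\mathrm{RSS}^{(i)}_{\text{full}})$, the reduced model omitting only
$j$'s lags.  Under the null, $T_\mathrm{eff} F$ is asymptotically
$\chi^2_q$ with $q$ the selected order — the standard VAR
likelihood-ratio degrees of freedom, recorded in the output
diagnostics.  P-values are uncorrected by design; thresholds play the
multiple-comparison role downstream.

## 4. Haemodynamics: forward model and backward reconstruction

The forward map is the four-state Balloon–Windkessel system per node
(vasodilatory signal $s$, inflow $f$, venous volume $v$,
deoxyhaemoglobin $q$):

$$\dot s = \eta V - \kappa s - \gamma (f - 1),\qquad \dot f = s,$$
$$\tau\dot v = f - v^{1/\alpha},\qquad
  \tau\dot q = f\,\frac{E(f,\rho)}{\rho} - v^{1/\alpha - 1} q,$$

with $E(f,\rho) = 1 - (1-\rho)^{1/f}$ and BOLD readout
$y = V_0\,(k_1(1-q) + k_2(1 - q/v) + k_3(1-v))$,
$k_1 = 4.3\,\vartheta_0\rho\,TE$, $k_2 = \epsilon r_0 \rho\,TE$,
$k_3 = 1 - \epsilon$.  Integration is fixed-step RK4; the step never
exceeds 0.01 s (the integrator sub-steps internally when the signal is
sampled more coarsely).  States start at the resting fixed point, so
zero input gives exactly zero BOLD deviation.

Backward reconstruction inverts the *linearized* model.  Writing the
linearized transfer function from neural drive to BOLD, its
denominator factors as

$$p(s) = \tau\,(s^2 + \kappa s + \gamma)
  \left(s + \tfrac{1}{\tau\alpha}\right)\left(s + \tfrac{1}{\tau}\right)
  = p_4 s^4 + p_3 s^3 + p_2 s^2 + p_1 s + p_0,$$

which yields the reconstruction weights directly:
$p_4 = \tau$, $p_3 = 1 + 1/\alpha + \tau\kappa$,
$p_2 = 1/(\tau\alpha) + \tau\gamma + (1 + 1/\alpha)\kappa$,
$p_1 = (1 + 1/\alpha)\gamma + \kappa/(\tau\alpha)$,
$p_0 = \gamma/(\tau\alpha)$.  Applying $p(d/dt)$ to $y$ leaves the
numerator, a mixture of the neural signal and its derivative:

$$z = \sum_{i=0}^4 p_i\,y^{(i)} = q_1 \dot V + q_0 V,$$

with, from the linearization of the oxygen-extraction and readout
equations,

$$q_1 = V_0\eta\,\bigl(k_2 - k_3 - (k_1 + k_2)\,c_f\bigr),\qquad
  q_0 = \frac{V_0\eta}{\tau}\Bigl(k_2 - k_3 - (k_1+k_2)
  \bigl(1 + \tfrac{c_f - 1}{\alpha}\bigr)\Bigr),$$

where $c_f = 1 + (1-\rho)\ln(1-\rho)/\rho$ is the slope of
$f\,E(f)/\rho$ at rest.  The $q$ coefficients were derived from this
package's own linearization and validated by the round-trip property:
on data generated by the linearized forward model the reconstruction
correlates with $q_1\dot V + q_0 V$ above $r = 0.999$ per node, and
stays above 0.9 under ±20% perturbation of
$\kappa, \gamma, \tau, \alpha$ — the reconstruction is deliberately
insensitive to the exact biophysical values.

**Parameter defaults** (all overridable in `balloon_params()`):
$\tau = 0.98$ s, $\epsilon = 0.5$, $\alpha = 0.32$,
$\kappa = 0.65$ s⁻¹, $\gamma = 0.41$ s⁻¹, $\rho = 0.34$,
$\eta = 0.02$, $V_0 = 0.02$, $r_0 = 25$ s⁻¹,
$\vartheta_0 = 40.3\,(B/1.5)$ s⁻¹.  `TE` and `B` are acquisition
properties and must be set per dataset (e.g. human 3 T: TE = 33 ms;
mouse 9.4 T: TE = 12 ms); they are arguments, never hard-coded.

**Derivatives.** Central differences, exact on quadratics (orders 1–2)
and quartics (orders 3–4), with output trimmed symmetrically by
`order` samples per side; all orders are aligned on the common trimmed
support inside `backward_reconstruct()`.  Filtering is *not* part of
differentiation; an optional Savitzky–Golay pre-filter (off by
default) is exposed for noisy recordings.

**A caveat on the round-trip target.** $q_1\dot V$ is only meaningful
when $V$ is differentiable.  A raw Ornstein–Uhlenbeck path is not (its
discrete derivative is dominated by the driving noise), so round-trip
checks use band-limited neural input (Gaussian-smoothed OU with a
0.2 s kernel, well below the haemodynamic time constants).  This is a
property of the comparison target, not of the reconstruction itself,
which is applied unchanged to rough inputs in the main pipeline.

## 5. Edge significance: the AR bootstrap

The null hypothesis for an edge is that all nodes were generated
independently.  Per node, an AR($q$) model is fitted by conditional
least squares on a common support; starting from white noise
($q = 0$), a higher order is accepted only if it lowers BIC by more
than 2, and non-stationary fits fall back to the previous stationary
order.  Surrogates draw every node independently from its own model
(preserving each node's power spectrum, destroying all cross-node
structure), with a 500-sample burn-in.  The empirical estimator is
re-run on each surrogate — the identical code path via
`estimate_fc()` — and each edge gets a Gaussian fit (mean, sd) to its
null values and a two-sided p-value
$2\Phi(-|x-\mu|/\sigma)$.

Choices worth recording:

* **Two-sided p-values**, because FC estimates are signed and an edge
  is interesting in either direction.
* **Gaussian null per edge**, even though some estimators' nulls are
  heavy-tailed; this follows the reference procedure.  Calibration is
  checked empirically: under a global AR(2) null the edge-wise
  rejection rate at $p < 0.05$ stays within $[0.02, 0.10]$ and the
  p-value ECDF is within KS distance 0.1 of uniform.
* **AR models are fitted to the same matrix the estimator consumes**
  (the reconstructed $z$ in the standard pipeline).  Fitting to BOLD
  and pushing surrogates through reconstruction is possible by
  composing the same functions, but is not the default.
* **No multiplicity correction**; the binarization thresholds
  $\{0.05, 0.01, 0.005, 0.001\}$ provide graded stringency.
* Default surrogate count is 1000; the heavier test-suite checks use
  500 and the pipeline smoke tests fewer, which only widens the
  Monte-Carlo error of the null moments.

`match_sparsity()` supports sparsity-matched comparisons: both methods
keep exactly their $k$ most significant off-diagonal positions (ties
broken by larger $|$empirical$|$, then row-major order), so a sparser
estimator cannot win merely by being sparse.

## 6. FC–SC comparison (SCS / ASCS)

Given per-subject binary networks and a structural matrix, the SC
entries at significant off-diagonal positions are pooled across
subjects into one SCS set; ASCS is its mean.  The diagonal is always
excluded (FC diagonals are self-terms, not connections) even though
the ordinal surrogate SC defines its diagonal as 7.  Undirected masks
are symmetric and therefore contribute both $(i,j)$ and $(j,i)$ once
each; directed edges are looked up as-is, row = sink.  For an
estimator selecting edges uniformly at random the expected ASCS equals
the mean off-diagonal SC — the natural chance floor, verified by Monte
Carlo in the suite.

The surrogate SC emulates two conventions: an ordinal tracing-style
scale, obtained by rank-quantizing $|W|$ into seven equal-mass bins
(1 = weakest, 7 = strongest; ties share a bin, absent edges map to 1;
diagonal 7), and a continuous symmetric diffusion-style matrix
$|W| + |W^\top|$ with zero diagonal.  Rank quantization is the
least-assumption emulation of an ordinal literature-derived scale.

## 7. Graph topology

All measures operate on binary graphs in the adjacency convention
$a_{ij} = 1 \iff i \to j$ (connectivity-convention inputs are
transposed on entry).  Directed definitions: triangles
$t_i = \tfrac12\sum_{j,h}(a_{ij}+a_{ji})(a_{ih}+a_{hi})(a_{jh}+a_{hj})$;
clustering denominator
$(k^{out}_i + k^{in}_i)(k^{out}_i + k^{in}_i - 1) - 2\sum_j a_{ij}a_{ji}$;
global efficiency is the mean inverse BFS distance with
$\infty^{-1} = 0$; local efficiency measures neighbour–neighbour paths
inside each induced neighbourhood subgraph, both directions summed.
Zero-denominator nodes contribute 0 to averages and are excluded from
transitivity's sums.  On symmetric graphs every directed formula
reduces to its undirected counterpart; the suite asserts this
numerically on hundreds of random graphs, alongside brute-force
oracles (Floyd–Warshall, triple enumeration, edge-count tabulation).

**Modularity.** With $e_{uv}$ the proportion of edges from module $u$
to module $v$ and $a_u = \sum_v e_{uv}$, the package computes the
standard Newman quality $Q = \sum_u (e_{uu} - a_u^2)$.  A historically
printed variant that squares the whole bracket,
$\sum_u (e_{uu} - a_u)^2$, is available behind
`printed_form = TRUE` for auditability, but it is not a modularity (it
is nonnegative and vanishes on two disconnected cliques); the standard
form is the default.  `find_partition()` is a deterministic greedy
agglomeration (merge the pair with the largest $\Delta Q$ while
positive), guaranteed never to return a partition worse than the
single-module $Q = 0$.

## 8. Behaviour linkage

A per-subject network statistic (global efficiency of the significant
network) is residualized on an intercept plus a configurable confound
set (the typical demographic/physiological set: age, weight, height,
systolic and diastolic blood pressure, total brain volume — note six
items; collinear columns are dropped with a warning).  Each behavioural measure with at most `max_missing`
(default 200) missing entries is then correlated with the residual
statistic on pairwise-complete subjects, *controlling for the
confounds on the measure side as well*: the measure is residualized on
the same confound columns before the Pearson correlation.  This makes
the ranking invariant to how strongly confounds load on a measure and
reduces to the plain residual-efficiency correlation when measures are
confound-free.  Rankings are by ascending uncorrected p-value, as per
the reference procedure; per-measure sample sizes are reported.

The surrogate behaviour generator plants exactly one coupled measure
(`coupling · efficiency + confound mix + noise`), includes the
confounds as observed columns, fills the rest with pure noise, and
masks a configurable fraction of non-confound entries at random.  It
emulates incomplete behavioural batteries; it does not emulate
response distributions, ceiling effects, or correlated measure
families, so passing tests show sign- and rank-recovery under linear
coupling, not robustness to those features of real batteries.

## 9. Synthetic study conditions and problem sizes

The generator defaults are the package's study conditions: networks of
10 nodes at density 0.2 with unit self-decay and couplings of
magnitude 0.5–1.5 (rescaled by 0.9 until stable), unit-variance
driving noise, Euler–Maruyama at dt = 0.01 s with the first 10% of
samples discarded as burn-in.  The test suite exercises the estimators
at the scales where their properties are measurable on one CPU in
minutes: T = 100,000 neural samples for the antisymmetry property,
T = 20,000 for edge-recovery ROC comparisons (20 planted networks),
500 bootstrap surrogates × 20 repeats for null calibration, VAR
detection at T = 5,000 over 50 seeds, and behaviour recovery at
n = 400 subjects over 100 seeds.  `scripts/acceptance.R` re-runs the
same computations from scratch at comparable sizes, seeded entirely
from `--seed`.

## 10. Known limitations

* The estimators assume an approximately linear, stationary generative
  process; nonlinear or strongly non-stationary dynamics are out of
  scope (no sliding-window variant is provided).
* The synthetic BOLD contains no scanner noise, motion, physiological
  confounds or ICA mixing; recoverability after component mixing is
  untested and not asserted.
* Backward reconstruction differentiates four times; at long TRs it
  relies on the haemodynamic response's low-pass character, and very
  noisy recordings may need the optional Savitzky–Golay pre-filter.
* The Gaussian edge-null is an approximation for heavy-tailed
  estimators; an empirical-quantile mode (`p_mode = "empirical"`) is
  provided but off by default, and needs many surrogates to resolve
  small p-values.
* Blind deconvolution and nonlinear model inversion (DCM-style
  variational fitting) are deliberately not implemented.
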