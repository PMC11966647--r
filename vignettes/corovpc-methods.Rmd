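---
title: "Virtual coronary cohorts and correlated sensitivity analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual coronary cohorts and correlated sensitivity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(corovpc)
```

# What this package computes

`corovpc` implements a virtual cohort generator (VCG) for multi-vessel
coronary artery disease and the statistical machinery needed to analyse the
cohorts it produces. A cohort member is a parameter vector of a reduced-order
pulsatile model of the coronary circulation; the outputs of interest are the
fractional flow reserve (FFR) of each stenotic lesion,

$$\mathrm{FFR} = \frac{\overline{P_d}}{\overline{P_a}},$$

the ratio of time-averaged post-stenotic to aortic pressure over three
cardiac cycles under hyperaemia, together with cardiac output and left-main
(LM) flow. An FFR of 0.8 or less marks a haemodynamically significant
lesion. The pipeline is:

1. **sample** input vectors uniformly within published physiological ranges
   (34 parameters for the two-lesion patient type, 36 for three lesions);
2. **simulate** each virtual patient and apply waveform quality control;
3. **filter** the cohort with physiological acceptance criteria;
4. **recover** the correlations those filters induce among the accepted
   inputs with a Gaussian copula;
5. **train** kernel greedy (VKOGA) surrogates of each lesion's FFR;
6. **decompose** the cohort FFR variance with correlated variance-based
   sensitivity indices on Smolyak sparse grids.

# The reduced-order circulation model

The full-order model this package emulates is a one-dimensional pulse-wave
propagation model. That solver is out of scope here; `simulate_patient()`
instead integrates a lumped (zero-dimensional) network chosen so that *every*
input parameter of the full model retains a physically sensible, monotone
pathway to the outputs:

* **Left ventricle** — time-varying elastance
  $P_{lv} = [E_{min} + s\,E_{max}\,a(t)]\,(V - V_0)$ with a smooth
  $\sin^{2\kappa}$ activation. The unloaded volume $V_0$ comes from the wall
  volume fraction; peak elastance scales with the active-stress scaling
  parameter; passive stiffness with the fibre/radial stress parameters; the
  systolic fraction and peak sharpness are monotone affine maps of the
  sarcomere parameters and the active-stress curvature. Preload is the
  pulmonary venous pressure behind a mitral diode; the aortic valve is a
  second diode.
* **Systemic circulation** — three-element Windkessel. The resistance is
  `resistance_scale` times a reference; the compliance is
  `compliance_scale * C_ref / (E (1 - mu^2))`, so the Young modulus and
  Poisson ratio of the wall act through the compliance, as they would in a
  distributed model.
* **Coronary branches (LAD, LCx, RCA)** — an epicardial resistance computed
  from the idealized geometry (Poiseuille per segment, discounted by the
  Murray-law flow fraction each segment carries), a nonlinear stenosis
  element, and an R-C-R-C-R-C microvascular Windkessel whose myocardial
  compartment is loaded by the intramyocardial pressure
  $P_{im} = f_{im} P_{lv}(t)$ — this produces the systolic impediment and
  diastolic predominance of coronary flow. Microvascular resistance totals
  are sized from the resting perfusion pressure and the per-branch share of
  total coronary flow (default split LAD:LCx:RCA = 50:30:20), and divided by
  the hyperaemia factor throughout the simulation.
* **Stenosis element** — $\Delta P = R_v q + K_t q |q|$ with $R_v$ the
  Poiseuille resistance of the narrowed lumen and
  $K_t = k_t \rho / (2 A_0^2) (A_0/A_s - 1)^2$, $k_t = 1.52$. Severity is a
  *diameter* reduction. Note the turbulent coefficient is referenced to the
  unobstructed area $A_0$, the Young–Tsai/Borda–Carnot expansion-loss
  convention used by lumped stenosis models in the 1D-haemodynamics
  literature. The variant that references the throat area squared
  overestimates the expansion loss by a factor $(A_0/A_s)^2$ and makes
  mid-range (50%) lesions nearly occlusive, which is incompatible with the
  cohort-level FFR statistics this class of model is known to produce; we
  therefore use the $A_0$ convention.

The network is integrated with a fixed-step RK4 scheme at 1000 steps per
cardiac cycle, which is also the output sampling contract (every analyzed
cycle is distributed over exactly 1000 points). The integration runs 25
burn-in cycles during which the contractility scale $s$ is updated
multiplicatively once per cycle until the cycle-mean aortic pressure matches
the sampled mean-pressure input; three analyzed cycles follow with $s$
frozen. The burn-in length is deliberately *fixed* rather than adaptive:
freezing at a data-dependent cycle makes the input-to-FFR map discontinuous
at the switching boundaries, which measurably degrades surrogate
generalization. A run is a `solver_failure` when the state becomes
non-finite, or when the achieved mean pressure misses its target by more
than 1% — emulating the prematurely terminated runs of the full-order
solver (implausible parameter combinations, e.g. high target pressure with
low preload, genuinely cannot reach their operating point).

## Geometry

The epicardial tree is idealized: a 2 cm LM bifurcating into a 10 cm LAD
and an 8 cm LCx, and a 10 cm RCA; all side branches have 0.1 cm radius;
wall thickness is 10% of the radius; successive main-line radii follow
Murray's law ($r^3$ conservation). Lesions sit in segment C1 (RCA), the
proximal 4 cm portion of C7 (LAD; twice the length of C1 and C11, so the
longer LAD lesions fit), and C11 (LCx). The shared position parameter
locates each lesion fractionally within the free span of its host segment,
so any admissible length fits at any position. The LM proximal radius
(0.2 cm) and the 50:30:20 resting flow split are *assumptions* — the source
geometry is schematic — and are configurable in `build_geometry()`.

# Sampling, quality control, filtering

Inputs are independent uniforms over the printed ranges
(`sample_inputs()`). The per-vessel severity range is 30–70% and lesion
lengths 3–37 mm (LAD) / 3–17 mm (LCx, RCA). Two parameters deserve note:
the table row for the two myocardial resistance fractions is interpreted as
*two* entries sharing one printed range, and the stenosis position is *one*
parameter shared by all lesions — the unique reading consistent with the
printed dimensions 34 = 29 + 2·2 + 1 and 36 = 29 + 3·2 + 1.

Waveform QC (`qc_waveform()`) low-pass filters the aortic pressure with a
zero-phase (forward–backward) second-order Butterworth filter (1000 Hz
sampling, 100 Hz cut-off) and rejects the run if the removed high-frequency
residual has RMS strictly above 4 Pa. The physiological filters
(`apply_physiological_filters()`) keep patients with diastolic aortic
pressure strictly above 50 mmHg, systolic strictly below 150 mmHg, LM flow
within [300, 900] ml/min and cardiac output within [3.5, 6] l/min. The
pressure bounds are strict ("above"/"below"); the flow and output bounds
are inclusive — the source wording does not fix inclusivity, so this is a
documented choice. Rejections are logged with the first violated criterion
in the fixed order solver → oscillation → diastolic → systolic → LM flow →
cardiac output, plus the complete violation list.

# Copula correlation recovery

Acceptance filtering makes the retained inputs dependent even though they
were sampled independently. `fit_gaussian_copula()` estimates that
dependence with rank-based normal scores: each column is mapped to
$(\mathrm{rank}-0.5)/n$, through $\Phi^{-1}$, and the Pearson correlation
matrix of the scores is the copula correlation. This separates the
correlation structure from the marginals (which remain the sampling-range
uniforms downstream) and is robust to any monotone marginal
transformation; we use it in place of maximum-likelihood copula fitting —
a deviation of estimator, not of model class. Correlation matrices are
repaired to positive semi-definite by eigenvalue clipping only when the
violation is below 1e-6; anything larger errors.

`inverse_rosenblatt()` maps unit-cube points to input space: normal
quantiles, correlation through the Cholesky factor of the (permuted)
matrix, normal CDF, marginal quantiles. The ordering argument selects the
conditioning sequence; the implied joint law is ordering-invariant.

# Kernel surrogates

`train_vkoga()` builds the surrogate
$S(x) = \sum_{j=1}^{n} \alpha_j K(x, x_j)$ with the Matérn k2 kernel
$K(\epsilon, r) = e^{-\epsilon r}(3 + 3\epsilon r + (\epsilon r)^2)$ on
inputs min–max scaled to the unit cube. Centers are chosen f-greedily (the
point of largest absolute residual), with numerically stable Newton-basis
updates; the residual maximum is non-increasing by construction, and the
surrogate interpolates its training values at the centers. The shape
parameter is selected by a held-out grid search over a log-spaced grid
(default $10^{-1}$–$10^{1}$); the source work adopts its hyperparameter
settings from an earlier paper that does not restate them, so the grid
search is a documented substitute. Surrogates are trained on the
*pre-filter* (QC-passing) population — non-physiological but valid
input/output pairs carry information about the model map and need not be
discarded for regression.

Validation follows the source protocol: at least 2500 training samples,
the remainder (~800) held out; RMSE and nRMSE (RMSE divided by the mean
held-out FFR) per Eq.-style definitions, and Bland–Altman limits of
agreement (mean ± 1.96 SD of the differences).

# Correlated sensitivity indices

For output $Y$ and input $X_i$ the two total indices are

$$S_i^{TC} = \frac{V(E(Y \mid X_i))}{V(Y)}, \qquad
  S_i^{TU} = \frac{E(V(Y \mid X_{-i}))}{V(Y)},$$

computed under the copula (correlations included). They decompose as
$S^{TC} = S^U + S^C$ and $S^{TU} = S^U + S^{IU}$, where $S^U$ is the
uncorrelated main effect, $S^C$ the correlation-attributed share and
$S^{IU}$ the uncorrelated-interaction share. $S^U_i$ is defined through the
*innovation* of $X_i$: with $X_i$ last in the Rosenblatt ordering, the last
cube coordinate drives exactly the component of $X_i$ independent of
$X_{-i}$ in the latent Gaussian space, and
$S^U_i = V(E(Y \mid u_i))/V(Y)$. The estimator placement — $X_i$ *first*
for $S^{TC}$ (outer 1D rule over its own coordinate, inner sparse grid over
the conditional remainder), $X_i$ *last* for $S^{TU}$ and $S^U$ — is
validated against closed forms (linear-Gaussian, Ishigami, additive)
rather than against any unpublished reference implementation; exact numeric
parity with the source appendix tables is not claimed. $S^C$ and $S^{IU}$
are computed as differences, so the decomposition identities hold exactly,
and negative values (a legitimate signature of correlation/interaction
effects) are never clipped.

## Quadrature

Integrals are evaluated with Smolyak sparse grids: multi-index set
$\{\,l \in \mathbb{N}_0^d : \sum_j l_j \le L\,\}$ with $L = k - 1$ for
paper-style accuracy level $k$, nested 1D Clenshaw–Curtis rules of sizes
1, 3, 5, 9, … ($2^l + 1$), and combination-technique (difference-rule)
weights. This is the unique convention that reproduces both printed grid
cardinalities: 54,877 nodes at $d = 34$ and 64,969 at $d = 36$ for $k = 4$
(`count_smolyak_nodes()`, cross-checked by enumeration). The level-3 1D
rule has 9 points, hence polynomial exactness of degree 8 ≥ 7
("seventh-order exactness" is asserted as a lower bound). For *unbounded*
(normal) marginals — used only by the analytic benchmarks —
Clenshaw–Curtis in the cube coordinate is singular through
$\Phi^{-1}$; those dimensions use Gauss–Hermite rules expressed in the
cube (nodes $\Phi(z_j)$), which integrate polynomials of the latent
Gaussian variable exactly. Cohort marginals are bounded uniforms, so the
cube endpoints always map to finite bounds.

Two numerical caveats, verified by the test suite:

* The accuracy-4 grid (69 nodes in $d=3$) resolves polynomial and
  linear-Gaussian benchmarks exactly but *cannot* resolve the Ishigami
  variance (it needs simultaneous high order in two dimensions, outside the
  level budget). The Ishigami benchmark is therefore asserted at accuracy 7,
  where the indices are converged to ~1e-5; accuracy 2/3/4 enter the
  convergence-ordering check instead (the 3→4 change is smaller than the
  2→3 change, mirroring the source's convergence study).
* Combination weights are signed; small indices can be slightly negative
  within quadrature tolerance. This is expected and not clipped.

# What the synthetic generator does and does not establish

The generator emulates: uniform input variation over the printed ranges,
a physics map with every parameter live (a 10%-of-range perturbation of any
input changes at least one output), per-lesion FFR with the correct
qualitative drivers (severity, mean pressure, hyperaemia factor, total
coronary flow), solver-failure and oscillation pathologies, and
filter-induced input correlations. It does **not** reproduce wave
propagation (no reflection, no pulse-wave velocity; the source's negative
post-stenotic LAD pressures are a 1D phenomenon this engine cannot show),
nor the exact failure counts of the full-order solver (those are
solver-specific), nor the source's clinical-data comparisons (the FAME
subset is not public — `compare_cohorts()` accepts any external per-vessel
FFR table instead). A green cohort-statistics test therefore establishes
that the *generator-plus-filter pipeline* reproduces the headline FFR
population statistics at desk scale, not that the reduced engine is a
validated haemodynamic model.

Known quantitative limitation: with the default geometry (LM radius 0.2 cm,
50:30:20 split) the LAD FFR distribution is wider and lower-mean than the
source's (our per-vessel means ≈ 0.65–0.87 vs printed 0.72–0.76). The
absolute surrogate RMSE (0.012–0.017) brackets the printed 0.013–0.014,
but dividing by a smaller mean FFR puts the LAD normalized RMSE at
≈ 0.022 (two-lesion) to 0.025 (three-lesion) against the printed ceiling
of 0.02 — a property of the stated world, not of the training algorithm
(interpolating *all* training points does not improve it, the held-out
error is flat across the shape-parameter range, and the map is numerically
smooth to 1e-7).

# Fixed numerical choices

| Constant | Value | Why |
|---|---|---|
| steps per cycle | 1000 | output contract; RK4 stable for all in-range time constants |
| burn-in cycles | 25 (fixed) | smooth input→output map; controller converged for feasible targets |
| mean-pressure tolerance | 1% | acceptance bound; tighter 0.5% used during adaptation |
| `k_t` | 1.52 | standard turbulent loss constant |
| LM radius | 0.2 cm | assumed (schematic source geometry); configurable |
| flow split | 50:30:20 | assumed resting LAD:LCx:RCA shares; configurable |
| venous fraction floor | 0.02 | the printed venous fraction range includes 0 |
| copula PSD repair bound | 1e-6 | larger violations indicate corrupt input |
| greedy tolerance | 1e-5 | FFR scale; ~3 orders below the target accuracy |
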