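---
title: "Methods: hybrid swarm-trained networks for heavy metals in water"
author: "hnpso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid swarm-trained networks for heavy metals in water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sites impacted by acid mine drainage need frequent monitoring of dissolved
heavy metals, but elemental analysis (acid digestion + ICP/AAS) is slow,
expensive and impractical in the field. Four physicochemical parameters —
temperature, pH, electrical conductivity (EC) and total dissolved solids
(TDS) — are cheap to measure in situ and are chemically coupled to metal
mobility: metal solubility rises as pH falls, and EC/TDS track the total
dissolved ion load. `hnpso` builds and interrogates per-metal regression
models from these four probes, separately for each season (dry/wet) and
water body (surface/ground), for eight metals: Cr, Cd, Fe, Mn, Zn, Ni, Pb
and Cu.

# Model and training procedure

Each metal model is a 4-HN-1 feed-forward network with hyperbolic-tangent
hidden units and a linear output unit. All variables are min–max normalized
to $[-1, +1]$ before fitting; the map is affine and never clipped, so it is
exactly invertible and values outside the fitted range (possible when
normalization is fitted on training rows only) remain meaningful. Rows are
split 70/15/15 into training/validation/test by a seeded permutation with
the rounding rule train $=\lfloor 0.70n \rfloor$, validation
$=\lfloor 0.15n \rfloor$, test = remainder (56/12/12 at $n = 80$).

**Output unit.** The hidden layer is tansig by convention; for the output
unit a linear activation is the default because the targets are regression
values normalized to $[-1, 1]$ and a saturating output would flatten
gradients exactly at the range endpoints, where the extreme concentrations
sit. A tansig output is available by flag.

**Swarm phase.** The network's weights and biases are flattened into a
vector of length $6\,\mathrm{HN} + 1$ (input weights row-major, hidden
biases, output weights, output bias); a particle swarm minimizes the
training-set mean squared error of the decoded network. Updates follow the
canonical form with inertia $\omega$ and attraction coefficients
$C_a, C_b$ toward each particle's personal best and the global best, with
fresh uniform$(0,1)$ draws per particle and dimension each step. Defaults
are the standard constriction-equivalent values $\omega = 0.729$,
$C_a = C_b = 1.49445$; positions start uniform in $[-1,1]^D$, velocities in
$[-0.1, 0.1]^D$; velocities are clamped componentwise at 1.0 and positions
clipped to $[-10, 10]^D$, which keeps the tansig units out of deep
saturation. The global-best fitness is non-increasing by construction.
Validation MSE of the global best is tracked every iteration; training
stops after 200 iterations without validation improvement (the patience is
a package default — only the *existence* of early stopping is prescribed by
the method), and the returned model is the snapshot at minimum validation
error.

**Refinement phase.** From the swarm solution, a damped Gauss–Newton
(Levenberg–Marquardt) iteration with an analytic Jacobian polishes the
least-squares fit. Two details matter on small samples:

* The iteration must handle more parameters than residuals (up to 181
  parameters vs 56 training rows), which rules out classic MINPACK solvers;
  the package's `lm_least_squares()` solves the damped normal equations
  directly.
* Unregularized convergence interpolates the training rows and generalizes
  poorly. The refiner therefore (a) evaluates validation MSE after every
  accepted step and returns the best-by-validation snapshot — the same
  "halt at the moment of lowest error" principle as the swarm phase — and
  (b) repeats the iteration over a small weight-decay grid
  $\{0, 10^{-4}, 10^{-3}, 10^{-2}\}$ (penalty $\lambda S \lVert\theta\rVert^2$
  added to the training sum of squares), keeping whichever candidate has
  the lowest validation MSE. The refiner is guarded: it never returns a
  model with worse validation MSE than its input.

**Topology selection.** HN is swept (1–30 in full mode) and each topology
scored by $\mathrm{AIC} = N \ln(\mathrm{MSE_{val}}) + 2\,\mathrm{HN}$ with
$N$ the full dataset size and the validation MSE on the normalized scale;
the governing structure is the criterion minimum, ties to the smaller HN.
Whether the criterion rises again past its minimum (the expected U-shape)
is visible in the stored sweep rows; it is logged, not asserted, because a
finite sweep of stochastic fits need not be unimodal.

**Scoring.** Per-partition MSE and Pearson R are reported on the normalized
scale (the concentration-scale MSE is recoverable through the stored
normalization specs). The Kling–Gupta efficiency
$1 - \sqrt{(R-1)^2 + (VE-1)^2 + (BT-1)^2}$ — with VE and BT the
predicted/observed ratios of population standard deviation and mean — is
computed on the *concentration* scale over the combined validation + test
rows: on the centred normalized scale the observed mean can be arbitrarily
close to zero, which makes the bias ratio meaningless, while concentrations
are positive. The evaluation partition is configurable; combined
validation + test is the default because the training rows would reward
memorization.

**Baselines.** Ordinary, Huber-robust (tuning constant 1.345) and stepwise
(bidirectional, information-criterion-driven) linear regressions, plus
$\varepsilon$-insensitive support-vector regression with linear, quadratic,
cubic and three Gaussian kernels. The fine/medium/coarse Gaussian kernel
scales follow the preset convention $\sqrt{p}/4$, $\sqrt{p}$, $4\sqrt{p}$
with $p = 4$ predictors; box constraint 1 and
$\varepsilon = \mathrm{IQR}(y)/13.49$. The quadratic-programming solve is
delegated to `e1071`; the comparison logic (same splits, same
normalization, per-metal R ratios against the best linear and best kernel
family on the test partition) is the package's. Everything is fitted
strictly on the training partition.

**Sensitivity.** Olden's connection-weight importance: input $i$'s signed
contribution is $c_i = \sum_x W_{1}[x,i]\, w_2[x]$. The textbook formula
normalizes by the signed grand sum $\sum_j c_j$, which can be zero or
negative; the package reports $100\,|c_i| / \sum_j |c_j|$ with the sign of
$c_i$ alongside, which is well-defined and preserves the percentage
reading. Importance is computed on the governing (post-selection) model.

# The synthetic-data generator

No raw field records are available in machine-readable form, so the
generator emulates the published evidence and is itself first-class, tested
code. It is calibrated once; its defaults are the study conditions and are
not tuning knobs.

* **Marginals.** Each of the 12 variables gets a scaled Beta on its
  published $[\min, \max]$ with the mean matched to the published mean and
  fixed concentration $\alpha + \beta = 6$ — the only bounded family that
  matches all three published numbers with one smooth unimodal shape. Means,
  ranges and $n = 80$ per campaign are transcribed from the published
  descriptive tables.
* **Feature dependence.** A Gaussian copula over the four features with the
  EC–TDS rank correlation set to $\rho_s = 0.6$ (converted to the latent
  Pearson scale by $2\sin(\pi\rho_s/6)$; assembled matrices are projected
  to the nearest correlation matrix if needed). EC and TDS are strongly
  coupled in any natural water, and 0.6 is a deliberately moderate choice
  that leaves the two informative as separate inputs.
* **Response surfaces.** Each metal's latent score is a linear combination
  of tanh-transformed standardized features plus one pairwise interaction,
  mapped through the metal's Beta quantile function by ranks — a monotone
  rescaling of a smooth function of the features. Coefficients encode
  acid-mine-drainage chemistry (negative pH weights, positive EC/TDS
  weights for the mobile metals) and are *shared* between metal pairs the
  evidence reports as positively associated (Cr–Cd everywhere; Cu–Zn,
  Cd–Cu, Cd–Pb, Ni–Pb in surface water; Cr–Ni, Cr–Pb, Cd–Ni, Cd–Pb, Fe–Zn
  in groundwater), which induces the reported correlation structure while
  keeping every target an exact function of the features at zero noise. A
  direct copula across the metals could not provide that determinism, which
  downstream learnability contracts require.
* **Noise.** Gaussian noise on the latent score with standard deviation
  5% of the score's spread, applied *before* the rank/quantile map. Placing
  the noise on the latent scale keeps the marginals exactly calibrated to
  the published tables and every draw inside its published range — noise
  applied after the quantile map would be clipped at the range ends and
  bias the means of the skewed metals. 5% is small enough that the
  published performance envelopes are attainable in principle (see below).
* **Seeding.** One root seed; every stage (copula draws, noise, splits,
  per-topology swarm seeds) uses a derived substream, so any run replays
  exactly.

What the generator does *not* emulate: spatial structure, temporal
autocorrelation, detection-limit censoring, non-smooth or regime-switching
chemistry, and the interpolation-based augmentation behind the published
$n = 80$ campaigns. Passing tests on synthetic data therefore demonstrate
the pipeline's correctness and its behavior under the documented
conditions, not field performance.

# Problem sizes and the desk scale

Full mode replicates the original sweep dimensions (HN 1–30, 2000 swarm
iterations). The default "desk" mode — HN ∈ {5, 10, 15, 20, 25, 30}, 500
iterations, swarm of 10, best of 3 derived seeds per topology — is the
package's chosen problem size for routine end-to-end runs of all 32 models
(8 metals × 2 seasons × 2 water types, $n = 80$ each) on a single core;
the refinement phase, not the swarm length, dominates final fit quality,
so the desk sweep loses little.

Observed at the desk scale (root seed 1): validation R ≥ 0.987 for every
dry-season surface-water model, normalized validation MSE ≤ 0.007
everywhere, and held-out KGE between 0.92 and 0.99 across the 32 models.
On the KGE floor: scoring the *noise-free* response against the noisy draws
bounds the achievable KGE at ≥ 0.96 for every campaign, and an independent
flexible regressor (a generalized additive model fitted to the same
training rows) scores 0.75–0.92 on the hardest metals — worse than the
swarm-trained networks. The residual gap between ≈0.92 and the ideal
envelope is estimator variance at $n = 80$ with 24 held-out rows,
concentrated in the most skewed marginals (e.g. dry-season Mn), and should
be read as the cost of small samples rather than a defect of the hybrid
trainer.

# Numerical choices and degenerate inputs

* tansig is the exact `tanh`, not a rational approximation; oracles in the
  test suite rely on exactness.
* A constant column cannot be normalized (error); a perfect fit reports
  $-\infty$ for the information criterion (sentinel, not an error); KGE
  refuses observed vectors with zero mean or variance; relative importance
  refuses all-zero contributions (e.g. a zero output layer).
* Criterion ties in the topology sweep go to the smaller HN; rank ties in
  the generator's quantile map are broken by first occurrence, keeping
  generation deterministic.
* Splits require every partition to be non-empty ($n \ge 7$ under the
  default fractions).

# Known limitations

* Single-output networks only (one model per metal); multi-output or
  recurrent architectures are out of scope.
* The swarm is the canonical global-best variant; alternative
  metaheuristics (GA, ICA, BBO) are deliberately not implemented.
* KGE's partition and scale conventions are reported choices; numbers are
  only comparable across runs using the same conventions.
* Synthetic-data results bound what can be claimed about field data (see
  the generator section).
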