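---
title: "RRHO partition functions, symmetry numbers, and learned estimators for TST kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RRHO partition functions, symmetry numbers, and learned estimators for TST kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qestr)
```

## The model

`qestr` computes gas-phase molecular partition functions under the
rigid-rotor/harmonic-oscillator (RRHO) approximation, factorized as

$$Q(T) \approx Q_\mathrm{el}(T)\, Q_\mathrm{trans}(T)\, Q_\mathrm{rot}(T)\, Q_\mathrm{vib}(T),$$

and assembles unimolecular transition-state-theory (TST) rate constants

$$k^\mathrm{TST}(T) = \frac{k_B T}{h}\,\frac{Q_\mathrm{TS}(T)}{Q_\mathrm{R}(T)}\, e^{-\beta E_a},$$

with $E_a$ the transition-state-minus-reactant ground-state energy gap and
$\beta = 1/k_B T$.  All partition-function arithmetic happens on the
natural-log scale: across the (50, 2000) K range the log values span
hundreds of units (the zero-point-dominated vibrational factor reaches
$e^{-600}$ and below at 50 K for a mid-sized organic), so linear-scale
arithmetic would underflow.

The individual factors are

* **electronic**: $\ln g$, the spin multiplicity; excited electronic
  states are ignored (the intended inputs are closed-shell organics);
* **translational**: $\ln[(2\pi m k_B T/h^2)^{3/2} V]$ with the volume
  convention $V = k_B T / p^\circ$, default $p^\circ = 10^5$ Pa (1 bar).
  The convention cancels exactly in $Q_\mathrm{TS}/Q_\mathrm{R}$, so TST
  rates are unaffected; absolute log Q values — and therefore any learned
  model of them — are convention-dependent, which is why the pressure is
  carried in `thermo_state()` and recorded implicitly in every dataset a
  model is trained on;
* **rotational**: classical rigid-rotor closed forms — $0$ for a point
  mass, $\ln[T/(\sigma\theta)]$ for a linear rotor,
  $\ln[(\sqrt{\pi}/\sigma)(T^3/\theta_A\theta_B\theta_C)^{1/2}]$ for a
  nonlinear top, with $\theta = \hbar^2/(2 I k_B)$ per principal moment;
* **vibrational**: per real harmonic mode with $x = hc\nu/k_B T$,
  $-x/2 - \ln(1 - e^{-x})$.  The zero-point energy lives *inside*
  $Q_\mathrm{vib}$ (so $\log Q_\mathrm{vib} \le 0$ is normal); with this
  convention $E_a$ is a difference of ground-state electronic energies
  with no separate ZPE bookkeeping.

## Symmetry numbers

The external symmetry number $\sigma$ counts proper rotations mapping the
molecule onto itself.  `detect_invariant_operations()` enumerates
candidate operations from a finite axis set — principal inertia axes,
center-of-mass→atom directions, and sums/differences of same-element atom
pairs — at angles $2\pi j/k$, $k \le 6$, keeping every orthogonal
transform that maps the element-labeled point set onto itself within a
tolerance (default 0.05 Å after mass-weighted centering).  Improper
candidates (reflections, $S_n$, inversion) are enumerated too, so the
operation count approximates the full point-group order; $\sigma$ is the
number kept with determinant $+1$.  Near-duplicate operations arising
from slightly different candidate axes are collapsed by matrix distance
(distinct operations of order $\le 6$ differ by a Frobenius distance
$\ge \sqrt 2$; perturbation duplicates sit far below $0.5$).

Linear molecules are the classic failure mode of operation-based
detectors: the perpendicular $C_2$ of a centrosymmetric linear molecule
surfaces as an improper reflection.  `qestr` therefore decides linear
species at the geometry level: a centrosymmetric same-element pattern
along the axis (O=C=O) gives $\sigma = 2$, anything else linear gives
$\sigma = 1$.  $\sigma$ is computed at the given tolerance only — no
adaptive loosening — so noisy geometries straddling the tolerance resolve
deterministically.

```{r symmetry}
co2 <- read_xyz("3\ncarbon dioxide\nO 0 0 -1.162\nC 0 0 0\nO 0 0 1.162")
rotational_symmetry_number(co2)
```

## Tunable parameters

| parameter | default | units | where |
|---|---|---|---|
| linearity threshold $I_\mathrm{min}/I_\mathrm{max}$ | 1e-4 | — | `inertia_analysis()` |
| spurious-mode cutoff | 1.0 | cm$^{-1}$ | `classify_modes()` |
| symmetry matching tolerance | 0.05 | Å | `rotational_symmetry_number()` |
| standard pressure $p^\circ$ | 1e5 | Pa | `thermo_state()` |
| temperature range | (50, 2000) | K | `fixture_spec()`, samplers |
| temperatures per reaction | 50 | — | `build_q_dataset()` |
| hold-out fraction / folds | 0.10 / 5 | — | `scaffold_split()` |
| outlier quantile envelope | (0.0005, 0.9995) | — | `drop_outliers()` |
| bond perception cutoff factor | 1.2 | — | `perceive_bonds()` |
| feature grid | 32 centers on [0, 6] Å | — | `feature_config()` |
| kernel width | 0.2 | Å | `feature_config()` |

The spurious-mode cutoff and the matching tolerance are deliberate,
conservative choices for DFT-quality inputs; neither is derivable from
first principles and both are exposed in the API.  Atomic masses are
standard (isotope-averaged) atomic weights, appropriate for
natural-abundance organics.

## Dataset construction and splitting

Training data is one row per (structure, temperature): temperatures are
drawn uniformly in $1/T$ over (50, 2000) K — covering the
low-temperature region densely, where $\log Q$ varies fastest — with a
per-reaction seed fanned out from the master seed by stable string
hashing, so every reaction gets its own reproducible temperature set.

Splits are grouped by the Bemis–Murcko scaffold of the *reactant*:
connectivity is perceived from the 3D geometry by covalent-radius
cutoffs, terminal atoms are pruned iteratively (leaving ring systems plus
linkers), and the remainder is canonicalized by element-colored canonical
graph labeling.  Whole scaffold groups go to the 10% hold-out first
(largest groups first, ties shuffled under the seed), then to five
development folds balancing counts, so no backbone ever straddles a
boundary.  Acyclic molecules all map to the empty scaffold and travel as
a single group — deterministic, leakage-free, and flagged in the split
report, at the cost of one potentially large group.  Leakage is enforced,
not advisory: training entry points and scaler fitting reject hold-out
reaction ids with a hard error.

The outlier rule is a symmetric quantile envelope on the development-set
log Q distribution, default (0.0005, 0.9995); it is a stand-in for
whatever exact rule produced any particular external dataset and must be
recalibrated before exact comparisons to one.

## Featurization and scaling

The EncodedBond descriptor is a fixed-length, smoothed radial histogram:
one channel per unordered element pair (H, C, N, O → 10 channels), each a
grid of Gaussian kernels over interatomic distance.  It is invariant to
rotation, translation and atom order, and its length does not depend on
molecule size.  Kernel contributions below 1e-12 are truncated to exact
zero so that grid positions a training set never populates stay exactly
zero rather than numerically tiny — important because input scaling is
range-based.

Qest inputs are min–max scaled per dimension (constant dimensions map to
0); QesTS inputs are deliberately *not* scaled — the difference features
are peaked around zero, and identity scaling screened best for that
model.  Targets are z-score normalized, exactly invertible.  Min–max
scaling is brittle under scaffold shift: a dimension whose development
range is tiny can scale an unseen molecule's value into the thousands.
Two guards handle this: dimensions whose fitted range is below a
noise threshold are treated as constant, and scaled values are clipped to
the unit interval.  Clipping trades a small amount of extrapolated signal
for bounded inputs; the recovery experiments below quantify what remains.

## Estimators

* **Qest** learns $\log Q$ from [scaled features ‖ $1/T$].
* **QesTS** learns $\log Q_\mathrm{TS}$ from [product−reactant difference
  features ‖ $\log Q_R$ ‖ $\log Q_P$ ‖ $1/T$].
* **Double** composes them: Qest supplies $\log Q_R$ and $\log Q_P$ to
  QesTS, so no transition-state information of any kind enters — the
  composition needs only reactant and product geometries plus $E_a$.
* **Null**: $\log Q = m(1/T) + b$ by OLS on the development set; applied
  to both species in a rate it reproduces the classical
  "$Q_\mathrm{TS}/Q_\mathrm{R} = 1$" assumption and is the baseline every
  structural model must beat.

The regressor is an ensemble (default 5 members) of single-hidden-layer
feed-forward networks with skip-layer (direct input→output) connections,
logistic hidden units, linear output, L2 weight decay and BFGS
optimization (`nnet` backend); member initializations are fanned out
deterministically from the spec seed and predictions are averaged, so
inference is reproducible.  The skip connections matter: they let the
model represent affine structure exactly, giving the learned nonlinearity
a sensible linear backbone.  The ensemble matters too: a single BFGS
solution carries an initialization-dependent bias on molecules outside
the training scaffolds, and averaging independently initialized members
cancels much of it.  A narrow hidden layer (8 units) optimizes more
reliably under full-batch BFGS than a wide one at these data scales, and
a deeper stack adds nothing; all hyperparameters (`estimator_spec()`) are
recorded in the saved bundle.  Training reports
a validation MAE from one held-out development fold (configurable);
full k-fold retraining was judged not worth k× the cost for the quantity
it reports.  The loss is MSE on normalized targets; evaluation is MAE on
log Q and MAE as a percentage of the evaluated targets' standard
deviation, with optional equal-width $1/T$-bin breakdowns.

## What the synthetic fixtures do and do not show

The fixture generator builds ring/chain C-H-N-O molecules (≤ 7 heavy
atoms), perturbed-copy products, interpolated "transition states" whose
mode list copies the reactant's minus one real mode plus one sampled
imaginary mode, sampled activation energies, and per-reaction temperature
sets.  This exercises every code path — validation, symmetry detection,
statmech, splitting, featurization, training — with known ground truth.

Two things it deliberately does not provide.  First, chemistry: fixture
frequencies are sampled, not derived from the geometry, so fixture
$\log Q$ has a structural component that is *random* with respect to the
features.  A geometry-based estimator cannot learn it, which is exactly
why the estimator tests use planted targets (a fixed linear map of the
features plus a $c/T$ term, structural part scaled to twice the
temperature part's spread, mirroring the structure-dominated variance of
real partition-function data).  Passing those tests demonstrates that the
pipeline — featurization, scaling, leakage guards, training, inversion —
recovers learnable structure; it does not certify accuracy on real DFT
datasets.  Second, scale: the suite runs hundreds of reactions, not tens
of thousands; scaffold diversity is far lower than in real data, which
makes scaffold-shifted generalization *harder* per molecule, and the
recovery thresholds account for that.

## Numerical choices and degenerate inputs

* Log-scale everything; `log1p(-exp(-x))` for the vibrational factor.
* Inertia eigenvalues are clamped at zero; linearity is a ratio test.
* A monatomic or linear species has a continuous rotation group, so the
  discrete operation count is reported as `NA` for them; $\sigma$ is
  still defined (1, or 2 for centrosymmetric linear).
* The state-sum oracle sums vibrational levels per mode and rotational
  levels for linear species, with convergence judged by the first
  *omitted* term (so a single-term sum in the deep quantum regime is
  valid).  The quantum rotational level sum of a linear rotor genuinely
  exceeds the classical closed form by the Mulholland factor
  $1 + \theta/3T + \theta^2/15T^2 + 4\theta^3/315T^3$ — about 0.9%
  for CO at 100 K.  Oracle-vs-closed-form comparisons therefore multiply
  the classical value by this factor
  (`linear_rotor_quantum_correction()`); the residual is then
  $O((\theta/T)^4)$ and the 0.1% agreement checks verify implementation,
  not the (false) identity of classical and quantum rotors.
* Ties in scaffold-group ordering are broken by a seeded shuffle; split
  assembly is otherwise deterministic (hold-out first, then folds).
* Seed fan-out uses a 31-bit string hash, keeping derived seeds valid R
  integers on every platform.

## Problem sizes used by the shipped experiments

The recovery experiments run at 200 reactions × 10 temperatures
(acceptance) and 60 × 4 (unit tests) with 16- and 8-center feature
grids; the statmech oracle comparisons use 20 random di/triatomics at
three temperatures; the sampling checks use $10^5$ draws.  These sizes
were chosen as the smallest at which the checked properties are
statistically unambiguous.

## Known limitations

* RRHO only: no hindered rotors, no anharmonicity, no conformer
  averaging — one local minimum per species.
* Multi-fragment products are treated as single structures if supplied
  that way; the translational/rotational factors are then those of the
  combined rigid body.
* $\sigma$ detection probes rotation orders up to 6 (capped by the
  largest same-element atom count); exotic higher-order axes would need
  `kmax` raised.
* Min–max clipping bounds but does not eliminate scaffold-shift
  degradation; learned models remain valid only inside the temperature
  and composition domain they were trained on.
* The null model, scaffold grouping of acyclic species, and the outlier
  envelope are pragmatic conventions, stated here so they can be
  recalibrated against any external dataset before exact comparison.
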