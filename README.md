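# qestr

Gas-phase thermochemistry and machine-learned partition-function
estimation for transition-state-theory (TST) kinetics, in R.

## The problem

Computing a reaction rate constant *ab initio* is dominated by one step:
finding the transition-state (TS) geometry on the potential energy
surface.  Once structures are known, TST gives the unimolecular rate as

    k(T) = (kB T / h) * (Q_TS / Q_R) * exp(-Ea / kB T)

where `Q_TS` and `Q_R` are the transition-state and reactant partition
functions (zero-point energy included) and `Ea` is the TS − reactant
ground-state energy gap.  `qestr` implements the full pipeline around
this expression for small organic molecules (C/H/N/O):

* **RRHO partition functions** from an XYZ geometry plus harmonic
  frequencies, factorized as `Q = Q_el * Q_trans * Q_rot * Q_vib` and
  evaluated on the natural-log scale;
* **rotational symmetry numbers** detected from the geometry by
  enumerating invariant symmetry operations and counting the proper
  (determinant +1) ones, with the geometry-level rule for linear
  molecules whose perpendicular C2 otherwise surfaces as an improper
  reflection;
* **dataset construction**: per-reaction temperature sets sampled
  uniformly in 1/T over (50, 2000) K, log-Q tables, quantile-envelope
  outlier filtering;
* **leakage-free splits** grouped by the Bemis–Murcko scaffold of the
  reactant (10% hold-out, 5 development folds; no scaffold ever crosses
  a boundary, enforced with hard errors at training time);
* **EncodedBond featurization**: fixed-length, rotation/translation/
  permutation-invariant Gaussian-smoothed distance histograms per
  element pair;
* **learned estimators**: `Qest` (geometry + 1/T → log Q), `QesTS`
  (product−reactant difference features + log Q_R + log Q_P + 1/T →
  log Q_TS), their composition `Double` (needs no TS information at
  all), and the `null` baseline `log Q = m/T + b`;
* **TST assembly** of `log k(T)` from computed or predicted partition
  functions with explicit activation-energy units (hartree, J,
  kJ/mol — never guessed).

A synthetic fixture generator (`make_reaction_set()`) builds validating
desk-scale reaction sets with known ground truth, so the whole pipeline
is testable offline; a brute-force state-sum oracle cross-checks the
closed-form partition functions.

## Worked example

```r
library(qestr)

h2o <- read_xyz("3\nwater\nO 0 0 0.1173\nH 0 0.7572 -0.4692\nH 0 -0.7572 -0.4692")
h2o <- attach_frequencies(h2o, c(1595, 3657, 3756))

rotational_symmetry_number(h2o)
#> <qest_symmetry> sigma = 2 (not_linear; 4 operations found)

total_log_q(h2o, thermo_state(298.15))
#> <qest_pf structure-738322182 @ 298.1 K> log Q = -3.047 (el 0.000, trans 14.929, rot 3.759, vib -21.734)
```

Water's C2v frame yields sigma = 2 from 4 detected operations (E, C2,
two mirror planes).  At 298 K the translational factor contributes
`ln Q = 14.9` (1 bar volume convention), rotation `3.8`, and the
vibrational factor `-21.7` — negative because the zero-point energy is
carried inside `Q_vib`.  The total is the exact sum of the components.

Rates over a grid, for a synthetic fixture reaction (Ea = 0.0701
hartree):

```r
rxn <- make_reaction_set(fixture_spec(n_reactions = 1, seed = 7, n_temps = 3))[[1]]
tst_rate_table(rxn, c(300, 600, 1200))
#>  T_K     log_k log_prefactor
#>  300 -42.03955      31.71189
#>  600  -5.69602      31.17970
#> 1200  12.59129      31.02915
```

`log_k = log_prefactor − Ea/(kB T)` exactly; the prefactor
`ln[(kB T/h) Q_TS/Q_R]` varies slowly while the Arrhenius term moves
~55 log units over this range.

Training and prediction follow the same grammar (see the vignette for
the full modeling account):

```r
rxns  <- make_reaction_set(fixture_spec(n_reactions = 200, seed = 1, n_temps = 10))
plan  <- scaffold_split(rxns, test_frac = 0.1, n_folds = 5, seed = 1)
rows  <- build_q_dataset(rxns, seed = 1)
dev   <- rows[rows$reaction_id %in% names(plan$folds), ]
structures <- unlist(lapply(rxns, function(r) list(r$reactant, r$ts, r$product)),
                     recursive = FALSE)
bundle <- train_qest(dev, structures, plan, feature_config(), estimator_spec(seed = 1))
predict_qest(bundle, rxns[[1]]$reactant, c(300, 1000))
```

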