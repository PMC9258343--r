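# Closed-form partition-function factors against independent arithmetic
# oracles; constants inlined here deliberately, not taken from the package.
H_PL <- 6.62607015e-34
KB <- 1.380649e-23
C_CM <- 2.99792458e10
AMU <- 1.66053906660e-27

test_that("electronic factor is the log multiplicity", {
  expect_equal(log_q_electronic(1), 0)
  expect_equal(log_q_electronic(2), log(2))
  expect_equal(log_q_electronic(3), log(3))
  expect_error(log_q_electronic(0), "multiplicity")
})

test_that("translational factor obeys its scaling laws and the argon oracle", {
  st <- thermo_state(298.15, standard_pressure = 1e5)
  m <- 39.948 * AMU
  expect_equal(log_q_translational(2 * m, st) - log_q_translational(m, st),
               1.5 * log(2), tolerance = 1e-12)
  st2 <- thermo_state(2 * 298.15, standard_pressure = 1e5)
  expect_equal(log_q_translational(m, st2) - log_q_translational(m, st),
               2.5 * log(2), tolerance = 1e-12)
  # independent closed-form evaluation for argon at 298.15 K, 1 bar
  oracle <- log((2 * pi * m * KB * 298.15 / H_PL^2)^1.5 * KB * 298.15 / 1e5)
  expect_equal(log_q_translational(m, st), oracle, tolerance = 1e-12)
  expect_equal(exp(oracle), 1.00e7, tolerance = 0.01)
  expect_error(log_q_translational(-1, st), "positive")
})

test_that("rotational factor covers monatomic, linear and nonlinear branches", {
  st <- thermo_state(300)
  mono <- inertia_analysis(structure_record("He", matrix(0, 1, 3)))
  expect_equal(log_q_rotational(mono, 1, st), 0)

  # homonuclear diatomic oracle: two 1-amu masses on a 1.0 A bond
  hh <- structure_record(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.0)))
  ih <- inertia_analysis(hh)
  I_oracle <- 2 * 1.008 * AMU * (0.5e-10)^2
  theta <- (H_PL / (2 * pi))^2 / (2 * I_oracle * KB)
  expect_equal(log_q_rotational(ih, 2, st), log(300 / (2 * theta)),
               tolerance = 1e-10)
  # sigma divides Q: sigma 1 vs 2 differ by exactly ln 2
  expect_equal(log_q_rotational(ih, 1, st) - log_q_rotational(ih, 2, st),
               log(2), tolerance = 1e-12)

  iw <- inertia_analysis(mol_h2o())
  expect_gt(log_q_rotational(iw, 2, st), 0)
})

test_that("vibrational factor matches closed-form arithmetic and limits", {
  novib <- classify_modes(attach_frequencies(
    structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.1))), numeric(0)))
  st <- thermo_state(300)
  expect_equal(log_q_vibrational(novib, st), 0)

  # pick T so that x = h c nu / (kB T) = ln 2: Q = 2^(-1/2)/(1 - 1/2) = sqrt(2)
  nu <- 100
  T_ln2 <- H_PL * C_CM * nu / (KB * log(2))
  one <- classify_modes(attach_frequencies(
    structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.1))), nu))
  expect_equal(log_q_vibrational(one, thermo_state(T_ln2)), log(sqrt(2)),
               tolerance = 1e-10)
  expect_equal(log(sqrt(2)), 0.3466, tolerance = 1e-4)

  # low-T limit: pure ZPE term -x/2
  Tlow <- 5
  x <- H_PL * C_CM * 2000 / (KB * Tlow)
  deep <- classify_modes(attach_frequencies(
    structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.1))), 2000))
  expect_equal(log_q_vibrational(deep, thermo_state(Tlow)), -x / 2,
               tolerance = 1e-8)

  # high-T (classical) limit: log Q + x/2 -> -log x as x -> 0
  Thigh <- 2e6
  xs <- H_PL * C_CM * 100 / (KB * Thigh)
  lo <- classify_modes(attach_frequencies(
    structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.1))), 100))
  expect_equal(log_q_vibrational(lo, thermo_state(Thigh)) + xs / 2, -log(xs),
               tolerance = 1e-3)
})

test_that("total log Q is the exact component sum; monatomic reduces to translation", {
  st <- thermo_state(300)
  he <- attach_frequencies(structure_record("He", matrix(0, 1, 3)), numeric(0))
  pf <- total_log_q(he, st)
  expect_identical(pf$log_q_total, pf$log_q_trans)
  expect_equal(pf$log_q_el, 0)
  expect_equal(pf$log_q_rot, 0)
  expect_equal(pf$log_q_vib, 0)

  pf2 <- total_log_q(mol_h2o(), st)
  expect_identical(pf2$log_q_total,
                   pf2$log_q_el + pf2$log_q_trans + pf2$log_q_rot + pf2$log_q_vib)
})

test_that("every factor and the total increase strictly with temperature", {
  set.seed(13)
  s <- make_molecule("asymmetric", seed = 17)
  temps <- sort(sample_temperatures(12, seed = 5))
  vals <- t(vapply(temps, function(T_K) {
    pf <- total_log_q(s, thermo_state(T_K))
    c(pf$log_q_trans, pf$log_q_rot, pf$log_q_vib, pf$log_q_total)
  }, numeric(4)))
  for (k in 1:4) expect_true(all(diff(vals[, k]) > 0))
})

test_that("standard pressure shifts log Q_trans by the exact log ratio and cancels in ratios", {
  s <- mol_h2o()
  a <- total_log_q(s, thermo_state(300, standard_pressure = 1e5))
  b <- total_log_q(s, thermo_state(300, standard_pressure = 101325))
  expect_equal(a$log_q_trans - b$log_q_trans, log(101325 / 1e5),
               tolerance = 1e-12)
  s2 <- mol_nh3()
  a2 <- total_log_q(s2, thermo_state(300, standard_pressure = 1e5))
  b2 <- total_log_q(s2, thermo_state(300, standard_pressure = 101325))
  expect_equal(a$log_q_total - a2$log_q_total, b$log_q_total - b2$log_q_total,
               tolerance = 1e-10)
})

test_that("state-sum oracle reproduces the closed forms for a toy diatomic", {
  s <- mol_co()
  for (T_K in c(300, 1000)) {
    closed <- total_log_q(s, thermo_state(T_K))$log_q_total
    oracle <- state_sum_oracle(s, T_K)
    theta <- rotational_temperatures(s)
    corr <- log(linear_rotor_quantum_correction(theta, T_K))
    # closed form times the known quantum rotational correction = level sum
    expect_equal(abs(exp(closed + corr - oracle) - 1), 0, tolerance = 1e-3)
  }
})

test_that("thermo state validates its domain flag", {
  expect_error(thermo_state(-5), "positive")
  expect_error(thermo_state(30, in_domain = TRUE), "in-domain")
  st <- thermo_state(300)
  expect_equal(st$beta * KB * 300, 1, tolerance = 1e-12)
})
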