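test_that("XYZ parsing handles minimal, constructed and malformed inputs", {
  s1 <- read_xyz("1\n\nH 0 0 0")
  expect_equal(s1$atoms, "H")
  expect_equal(s1$coords, matrix(0, 1, 3))

  s2 <- read_xyz("2\ndioxygen\nO 0 0 0\nO 0 0 1.21")
  expect_equal(length(s2$atoms), 2L)
  expect_equal(sqrt(sum((s2$coords[1, ] - s2$coords[2, ])^2)), 1.21)
  expect_equal(s2$comment, "dioxygen")

  expect_error(read_xyz("2\n\nXx 0 0 0\nH 0 0 1"), "Xx")
  expect_error(read_xyz("zzz\n\nH 0 0 0"), "atom count")
  expect_error(read_xyz("1\n\nH 0 zero 0"), "non-numeric")
  expect_error(read_xyz("3\n\nH 0 0 0"), "coordinate lines")
})

test_that("XYZ round trip preserves atoms and coordinates to printed precision", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(2:8, 1)
    s <- structure_record(sample(c("C", "H", "N", "O"), n, replace = TRUE),
                          matrix(rnorm(3 * n, sd = 2), n, 3))
    s2 <- read_xyz(write_xyz(s, digits = 8))
    expect_identical(s2$atoms, s$atoms)
    expect_equal(s2$coords, s$coords, tolerance = 1e-7)
  }
})

test_that("structure invariants are enforced", {
  expect_error(structure_record("H", matrix(0, 2, 3)), "one row per atom")
  expect_error(structure_record("H", matrix(0, 1, 3), multiplicity = 0),
               "multiplicity")
  # too many real modes for the atom count
  expect_error(
    attach_frequencies(structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.1))),
                       c(500, 900, 1200)),
    "3N-5")
})

test_that("inertia analysis classifies monatomic, linear and bent species", {
  he <- structure_record("He", matrix(0, 1, 3))
  ih <- inertia_analysis(he)
  expect_true(ih$is_monatomic)
  expect_equal(ih$principal_moments, c(0, 0, 0))

  ic <- inertia_analysis(mol_co2())
  expect_true(ic$is_linear)
  expect_equal(ic$principal_moments[2], ic$principal_moments[3])
  # direct oracle: I = 2 * m_O * d^2 about the perpendicular axes
  m_o <- atomic_mass("O", "kg")
  expect_equal(ic$principal_moments[3], 2 * m_o * (1.162e-10)^2,
               tolerance = 1e-10)

  iw <- inertia_analysis(mol_h2o())
  expect_false(iw$is_linear)
  expect_true(all(iw$principal_moments > 0))
  expect_true(all(diff(iw$principal_moments) > 1e-49))
})

test_that("principal moments are invariant under rigid rotation and translation", {
  set.seed(7)
  s <- make_molecule("asymmetric", seed = 3)
  base <- inertia_analysis(s)$principal_moments
  for (i in 1:5) {
    R <- random_rotation()
    s2 <- s
    s2$coords <- s$coords %*% t(R) + matrix(rnorm(3), nrow(s$coords), 3,
                                            byrow = TRUE)
    rot <- inertia_analysis(s2)$principal_moments
    expect_equal(rot, base, tolerance = 1e-8)
  }
})

test_that("mode classification drops imaginary/spurious modes and computes ZPE", {
  tri <- structure_record(c("C", "C", "O"),
                          rbind(c(0, 0, 0), c(0, 0, 1.4), c(1.2, 0, 2.0)))
  r <- attach_frequencies(tri, c(1000, 2000))
  vp <- classify_modes(r)
  expect_equal(vp$real_modes, c(1000, 2000))
  # zpe = h c (1500 cm^-1): half the mode sum
  h <- 6.62607015e-34; c_cm <- 2.99792458e10
  expect_equal(vp$zpe, h * c_cm * 1500, tolerance = 1e-12)

  ts <- structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.2)),
                         frequencies = c(-450, 800), role = "transition_state")
  vts <- classify_modes(ts)
  expect_equal(vts$real_modes, 800)
  expect_equal(vts$dropped_modes, -450)

  expect_error(
    classify_modes(structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.1)),
                                    frequencies = c(-300, 900))),
    "imaginary")
  expect_error(
    classify_modes(structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.1)),
                                    frequencies = 500, role = "transition_state")),
    "exactly one imaginary")
})

test_that("ZPE is additive over concatenated mode lists", {
  base <- structure_record(c("C", "C", "O"), matrix(rnorm(9), 3, 3) * 2)
  a <- classify_modes(attach_frequencies(base, c(500, 700)))
  b <- classify_modes(attach_frequencies(base, c(1100, 1900)))
  ab <- classify_modes(attach_frequencies(base, c(500, 700, 1100, 1900)))
  expect_identical(ab$zpe, a$zpe + b$zpe)
})

test_that("frequency sidecar and JSON reaction records round trip", {
  f <- tempfile()
  writeLines(c("# header", "1234.5", "-450.2", ""), f)
  expect_equal(read_frequency_file(f), c(1234.5, -450.2))

  rxns <- make_reaction_set(fixture_spec(n_reactions = 2, seed = 5, n_temps = 3))
  jf <- tempfile(fileext = ".json")
  write_reactions_json(rxns, jf)
  back <- read_reactions_json(jf)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$ea, rxns[[1]]$ea)
  expect_equal(back[[1]]$temperatures, rxns[[1]]$temperatures)
  expect_equal(back[[2]]$ts$frequencies, rxns[[2]]$ts$frequencies)
  expect_equal(back[[1]]$reactant$coords, rxns[[1]]$reactant$coords)
})
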