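# Desk-scale synthetic molecules and reactions with known ground truth.
# The fixtures exercise code paths (validation, symmetry, statmech,
# splitting, featurization, training); no chemical realism of transition
# states is attempted.

#' Fixture generator parameters
#'
#' @param n_reactions number of reactions to generate.
#' @param atom_budget maximum heavy (C/N/O) atoms per molecule (default 7,
#'   the dataset's composition bound).
#' @param seed master seed; per-molecule/per-reaction seeds are fanned out
#'   by stable hashing.
#' @param frequency_range bounds for sampled real wavenumbers, cm^-1.
#' @param ea_range bounds for sampled activation energies, hartree.
#' @param t_min,t_max temperature range, K.
#' @param n_temps temperatures sampled per reaction.
#' @return an object of class `qest_fixture_spec`.
#' @export
fixture_spec <- function(n_reactions = 10, atom_budget = 7, seed = 1,
                         frequency_range = c(200, 3500),
                         ea_range = c(0.005, 0.1),
                         t_min = 50, t_max = 2000, n_temps = 50) {
  stopifnot(atom_budget >= 2, frequency_range[1] > 0,
            frequency_range[1] < frequency_range[2])
  sp <- list(n_reactions = as.integer(n_reactions),
             atom_budget = as.integer(atom_budget), seed = as.integer(seed),
             frequency_range = frequency_range, ea_range = ea_range,
             t_min = t_min, t_max = t_max, n_temps = as.integer(n_temps))
  class(sp) <- "qest_fixture_spec"
  sp
}

.sample_freqs <- function(n, range) {
  if (n <= 0) return(numeric(0))
  sort(stats::runif(n, range[1], range[2]))
}

#' Generate a synthetic molecule of a requested symmetry class
#'
#' `"monatomic"`: a single heavy atom.  `"linear"`: a chain on the z axis
#' (heteronuclear by default; `centrosymmetric = TRUE` plants a mirror-
#' symmetric pattern such as O=C=O whose symmetry-number oracle is 2).
#' `"symmetric_top"`: an apex atom over three identical legs on a planted
#' C3 axis (sigma oracle 3).  `"asymmetric"`: a jittered heavy-atom chain
#' with hydrogens, generic enough that sigma = 1.  All kinds carry
#' 3N-6 (3N-5 if linear, 0 if monatomic) sampled positive frequencies and
#' a sampled electronic energy, and validate as reactants.
#'
#' @param kind one of `"asymmetric"`, `"symmetric_top"`, `"linear"`,
#'   `"monatomic"`.
#' @param seed integer seed for this molecule.
#' @param spec a `qest_fixture_spec`.
#' @param centrosymmetric for `kind = "linear"`: plant the sigma = 2
#'   pattern.
#' @param id optional structure id.
#' @return a `qest_structure` with role `"reactant"`.
#' @export
make_molecule <- function(kind = c("asymmetric", "symmetric_top", "linear",
                                   "monatomic"),
                          seed = 1, spec = fixture_spec(),
                          centrosymmetric = FALSE, id = NULL) {
  kind <- match.arg(kind)
  .with_seed(seed, {
    if (kind == "monatomic") {
      el <- sample(c("C", "N", "O"), 1)
      s <- structure_record(el, matrix(0, 1, 3), frequencies = numeric(0),
                            electronic_energy = stats::runif(1, -120, -30),
                            role = "reactant",
                            id = id %||% paste0("mono-", seed))
    } else if (kind == "linear") {
      if (centrosymmetric) {
        ends <- sample(c("O", "N"), 1)
        atoms <- c(ends, "C", ends)
        d <- stats::runif(1, 1.1, 1.3)
        z <- c(-d, 0, d)
      } else {
        atoms <- c("C", "O")
        z <- c(0, stats::runif(1, 1.1, 1.3))
      }
      coords <- cbind(0, 0, z)
      n <- length(atoms)
      s <- structure_record(atoms, coords,
                            frequencies = .sample_freqs(3 * n - 5, spec$frequency_range),
                            electronic_energy = stats::runif(1, -200, -80),
                            role = "reactant",
                            id = id %||% paste0("lin-", seed))
    } else if (kind == "symmetric_top") {
      apex <- sample(c("N", "C"), 1)
      r <- stats::runif(1, 0.9, 1.0)
      h <- stats::runif(1, 0.3, 0.45)
      ang <- 2 * pi * (0:2) / 3
      coords <- rbind(c(0, 0, h),
                      cbind(r * cos(ang), r * sin(ang), 0))
      atoms <- c(apex, rep("H", 3))
      s <- structure_record(atoms, coords,
                            frequencies = .sample_freqs(3 * 4 - 6, spec$frequency_range),
                            electronic_energy = stats::runif(1, -80, -40),
                            role = "reactant",
                            id = id %||% paste0("top-", seed))
    } else {
      n_heavy <- sample(3:spec$atom_budget, 1)
      heavy <- sample(c("C", "N", "O"), n_heavy, replace = TRUE)
      coords <- matrix(0, n_heavy, 3)
      for (i in 2:n_heavy) {
        repeat {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          cand <- coords[i - 1, ] + stats::runif(1, 1.35, 1.55) * dir
          if (i == 2 || min(sqrt(rowSums(sweep(coords[1:(i - 1), , drop = FALSE],
                                               2, cand)^2))) > 1.2) {
            coords[i, ] <- cand
            break
          }
        }
      }
      # hydrogens on the chain ends, plus jitter to break any symmetry
      hpos <- rbind(coords[1, ] + c(0, 0, 1.09), coords[n_heavy, ] + c(0, 1.09, 0))
      atoms <- c(heavy, "H", "H")
      coords <- rbind(coords, hpos) + matrix(stats::rnorm(3 * (n_heavy + 2), 0, 0.08),
                                             ncol = 3)
      n <- length(atoms)
      s <- structure_record(atoms, coords,
                            frequencies = .sample_freqs(3 * n - 6, spec$frequency_range),
                            electronic_energy = stats::runif(1, -300, -80),
                            role = "reactant",
                            id = id %||% paste0("asym-", seed))
    }
    s
  })
}

# Ring-or-chain reactant.  The ring core (size x heteroatom pattern) cycles
# deterministically with the reaction index, so even a handful of reactions
# spans many scaffold groups; decorations (side heavy atoms, out-of-plane
# tilts, jitter) are sampled per reaction, so molecules *within* a scaffold
# group differ -- real scaffold groups hold many decorated variants, and
# split-based generalization is only meaningful when groups are
# heterogeneous and share their decoration chemistry.
.fixture_reactant <- function(i, seed, spec) {
  .with_seed(seed, {
    acyclic <- (i %% 11 == 0)
    if (acyclic) {
      n_heavy <- sample(3:min(7, spec$atom_budget), 1)
      heavy <- sample(c("C", "C", "C", "N", "O"), n_heavy, replace = TRUE)
      coords <- matrix(0, n_heavy, 3)
      dir <- c(1, 0, 0)
      for (j in 2:n_heavy) {
        # zig-zag backbone with a random dihedral wiggle
        wig <- stats::rnorm(3, 0, 0.35)
        dir <- dir + wig
        dir <- dir / sqrt(sum(dir^2))
        coords[j, ] <- coords[j - 1, ] + stats::runif(1, 1.45, 1.55) * dir
      }
      atoms <- c(heavy, "H", "H")
      coords <- rbind(coords,
                      coords[1, ] + c(0, 0, 1.09),
                      coords[n_heavy, ] + c(0, 0, 1.09))
    } else {
      k <- 3 + (i %% 4)                       # ring size 3..6, cycles with i
      pattern <- (i %/% 4) %% 4               # heteroatom pattern, cycles
      ring <- rep("C", k)
      if (pattern == 1) ring[1] <- "O"
      if (pattern == 2) ring[1] <- "N"
      if (pattern == 3) { ring[1] <- "O"; ring[min(3, k)] <- "N" }
      R <- 1.5 / (2 * sin(pi / k))
      ang <- 2 * pi * (seq_len(k) - 1) / k
      ring_xy <- cbind(R * cos(ang), R * sin(ang), 0)
      # random side heavy atoms within the atom budget; they prune away in
      # the Murcko scaffold, so they diversify molecules within a group
      n_side <- sample(0:min(2, spec$atom_budget - k), 1)
      side_at <- character(0)
      side_xy <- NULL
      if (n_side > 0) {
        pos <- sample(seq_len(k), n_side)
        side_at <- sample(c("C", "N", "O"), n_side, replace = TRUE)
        side_xy <- cbind((R + 1.5) * cos(ang[pos]), (R + 1.5) * sin(ang[pos]),
                         stats::runif(n_side, -0.4, 0.4))
      }
      h_on <- setdiff(which(ring == "C"),
                      if (n_side > 0) pos else integer(0))
      h_xy <- if (length(h_on) > 0) {
        cbind((R + 1.09) * cos(ang[h_on]), (R + 1.09) * sin(ang[h_on]), 0)
      } else NULL
      atoms <- c(ring, side_at, rep("H", length(h_on)))
      coords <- rbind(ring_xy, side_xy, h_xy)
    }
    coords <- coords + matrix(stats::rnorm(length(coords), 0, 0.02),
                              ncol = 3)
    n <- length(atoms)
    structure_record(atoms, coords,
                     frequencies = .sample_freqs(3 * n - 6, spec$frequency_range),
                     electronic_energy = stats::runif(1, -300, -80),
                     role = "reactant", id = paste0("rxn", i, "-R"))
  })
}

#' Generate a synthetic reaction set
#'
#' Each reaction pairs a ring-or-chain reactant (ring size and heteroatom
#' pattern vary across the set so scaffold splitting has many groups) with
#' a product that shares its atom composition (a perturbed copy), and a
#' transition state interpolated between them.  The transition state's
#' frequency list copies the reactant's modes, deletes one, and appends a
#' sampled imaginary mode, so mode-count bookkeeping holds without a real
#' hessian.  Activation energies and per-reaction temperature sets are
#' sampled from the spec ranges; ground-truth log Q is computable for all
#' three structures.
#'
#' @param spec a `qest_fixture_spec`.
#' @return list of `qest_reaction`.
#' @export
make_reaction_set <- function(spec = fixture_spec()) {
  lapply(seq_len(spec$n_reactions), function(i) {
    sd_i <- .fanout_seed(spec$seed, paste0("rxn-", i))
    reactant <- .fixture_reactant(i, sd_i, spec)
    .with_seed(.fanout_seed(sd_i, "variant"), {
      pcoords <- reactant$coords + matrix(stats::rnorm(length(reactant$coords), 0, 0.03),
                                          ncol = 3)
      product <- structure_record(reactant$atoms, pcoords,
                                  frequencies = .sample_freqs(length(reactant$frequencies),
                                                              spec$frequency_range),
                                  electronic_energy = reactant$electronic_energy +
                                    stats::runif(1, -0.05, 0.05),
                                  role = "product", id = paste0("rxn", i, "-P"))
      ts_freqs <- reactant$frequencies[-sample(length(reactant$frequencies), 1)]
      ts_freqs <- c(-stats::runif(1, 200, 2000), ts_freqs)
      ea <- stats::runif(1, spec$ea_range[1], spec$ea_range[2])
      ts <- structure_record(reactant$atoms, (reactant$coords + pcoords) / 2,
                             frequencies = ts_freqs,
                             electronic_energy = reactant$electronic_energy + ea,
                             role = "transition_state", id = paste0("rxn", i, "-TS"))
      temps <- sample_temperatures(spec$n_temps, spec$t_min, spec$t_max,
                                   seed = .fanout_seed(sd_i, "T"))
      reaction_record(paste0("rxn", i), reactant, ts, product, ea, temps)
    })
  })
}

#' Direct state-sum partition function oracle
#'
#' Independent verification route for the closed forms: the vibrational
#' factor is the explicit Boltzmann sum over harmonic levels
#' sum_n exp(-beta h c nu (n + 1/2)) per mode (product over modes); the
#' rotational factor of a linear species is the explicit level sum
#' sum_J (2J+1) exp(-theta J(J+1)/T) / sigma.  Nonlinear tops have no
#' tractable level sum and reuse the classical closed form, so for them
#' the oracle checks the electronic/translational/vibrational factors.
#' Truncation is checked: if the last retained term exceeds 1e-12 of the
#' running sum, an error demands higher `v_max`/`j_max`.
#'
#' Note the physics: for a linear rotor the quantum level sum exceeds the
#' classical closed form by the factor returned by
#' [linear_rotor_quantum_correction()] (about theta/3T relatively), so
#' oracle comparisons of the rotational factor must account for it.
#'
#' @param s a `qest_structure` with frequencies attached.
#' @param temperature K.
#' @param v_max highest vibrational level per mode.
#' @param j_max highest rotational level.
#' @param standard_pressure Pa.
#' @param spurious_tol forwarded to [classify_modes()].
#' @return total log Q from the summed factors.
#' @export
state_sum_oracle <- function(s, temperature, v_max = 400, j_max = 1000,
                             standard_pressure = 1e5, spurious_tol = 1.0) {
  st <- thermo_state(temperature, standard_pressure)
  vp <- classify_modes(s, spurious_tol = spurious_tol)
  log_qvib <- 0
  for (nu in vp$real_modes) {
    x <- .pc$c2 * nu / temperature            # beta h c nu
    terms <- exp(-x * (0:v_max + 0.5))
    # convergence judged by the first omitted level
    if (exp(-x * (v_max + 1.5)) > 1e-12 * sum(terms)) {
      stop("vibrational sum not converged at v_max = ", v_max,
           " for mode ", nu, " cm^-1; raise v_max")
    }
    log_qvib <- log_qvib + log(sum(terms))
  }
  inertia <- inertia_analysis(s)
  log_qrot <- if (inertia$is_monatomic) {
    0
  } else if (inertia$is_linear) {
    sym <- rotational_symmetry_number(s)
    theta <- .theta_rot(inertia$principal_moments[3])
    J <- 0:j_max
    terms <- (2 * J + 1) * exp(-theta * J * (J + 1) / temperature)
    next_term <- (2 * (j_max + 1) + 1) *
      exp(-theta * (j_max + 1) * (j_max + 2) / temperature)
    if (next_term > 1e-12 * sum(terms)) {
      stop("rotational sum not converged at j_max = ", j_max, "; raise j_max")
    }
    log(sum(terms) / sym$sigma)
  } else {
    sym <- rotational_symmetry_number(s)
    log_q_rotational(inertia, sym$sigma, st)
  }
  log_q_electronic(s$multiplicity) +
    log_q_translational(sum(atomic_mass(s$atoms, "kg")), st) +
    log_qrot + log_qvib
}
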