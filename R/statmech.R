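# Rigid-rotor / harmonic-oscillator partition function, factorized as
# Q = Q_el * Q_trans * Q_rot * Q_vib and evaluated entirely on the natural
# log scale (dataset log Q values span hundreds of log units).

#' Thermodynamic state for partition-function evaluation
#'
#' @param temperature absolute temperature, K (> 0).
#' @param standard_pressure pressure defining the translational volume
#'   convention V = kB*T/p, Pa.  Default 1e5 Pa (1 bar).  For unimolecular
#'   TST the convention cancels in Q_TS/Q_R; it only shifts absolute
#'   log Q values, so learned models are convention-dependent.
#' @param in_domain if `TRUE`, additionally require the temperature to lie
#'   in the dataset range (50, 2000) K.
#' @return an object of class `qest_thermo` with `temperature`, `beta`
#'   (1/(kB*T), 1/J) and `standard_pressure`.
#' @export
thermo_state <- function(temperature, standard_pressure = 1e5,
                         in_domain = FALSE) {
  temperature <- as.numeric(temperature)
  if (length(temperature) != 1 || !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive number in K")
  }
  if (in_domain && (temperature < 50 || temperature > 2000)) {
    stop("temperature ", temperature, " K outside the in-domain range (50, 2000) K")
  }
  st <- list(temperature = temperature, beta = 1 / (.pc$kB * temperature),
             standard_pressure = as.numeric(standard_pressure))
  class(st) <- "qest_thermo"
  st
}

#' Electronic partition function (log scale)
#'
#' Ground-state degeneracy only: ln(multiplicity).  Excited electronic
#' states are ignored (closed-shell organics).
#'
#' @param multiplicity positive integer spin multiplicity.
#' @return `log(multiplicity)`.
#' @export
log_q_electronic <- function(multiplicity) {
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  log(as.numeric(multiplicity))
}

#' Translational partition function (log scale)
#'
#' ln[(2 pi m kB T / h^2)^(3/2) * V] with V = kB*T/standard_pressure.
#'
#' @param total_mass total molecular mass, kg.
#' @param state a `qest_thermo`.
#' @return log of the translational partition function.
#' @export
log_q_translational <- function(total_mass, state) {
  stopifnot(inherits(state, "qest_thermo"))
  if (total_mass <= 0) stop("total mass must be positive")
  T_K <- state$temperature
  1.5 * log(2 * pi * total_mass * .pc$kB * T_K / .pc$h^2) +
    log(.pc$kB * T_K / state$standard_pressure)
}

# rotational temperature, K, for one principal moment (kg m^2)
.theta_rot <- function(I) .pc$hbar^2 / (2 * I * .pc$kB)

#' Rotational partition function (log scale)
#'
#' Classical rigid-rotor forms: 0 for a monatomic; ln[T/(sigma*theta)] for
#' a linear rotor with theta = hbar^2/(2 I kB) and I the degenerate
#' moment; ln[(sqrt(pi)/sigma) * sqrt(T^3/(theta_A theta_B theta_C))] for
#' a nonlinear top.
#'
#' @param inertia a `qest_inertia` from [inertia_analysis()].
#' @param sigma rotational symmetry number (integer >= 1).
#' @param state a `qest_thermo`.
#' @return log of the rotational partition function.
#' @export
log_q_rotational <- function(inertia, sigma, state) {
  stopifnot(inherits(inertia, "qest_inertia"), inherits(state, "qest_thermo"))
  if (sigma < 1 || sigma != round(sigma)) stop("sigma must be a positive integer")
  T_K <- state$temperature
  if (inertia$is_monatomic) return(0)
  if (inertia$is_linear) {
    I <- inertia$principal_moments[3]  # the degenerate pair I_B ~ I_C
    if (I <= 0) stop("zero moment of inertia for a linear species")
    return(log(T_K / (sigma * .theta_rot(I))))
  }
  mom <- inertia$principal_moments
  if (any(mom <= 0)) stop("zero principal moment for a nonlinear species")
  th <- .theta_rot(mom)
  log(sqrt(pi) / sigma) + 0.5 * log(T_K^3 / prod(th))
}

#' Vibrational partition function (log scale, ZPE-in-Q convention)
#'
#' Per real mode i with x_i = h c nu_i / (kB T):
#' sum_i [ -x_i/2 - ln(1 - exp(-x_i)) ].  The zero-point energy is carried
#' inside Q_vib, so log Q_vib <= 0 is permitted; an empty mode list gives 0.
#'
#' @param vp a `qest_vibration` from [classify_modes()].
#' @param state a `qest_thermo`.
#' @return log of the vibrational partition function.
#' @export
log_q_vibrational <- function(vp, state) {
  stopifnot(inherits(vp, "qest_vibration"), inherits(state, "qest_thermo"))
  if (length(vp$real_modes) == 0) return(0)
  if (any(vp$real_modes <= 0)) stop("vibrational modes must be positive wavenumbers")
  x <- .pc$c2 * vp$real_modes / state$temperature
  sum(-x / 2 - log1p(-exp(-x)))
}

# Temperature-independent ingredients, computed once per structure so that
# many-temperature evaluation does not redo inertia/symmetry/mode work.
.pf_terms <- function(s, sigma = NULL, spurious_tol = 1.0, linear_tol = 1e-4,
                      symmetry_tol = 0.05) {
  inertia <- inertia_analysis(s, linear_tol = linear_tol)
  vp <- classify_modes(s, spurious_tol = spurious_tol)
  if (is.null(sigma)) {
    sigma <- rotational_symmetry_number(s, tol = symmetry_tol,
                                        linear_tol = linear_tol)$sigma
  }
  list(structure_id = s$id, mass = sum(atomic_mass(s$atoms, "kg")),
       multiplicity = s$multiplicity, inertia = inertia, vp = vp,
       sigma = sigma)
}

.pf_eval <- function(terms, state) {
  lel <- log_q_electronic(terms$multiplicity)
  ltr <- log_q_translational(terms$mass, state)
  lrt <- log_q_rotational(terms$inertia, terms$sigma, state)
  lvb <- log_q_vibrational(terms$vp, state)
  res <- list(log_q_el = lel, log_q_trans = ltr, log_q_rot = lrt,
              log_q_vib = lvb, log_q_total = lel + ltr + lrt + lvb,
              temperature = state$temperature, structure_id = terms$structure_id)
  class(res) <- "qest_pf"
  res
}

#' Total RRHO partition function (log scale)
#'
#' Evaluates the four factors and their sum for one structure at one
#' temperature.  The total is the exact sum of the components by
#' construction.
#'
#' @param s a `qest_structure` with frequencies attached.
#' @param state a `qest_thermo`.
#' @param sigma optional rotational symmetry number; detected from the
#'   geometry when `NULL`.
#' @param spurious_tol,linear_tol,symmetry_tol tolerances forwarded to mode
#'   classification, linearity detection and symmetry detection.
#' @return an object of class `qest_pf` with fields `log_q_el`,
#'   `log_q_trans`, `log_q_rot`, `log_q_vib`, `log_q_total`,
#'   `temperature`, `structure_id`.
#' @export
total_log_q <- function(s, state, sigma = NULL, spurious_tol = 1.0,
                        linear_tol = 1e-4, symmetry_tol = 0.05) {
  stopifnot(inherits(s, "qest_structure"), inherits(state, "qest_thermo"))
  terms <- .pf_terms(s, sigma = sigma, spurious_tol = spurious_tol,
                     linear_tol = linear_tol, symmetry_tol = symmetry_tol)
  .pf_eval(terms, state)
}

#' @export
print.qest_pf <- function(x, ...) {
  cat(sprintf(paste0("<qest_pf %s @ %.1f K> log Q = %.3f ",
                     "(el %.3f, trans %.3f, rot %.3f, vib %.3f)\n"),
              x$structure_id, x$temperature, x$log_q_total, x$log_q_el,
              x$log_q_trans, x$log_q_rot, x$log_q_vib))
  invisible(x)
}

#' Total log Q over a temperature vector
#'
#' Vectorized convenience around [total_log_q()]: the temperature-
#' independent ingredients (masses, inertia, symmetry number, mode
#' classification) are computed once.
#'
#' @param s a `qest_structure` with frequencies attached.
#' @param temperatures numeric vector, K.
#' @param standard_pressure Pa.
#' @param ... tolerances forwarded to the per-structure setup.
#' @return numeric vector of total log Q values.
#' @export
total_log_q_vec <- function(s, temperatures, standard_pressure = 1e5, ...) {
  terms <- .pf_terms(s, ...)
  vapply(temperatures, function(T_K) {
    .pf_eval(terms, thermo_state(T_K, standard_pressure))$log_q_total
  }, numeric(1))
}

#' Quantum correction factor for a linear rigid rotor
#'
#' The quantum rotational level sum of a linear rotor exceeds the classical
#' closed form T/(sigma*theta) by the Mulholland (Euler-Maclaurin) series;
#' this returns the leading factor 1 + theta/3T + theta^2/15T^2 +
#' 4 theta^3/315T^3.  Used when comparing the classical closed form against
#' an explicit level-sum oracle: the two differ by this physical factor,
#' not by implementation error.
#'
#' @param theta rotational temperature, K.
#' @param temperature K.
#' @return dimensionless multiplicative correction (>= 1).
#' @export
linear_rotor_quantum_correction <- function(theta, temperature) {
  r <- theta / temperature
  1 + r / 3 + r^2 / 15 + 4 * r^3 / 315
}

#' Rotational temperature(s) of a structure
#'
#' Convenience accessor: theta = hbar^2/(2 I kB) per positive principal
#' moment, K.
#'
#' @param s a `qest_structure`.
#' @return numeric vector (length 1 for a linear rotor, 3 for a top,
#'   empty for a monatomic).
#' @export
rotational_temperatures <- function(s) {
  inertia <- inertia_analysis(s)
  if (inertia$is_monatomic) return(numeric(0))
  if (inertia$is_linear) return(.theta_rot(inertia$principal_moments[3]))
  .theta_rot(inertia$principal_moments)
}
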