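# Physical constants (CODATA 2018; SI-exact where the SI defines them).
.pc <- list(
  h       = 6.62607015e-34,          # Planck constant, J s
  hbar    = 6.62607015e-34 / (2 * pi),
  kB      = 1.380649e-23,            # Boltzmann constant, J/K
  c_cm    = 2.99792458e10,           # speed of light, cm/s (wavenumber use)
  amu     = 1.66053906660e-27,       # unified atomic mass unit, kg
  hartree = 4.3597447222071e-18,     # hartree, J
  NA_avog = 6.02214076e23            # Avogadro constant, 1/mol
)

# hc/kB in K per cm^-1; converts a wavenumber to a vibrational temperature.
.pc$c2 <- .pc$h * .pc$c_cm / .pc$kB

# Standard atomic weights (IUPAC 2021, conventional values), unified amu.
.atomic_weights <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.948,
  Br = 79.904, I = 126.90447
)

# Covalent radii in Angstrom (Cordero et al. single-bond radii).
.covalent_radii <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
  N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
  Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  Br = 1.20, I = 1.39
)

#' Atomic masses from element symbols
#'
#' Standard (isotope-averaged) atomic weights; the dataset molecules are
#' natural-abundance organics, so no isotope handling is attempted.
#'
#' @param symbols character vector of element symbols (e.g. `c("C","H")`).
#' @param unit `"amu"` (default) or `"kg"`.
#' @return numeric vector of masses.
#' @export
#' @examples
#' atomic_mass(c("H", "C", "O"))
atomic_mass <- function(symbols, unit = c("amu", "kg")) {
  unit <- match.arg(unit)
  bad <- setdiff(unique(symbols), names(.atomic_weights))
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  m <- unname(.atomic_weights[symbols])
  if (unit == "kg") m <- m * .pc$amu
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit-safe string hash (used for seed fan-out and config ids).
.hash_string <- function(x) {
  codes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  h
}

# Fan a master seed out to a per-key child seed, stable across platforms.
.fanout_seed <- function(master, key) {
  h <- .hash_string(as.character(key))
  s <- (h * 16807 + as.numeric(master) %% 2147483647) %% 2147483647
  s <- (s * 48271 + 11) %% 2147483647
  as.integer(max(1, s))
}

# Evaluate expr under a given seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
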