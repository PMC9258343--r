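#' Principal moments of inertia and linearity classification
#'
#' Builds the center-of-mass inertia tensor from the geometry and standard
#' atomic weights, diagonalizes it, and classifies the species as monatomic
#' (one atom), linear (smallest/largest principal moment ratio below
#' `linear_tol`) or a general nonlinear top.
#'
#' @param s a `qest_structure`.
#' @param linear_tol dimensionless ratio I_min/I_max below which the
#'   species counts as linear (default 1e-4, conservative for DFT-quality
#'   geometries).
#' @return an object of class `qest_inertia` with fields
#'   `principal_moments` (ascending, kg m^2), `axes` (eigenvector columns
#'   matching the moments), `is_linear`, `is_monatomic`.
#' @export
inertia_analysis <- function(s, linear_tol = 1e-4) {
  stopifnot(inherits(s, "qest_structure"))
  n <- length(s$atoms)
  m <- atomic_mass(s$atoms, "kg")
  X <- s$coords * 1e-10  # Angstrom -> m
  com <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, com)
  if (n == 1) {
    res <- list(principal_moments = c(0, 0, 0), axes = diag(3),
                is_linear = FALSE, is_monatomic = TRUE)
    class(res) <- "qest_inertia"
    return(res)
  }
  r2 <- rowSums(Xc^2)
  I <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(m * ((a == b) * r2 - Xc[, a] * Xc[, b]))
  }
  eig <- eigen(I, symmetric = TRUE)
  ord <- order(eig$values)
  mom <- pmax(eig$values[ord], 0)
  axes <- eig$vectors[, ord, drop = FALSE]
  is_linear <- mom[3] > 0 && (mom[1] / mom[3]) < linear_tol
  res <- list(principal_moments = mom, axes = axes,
              is_linear = is_linear, is_monatomic = FALSE)
  class(res) <- "qest_inertia"
  res
}

#' @export
print.qest_inertia <- function(x, ...) {
  cat(sprintf("<qest_inertia> I = (%.4e, %.4e, %.4e) kg m^2; %s\n",
              x$principal_moments[1], x$principal_moments[2],
              x$principal_moments[3],
              if (x$is_monatomic) "monatomic" else if (x$is_linear) "linear" else "nonlinear"))
  invisible(x)
}

#' Classify vibrational modes and compute the zero-point energy
#'
#' Imaginary modes (negative wavenumbers) and spurious near-zero modes
#' (|nu| below `spurious_tol`) are dropped from the vibrational product;
#' the zero-point energy sums h c nu / 2 over the retained modes.  A
#' transition state must present exactly one imaginary mode; a reactant or
#' product none beyond the tolerance.
#'
#' @param s a `qest_structure` with frequencies attached.
#' @param spurious_tol wavenumber magnitude cutoff, cm^-1 (default 1.0).
#' @return an object of class `qest_vibration` with fields `zpe` (J),
#'   `real_modes` and `dropped_modes` (cm^-1).
#' @export
classify_modes <- function(s, spurious_tol = 1.0) {
  stopifnot(inherits(s, "qest_structure"))
  if (is.null(s$frequencies)) stop("structure ", s$id, " has no frequencies attached")
  validate_structure(s, spurious_tol = spurious_tol)
  freqs <- s$frequencies
  keep <- freqs > 0 & abs(freqs) >= spurious_tol
  vp <- list(zpe = sum(.pc$h * .pc$c_cm * freqs[keep]) / 2,
             real_modes = freqs[keep],
             dropped_modes = freqs[!keep])
  class(vp) <- "qest_vibration"
  vp
}

#' @export
print.qest_vibration <- function(x, ...) {
  cat(sprintf("<qest_vibration> %d real modes, %d dropped, ZPE = %.4e J\n",
              length(x$real_modes), length(x$dropped_modes), x$zpe))
  invisible(x)
}
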