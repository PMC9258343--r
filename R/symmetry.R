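# External rotational symmetry number by brute-force enumeration of
# candidate point-group operations.  Candidate rotation axes are taken from
# the principal inertia axes, the center-of-mass -> atom directions and the
# sums/differences of same-element atom pairs; candidate angles are
# 2*pi*j/k for k in 2..kmax.  Every candidate orthogonal transform is kept
# iff it maps the centered, element-labeled point set onto itself within a
# distance tolerance, with a bijective same-element matching.

.rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

.reflection_matrix <- function(normal) {
  nrm <- normal / sqrt(sum(normal^2))
  diag(3) - 2 * tcrossprod(nrm)
}

# Mass-weighted centering; symmetry operations must fix the center of mass.
.center_coords <- function(s) {
  m <- atomic_mass(s$atoms, "amu")
  sweep(s$coords, 2, colSums(s$coords * m) / sum(m))
}

# Bijective same-element nearest-neighbor matching within tol.
.maps_onto_itself <- function(X, elements, M, tol) {
  Y <- X %*% t(M)
  n <- nrow(X)
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d2 <- (X[, 1] - Y[i, 1])^2 + (X[, 2] - Y[i, 2])^2 + (X[, 3] - Y[i, 3])^2
    cand <- which(!used & elements == elements[i] & d2 < tol^2)
    if (length(cand) == 0L) return(FALSE)
    used[cand[which.min(d2[cand])]] <- TRUE
  }
  TRUE
}

# Deduplicated unit axes from inertia axes, atom directions and
# same-element pair sums/differences.
.candidate_axes <- function(X, elements, inertia_axes) {
  cand <- list(inertia_axes[, 1], inertia_axes[, 2], inertia_axes[, 3])
  n <- nrow(X)
  for (i in seq_len(n)) cand[[length(cand) + 1L]] <- X[i, ]
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (elements[i] == elements[j]) {
        cand[[length(cand) + 1L]] <- X[i, ] + X[j, ]
        cand[[length(cand) + 1L]] <- X[i, ] - X[j, ]
      }
    }
  }
  keep <- list()
  seen <- character(0)
  for (v in cand) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) next
    u <- v / nv
    # canonical sign: first significant component positive
    lead <- which(abs(u) > 1e-8)[1]
    if (u[lead] < 0) u <- -u
    key <- paste(round(u, 5), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      keep[[length(keep) + 1L]] <- u
    }
  }
  keep
}

#' Enumerate invariant symmetry operations of a nonlinear molecule
#'
#' Returns every detected orthogonal operation (proper rotations,
#' reflections, improper rotations, inversion, and the identity) that maps
#' the centered structure onto itself within `tol`.  Linear and monatomic
#' species have continuous operation sets and are handled directly by
#' [rotational_symmetry_number()].
#'
#' @param s a `qest_structure` (nonlinear, at least two atoms).
#' @param tol matching tolerance in Angstrom after centering (default 0.05).
#' @param kmax highest rotation order probed (default 6; automatically
#'   capped at the largest same-element atom count).
#' @param proper_only if `TRUE`, skip improper candidates (faster when only
#'   the symmetry number is needed).
#' @return a list of operations, each a list with `matrix` (3 x 3
#'   orthogonal) and `is_proper` (determinant +1).
#' @export
detect_invariant_operations <- function(s, tol = 0.05, kmax = 6,
                                        proper_only = FALSE) {
  stopifnot(inherits(s, "qest_structure"))
  X <- .center_coords(s)
  if (max(sqrt(rowSums(X^2))) < 1e-6) {
    stop("degenerate geometry: all atoms coincide with the center of mass")
  }
  inertia <- inertia_analysis(s)
  axes <- .candidate_axes(X, s$atoms, inertia$axes)
  kmax <- max(2L, min(kmax, max(table(s$atoms))))
  thetas <- unique(unlist(lapply(2:kmax, function(k) 2 * pi * seq_len(k - 1) / k)))

  ops <- list(list(matrix = diag(3), is_proper = TRUE))
  # Distinct operations of order <= kmax differ by a Frobenius distance of
  # at least 2*sqrt(1 - cos(2*pi/kmax)); near-duplicates arising from
  # perturbed candidate axes sit far below 0.5 and are collapsed.
  add_op <- function(M, proper) {
    for (o in ops) {
      if (sqrt(sum((o$matrix - M)^2)) < 0.5) return(invisible(NULL))
    }
    if (.maps_onto_itself(X, s$atoms, M, tol)) {
      ops[[length(ops) + 1L]] <<- list(matrix = M, is_proper = proper)
    }
    invisible(NULL)
  }

  if (!proper_only) add_op(-diag(3), FALSE)  # inversion
  for (u in axes) {
    if (!proper_only) add_op(.reflection_matrix(u), FALSE)
    refl <- .reflection_matrix(u)
    for (th in thetas) {
      R <- .rotation_matrix(u, th)
      add_op(R, TRUE)
      if (!proper_only) add_op(R %*% refl, FALSE)  # improper rotation S(u, th)
    }
  }
  ops
}

# TRUE iff the 1D arrangement along the molecular axis is centrosymmetric:
# every atom has a same-element partner mirrored through the center of mass.
.linear_is_centrosymmetric <- function(s, tol) {
  X <- .center_coords(s)
  inertia <- inertia_analysis(s)
  axis <- inertia$axes[, 1]  # eigenvector of the (near-zero) smallest moment
  z <- as.numeric(X %*% axis)
  used <- rep(FALSE, length(z))
  for (i in seq_along(z)) {
    cand <- which(!used & s$atoms == s$atoms[i] & abs(z + z[i]) < tol)
    if (length(cand) == 0L) return(FALSE)
    used[cand[which.min(abs(z[cand] + z[i]))]] <- TRUE
  }
  TRUE
}

#' Rotational symmetry number
#'
#' The external symmetry number sigma counts the proper rotations (positive
#' determinant) that leave the molecule invariant.  Monatomic species give
#' sigma = 1.  Linear molecules are decided by a geometry-level rule rather
#' than from the discrete operation list: a centrosymmetric atom pattern
#' along the axis (e.g. O=C=O) gives sigma = 2 -- the perpendicular C2 of a
#' linear molecule otherwise surfaces as an improper reflection in
#' operation-based detectors -- and any other linear molecule gives
#' sigma = 1.  Nonlinear molecules get sigma from the enumerated proper
#' operations.
#'
#' @param s a `qest_structure`.
#' @param tol matching tolerance in Angstrom (default 0.05); sigma is
#'   computed at the given tolerance only, with no adaptive loosening.
#' @param linear_tol linearity threshold passed to [inertia_analysis()].
#' @return an object of class `qest_symmetry` with fields `sigma`,
#'   `operations_found`, `proper_count` (both `NA` for the continuous
#'   groups of monatomic/linear species) and `linear_class` (one of
#'   `"not_linear"`, `"linear_sigma1"`, `"linear_sigma2"`).
#' @export
rotational_symmetry_number <- function(s, tol = 0.05, linear_tol = 1e-4) {
  stopifnot(inherits(s, "qest_structure"))
  inertia <- inertia_analysis(s, linear_tol = linear_tol)
  if (inertia$is_monatomic) {
    res <- list(sigma = 1L, operations_found = NA_integer_,
                proper_count = NA_integer_, linear_class = "not_linear")
  } else if (inertia$is_linear) {
    centro <- .linear_is_centrosymmetric(s, tol)
    res <- list(sigma = if (centro) 2L else 1L,
                operations_found = NA_integer_, proper_count = NA_integer_,
                linear_class = if (centro) "linear_sigma2" else "linear_sigma1")
  } else {
    ops <- detect_invariant_operations(s, tol = tol, proper_only = FALSE)
    proper <- sum(vapply(ops, function(o) o$is_proper, logical(1)))
    res <- list(sigma = as.integer(proper), operations_found = length(ops),
                proper_count = as.integer(proper), linear_class = "not_linear")
  }
  class(res) <- "qest_symmetry"
  res
}

#' @export
print.qest_symmetry <- function(x, ...) {
  cat(sprintf("<qest_symmetry> sigma = %d (%s; %s operations found)\n",
              x$sigma, x$linear_class,
              ifelse(is.na(x$operations_found), "continuous",
                     as.character(x$operations_found))))
  invisible(x)
}
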