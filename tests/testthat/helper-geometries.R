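# Textbook molecular geometries (Angstrom) used across the suite, plus an
# independently coded brute-force symmetry-number oracle.

mol_co <- function() {
  structure_record(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.128)),
                   frequencies = 2143, id = "CO")
}

mol_co2 <- function() {
  structure_record(c("O", "C", "O"),
                   rbind(c(0, 0, -1.162), c(0, 0, 0), c(0, 0, 1.162)),
                   frequencies = c(667, 667, 1333, 2349), id = "CO2")
}

mol_h2o <- function() {
  structure_record(c("O", "H", "H"),
                   rbind(c(0, 0, 0.1173),
                         c(0, 0.7572, -0.4692),
                         c(0, -0.7572, -0.4692)),
                   frequencies = c(1595, 3657, 3756), id = "H2O")
}

mol_nh3 <- function() {
  structure_record(c("N", "H", "H", "H"),
                   rbind(c(0, 0, 0),
                         c(0.9377, 0, -0.3816),
                         c(-0.46885, 0.81208, -0.3816),
                         c(-0.46885, -0.81208, -0.3816)),
                   frequencies = c(950, 1627, 1627, 3337, 3444, 3444),
                   id = "NH3")
}

mol_ch4 <- function() {
  h <- 0.6294 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  structure_record(c("C", "H", "H", "H", "H"), rbind(c(0, 0, 0), h),
                   frequencies = c(1306, 1306, 1306, 1534, 1534, 2917,
                                   3019, 3019, 3019),
                   id = "CH4")
}

mol_c2h4 <- function() {
  structure_record(c("C", "C", "H", "H", "H", "H"),
                   rbind(c(0.6695, 0, 0), c(-0.6695, 0, 0),
                         c(1.2321, 0.9289, 0), c(1.2321, -0.9289, 0),
                         c(-1.2321, 0.9289, 0), c(-1.2321, -0.9289, 0)),
                   frequencies = c(826, 943, 949, 1023, 1236, 1342, 1444,
                                   1623, 3021, 3026, 3103, 3106),
                   id = "C2H4")
}

mol_benzene <- function() {
  ang <- 2 * pi * (0:5) / 6
  structure_record(rep(c("C", "H"), each = 6),
                   rbind(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
                         cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)),
                   frequencies = rep(1000, 30), id = "C6H6")
}

# n-butane heavy-atom zig-zag with terminal hydrogens (acyclic -> empty
# scaffold)
mol_butane <- function() {
  cc <- cbind(1.45 * (1:4), 0.3 * ((1:4) %% 2), 0)
  structure_record(c(rep("C", 4), "H", "H"),
                   rbind(cc, cc[1, ] + c(0, 0, 1.09), cc[4, ] + c(0, 0, 1.09)),
                   id = "butane")
}

mol_toluene <- function() {
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hs <- cbind(2.48 * cos(ang[2:6]), 2.48 * sin(ang[2:6]), 0)
  structure_record(c(rep("C", 6), "C", rep("H", 5)),
                   rbind(ring, c(2.89, 0, 0), hs), id = "toluene")
}

# random proper rotation matrix (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# --- independent brute-force sigma oracle -----------------------------------
# Rotations about every axis through atom positions, same-element pair
# midpoints and inertia axes, at angles 2*pi*j/k, k in 2..6; invariance
# decided by comparing sorted per-atom nearest-image distances.  Coded
# separately from the package's detector (different candidate assembly and
# matching route).
sigma_bruteforce <- function(s, tol = 0.05) {
  m <- atomic_mass(s$atoms, "amu")
  X <- sweep(s$coords, 2, colSums(s$coords * m) / sum(m))
  n <- nrow(X)
  inertia <- inertia_analysis(s)
  axes <- list(inertia$axes[, 1], inertia$axes[, 2], inertia$axes[, 3])
  for (i in seq_len(n)) axes[[length(axes) + 1]] <- X[i, ]
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (s$atoms[i] == s$atoms[j]) {
        axes[[length(axes) + 1]] <- (X[i, ] + X[j, ]) / 2
      }
    }
  }
  ok_match <- function(Y) {
    # exhaustive bijective matching via recursive search (small n only)
    assign_rec <- function(i, free) {
      if (i > n) return(TRUE)
      d <- sqrt(colSums((t(X[free, , drop = FALSE]) - Y[i, ])^2))
      for (k in order(d)) {
        j <- free[k]
        if (d[k] < tol && s$atoms[j] == s$atoms[i]) {
          if (assign_rec(i + 1, setdiff(free, j))) return(TRUE)
        } else if (d[k] >= tol) break
      }
      FALSE
    }
    assign_rec(1, seq_len(n))
  }
  found <- list(diag(3))
  for (ax in axes) {
    nv <- sqrt(sum(ax^2))
    if (nv < 1e-8) next
    u <- ax / nv
    for (k in 2:6) for (j in 1:(k - 1)) {
      th <- 2 * pi * j / k
      ct <- cos(th); st <- sin(th)
      K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
      R <- diag(3) + st * K + (1 - ct) * (K %*% K)
      dup <- any(vapply(found, function(M) sqrt(sum((M - R)^2)) < 0.5, logical(1)))
      if (!dup && ok_match(X %*% t(R))) found[[length(found) + 1]] <- R
    }
  }
  length(found)
}
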