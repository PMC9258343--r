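# EncodedBond-style fixed-length 3D featurization: per element-pair
# channels, Gaussian-smoothed histograms of interatomic distances on a
# radial grid.  Fixed length across molecules of any size is the defining
# property of the descriptor.

#' Featurizer configuration
#'
#' @param elements ordered element vocabulary (default H, C, N, O -- the
#'   dataset composition).
#' @param r_min,r_max radial grid bounds, Angstrom (defaults 0 and 6).
#' @param n_centers grid points per element-pair channel (default 32).
#' @param kernel_width Gaussian kernel width w, Angstrom (default 0.2).
#' @return an object of class `qest_feature_config` carrying the channel
#'   order (canonical unordered element pairs), grid centers, total
#'   `length` = n_centers * V(V+1)/2, and a `hash` identifying the
#'   configuration.
#' @export
feature_config <- function(elements = c("H", "C", "N", "O"),
                           r_min = 0, r_max = 6, n_centers = 32,
                           kernel_width = 0.2) {
  if (!(r_min < r_max)) stop("r_min must be < r_max")
  if (n_centers < 2) stop("n_centers must be >= 2")
  elements <- as.character(elements)
  pairs <- list()
  for (i in seq_along(elements)) for (j in i:length(elements)) {
    pairs[[length(pairs) + 1L]] <- c(elements[i], elements[j])
  }
  channel_names <- vapply(pairs, paste, character(1), collapse = "-")
  centers <- seq(r_min, r_max, length.out = n_centers)
  cfg <- list(elements = elements, r_min = r_min, r_max = r_max,
              n_centers = as.integer(n_centers), kernel_width = kernel_width,
              channels = channel_names, centers = centers,
              length = as.integer(n_centers * length(pairs)))
  cfg$hash <- sprintf("fc-%d", .hash_string(c(
    elements, format(c(r_min, r_max, n_centers, kernel_width), digits = 15))))
  class(cfg) <- "qest_feature_config"
  cfg
}

#' @export
print.qest_feature_config <- function(x, ...) {
  cat(sprintf("<qest_feature_config %s> %d channels x %d centers (%d values)\n",
              x$hash, length(x$channels), x$n_centers, x$length))
  invisible(x)
}

# canonical channel name for an unordered element pair
.pair_channel <- function(a, b, cfg) {
  ia <- match(a, cfg$elements)
  ib <- match(b, cfg$elements)
  if (ia <= ib) paste(a, b, sep = "-") else paste(b, a, sep = "-")
}

#' EncodedBond features of a structure
#'
#' For each unordered element pair (A, B) and grid center r_k the feature
#' value is the sum over unordered atom pairs \{i, j\} with elements
#' \{A, B\} of exp(-(d_ij - r_k)^2 / (2 w^2)).  Channels are concatenated
#' in canonical pair order; a single atom yields the all-zero vector.
#' The vector is invariant to rigid rotation/translation and to atom
#' permutation in the input file.
#'
#' @param s a `qest_structure` whose elements all lie in the vocabulary.
#' @param cfg a `qest_feature_config`.
#' @return an object of class `qest_features`: `values` (numeric, fixed
#'   length), `config_hash`, `is_difference = FALSE`.
#' @export
encoded_bond_features <- function(s, cfg = feature_config()) {
  stopifnot(inherits(s, "qest_structure"), inherits(cfg, "qest_feature_config"))
  bad <- setdiff(unique(s$atoms), cfg$elements)
  if (length(bad) > 0) {
    stop("element(s) outside the featurizer vocabulary: ",
         paste(bad, collapse = ", "))
  }
  values <- numeric(cfg$length)
  n <- length(s$atoms)
  if (n >= 2) {
    w2 <- 2 * cfg$kernel_width^2
    d <- as.matrix(stats::dist(s$coords))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ch <- .pair_channel(s$atoms[i], s$atoms[j], cfg)
      k <- match(ch, cfg$channels)
      idx <- ((k - 1) * cfg$n_centers + 1):(k * cfg$n_centers)
      values[idx] <- values[idx] + exp(-(d[i, j] - cfg$centers)^2 / w2)
    }
    # truncate numerically negligible kernel tails: keeps unpopulated grid
    # positions exactly zero so downstream range-based scaling stays sane
    values[values < 1e-12] <- 0
  }
  fv <- list(values = values, config_hash = cfg$hash, is_difference = FALSE)
  class(fv) <- "qest_features"
  fv
}

#' Product - reactant difference features
#'
#' Elementwise product minus reactant feature vector: describes the change
#' in 3D structure over the reaction and is the geometric input of the
#' transition-state estimator.  Antisymmetric in its arguments; identical
#' structures give the zero vector.
#'
#' @param product_fv,reactant_fv non-difference `qest_features` sharing a
#'   configuration.
#' @return a `qest_features` with `is_difference = TRUE`.
#' @export
difference_features <- function(product_fv, reactant_fv) {
  stopifnot(inherits(product_fv, "qest_features"),
            inherits(reactant_fv, "qest_features"))
  if (product_fv$config_hash != reactant_fv$config_hash) {
    stop("feature configuration mismatch: ", product_fv$config_hash,
         " vs ", reactant_fv$config_hash)
  }
  if (product_fv$is_difference || reactant_fv$is_difference) {
    stop("difference features require non-difference inputs")
  }
  fv <- list(values = product_fv$values - reactant_fv$values,
             config_hash = product_fv$config_hash, is_difference = TRUE)
  class(fv) <- "qest_features"
  fv
}

# ---- scalers ----------------------------------------------------------------

#' Fit an input or target scaler
#'
#' `"minmax_input"` maps each column's fitted range to `[0, 1]` (constant
#' columns map to 0, no division error); `"target_norm"` standardizes a
#' target vector (z-score) and is exactly invertible; `"identity"` leaves
#' values untouched (the transition-state estimator's screened choice).
#' Scalers must be fitted on development data only: when `ids` and `split`
#' are supplied, any id found in the hold-out aborts.
#'
#' @param kind one of `"minmax_input"`, `"target_norm"`, `"identity"`.
#' @param x matrix (minmax) or numeric vector (target_norm).
#' @param ids optional identifiers of the fit rows.
#' @param split optional `qest_split` used for the leakage guard.
#' @return an object of class `qest_scaler`.
#' @export
fit_scaler <- function(kind = c("minmax_input", "target_norm", "identity"),
                       x = NULL, ids = NULL, split = NULL) {
  kind <- match.arg(kind)
  if (!is.null(ids) && !is.null(split)) {
    leak <- intersect(unique(ids), split$test_ids)
    if (length(leak) > 0) {
      stop("leakage: scaler fit set contains hold-out id(s): ",
           paste(utils::head(leak, 3), collapse = ", "))
    }
  }
  sc <- switch(kind,
    identity = list(kind = kind),
    minmax_input = {
      if (is.null(x) || length(x) == 0) stop("empty fit set")
      x <- as.matrix(x)
      list(kind = kind, mins = apply(x, 2, min), maxs = apply(x, 2, max))
    },
    target_norm = {
      if (is.null(x) || length(x) == 0) stop("empty fit set")
      s <- stats::sd(x)
      list(kind = kind, mean = mean(x), sd = if (is.na(s) || s == 0) 1 else s)
    })
  class(sc) <- "qest_scaler"
  sc
}

#' @rdname fit_scaler
#' @param sc a fitted `qest_scaler`.
#' @export
apply_scaler <- function(sc, x) {
  stopifnot(inherits(sc, "qest_scaler"))
  switch(sc$kind,
    identity = x,
    target_norm = (x - sc$mean) / sc$sd,
    minmax_input = {
      x <- as.matrix(x)
      rng <- sc$maxs - sc$mins
      out <- sweep(x, 2, sc$mins)
      # ranges at numerical-noise level count as constant columns: dividing
      # by them would blow unseen data up by many orders of magnitude
      cols <- which(rng > 1e-10)
      out[, cols] <- sweep(out[, cols, drop = FALSE], 2, rng[cols], "/")
      zero <- which(rng <= 1e-10)
      if (length(zero) > 0) out[, zero] <- 0
      # data outside the fitted range (unseen scaffolds) is clipped to the
      # unit interval rather than extrapolated
      pmin(pmax(out, 0), 1)
    })
}

#' @rdname fit_scaler
#' @param y scaled values to invert.
#' @export
invert_scaler <- function(sc, y) {
  stopifnot(inherits(sc, "qest_scaler"))
  switch(sc$kind,
    identity = y,
    target_norm = y * sc$sd + sc$mean,
    minmax_input = stop("min-max input scaling is not inverted in this pipeline"))
}
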