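# Bemis-Murcko scaffolds from 3D geometry, and leakage-free scaffold-based
# hold-out / fold splitting.

#' Perceive bonds from 3D geometry
#'
#' Two atoms are bonded when their distance is below
#' `factor * (r_cov_i + r_cov_j)` with single-bond covalent radii.
#'
#' @param s a `qest_structure`.
#' @param factor distance cutoff multiplier (default 1.2).
#' @return integer matrix with two columns (bonded atom index pairs).
#' @export
perceive_bonds <- function(s, factor = 1.2) {
  stopifnot(inherits(s, "qest_structure"))
  n <- length(s$atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  rc <- unname(.covalent_radii[s$atoms])
  if (anyNA(rc)) stop("no covalent radius for: ",
                      paste(unique(s$atoms[is.na(rc)]), collapse = ", "))
  d <- as.matrix(stats::dist(s$coords))
  cut <- factor * outer(rc, rc, `+`)
  idx <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2, dimnames = NULL)
}

#' Bemis-Murcko scaffold of a structure
#'
#' Connectivity is perceived from the 3D geometry (covalent-radius distance
#' cutoff), then terminal atoms are deleted iteratively until a fixed point:
#' what remains is exactly the ring systems plus the linker paths between
#' them.  The result is canonicalized (canonical vertex labeling with
#' element colors) into a string key.  Acyclic molecules prune away
#' entirely and yield the empty scaffold `""`, forming one common split
#' group.
#'
#' @param s a `qest_structure`.
#' @param bond_factor cutoff multiplier for [perceive_bonds()].
#' @return the canonical scaffold string (`""` for acyclic molecules).
#' @export
murcko_scaffold <- function(s, bond_factor = 1.2) {
  stopifnot(inherits(s, "qest_structure"))
  edges <- perceive_bonds(s, factor = bond_factor)
  g <- igraph::make_empty_graph(n = length(s$atoms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = s$atoms)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  # iterative leaf pruning: removes all tree-like appendages, keeps
  # rings and ring-ring linkers (their atoms have degree >= 2 throughout)
  repeat {
    deg <- igraph::degree(g)
    drop <- which(deg <= 1)
    if (length(drop) == 0 || igraph::vcount(g) == 0) break
    g <- igraph::delete_vertices(g, drop)
  }
  if (igraph::vcount(g) == 0) return("")
  elements <- igraph::vertex_attr(g, "element")
  colors <- match(elements, names(.atomic_weights))
  cp <- igraph::canonical_permutation(g, colors = colors)
  gc <- igraph::permute(g, cp$labeling)
  el <- igraph::as_edgelist(gc, names = FALSE)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0(paste(igraph::vertex_attr(gc, "element"), collapse = ""),
         "|", paste(el[, 1], el[, 2], sep = "-", collapse = ","))
}

#' Scaffold-grouped hold-out and fold split
#'
#' Reactions are grouped by the Murcko scaffold of their reactant so that
#' the same (and similar) backbones never straddle a split boundary.
#' Whole groups -- largest first, ties shuffled under the seed -- are
#' assigned to the hold-out test set until it reaches `test_frac` of the
#' reactions; the remaining groups are distributed over `n_folds` folds,
#' each group going to the currently smallest fold.
#'
#' @param reactions list of `qest_reaction`.
#' @param test_frac hold-out fraction in (0, 1), default 0.10.
#' @param n_folds number of development folds (>= 2), default 5.
#' @param seed integer seed for tie shuffling.
#' @param bond_factor forwarded to [murcko_scaffold()].
#' @return an object of class `qest_split`: `test_ids` (character),
#'   `folds` (named integer vector reaction_id -> fold 0..n_folds-1 for
#'   development reactions) and `scaffold_key` (named character vector
#'   reaction_id -> scaffold).
#' @export
scaffold_split <- function(reactions, test_frac = 0.10, n_folds = 5,
                           seed = 1, bond_factor = 1.2) {
  if (!(test_frac > 0 && test_frac < 1)) stop("test_frac must be in (0,1)")
  if (n_folds < 2) stop("n_folds must be >= 2")
  ids <- vapply(reactions, function(r) r$reaction_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  scaff <- vapply(reactions, function(r) {
    murcko_scaffold(r$reactant, bond_factor = bond_factor)
  }, character(1))
  names(scaff) <- ids
  groups <- split(ids, scaff)
  if (length(groups) < n_folds + 1) {
    stop("need at least n_folds + 1 = ", n_folds + 1,
         " scaffold groups, found ", length(groups))
  }
  sizes <- lengths(groups)
  ord <- .with_seed(seed, order(-sizes, sample.int(length(sizes))))
  groups <- groups[ord]
  sizes <- sizes[ord]

  n_total <- length(ids)
  test_ids <- character(0)
  gi <- 1
  while (length(test_ids) < test_frac * n_total && gi <= length(groups)) {
    test_ids <- c(test_ids, groups[[gi]])
    gi <- gi + 1
  }
  fold_counts <- rep(0L, n_folds)
  folds <- integer(0)
  if (gi <= length(groups)) {
    for (k in gi:length(groups)) {
      f <- which.min(fold_counts) - 1L
      fold_counts[f + 1L] <- fold_counts[f + 1L] + length(groups[[k]])
      fv <- rep(f, length(groups[[k]]))
      names(fv) <- groups[[k]]
      folds <- c(folds, fv)
    }
  }
  if (length(folds) == 0) stop("test assignment consumed every group; lower test_frac")
  plan <- list(test_ids = test_ids, folds = folds, scaffold_key = scaff)
  class(plan) <- "qest_split"
  plan
}

#' @export
print.qest_split <- function(x, ...) {
  cat(sprintf("<qest_split> %d test, %d development over %d folds, %d scaffolds\n",
              length(x$test_ids), length(x$folds),
              length(unique(x$folds)), length(unique(x$scaffold_key))))
  invisible(x)
}

#' Write / read a split manifest as JSON
#'
#' @param plan a `qest_split`.
#' @param file path.
#' @return `read_split_json` returns the `qest_split`.
#' @export
write_split_json <- function(plan, file) {
  jsonlite::write_json(
    list(test = plan$test_ids, folds = as.list(plan$folds),
         scaffolds = as.list(plan$scaffold_key)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  plan <- list(test_ids = as.character(x$test),
               folds = unlist(x$folds),
               scaffold_key = unlist(lapply(x$scaffolds, function(v) v %||% "")))
  storage.mode(plan$folds) <- "integer"
  class(plan) <- "qest_split"
  plan
}
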