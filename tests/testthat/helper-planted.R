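# Planted-signal regression task for estimator recovery experiments: the
# ground truth is a fixed linear map of the EncodedBond features plus a
# c * (1/T) term.  The map is supported on the feature dimensions populated
# across most molecules (as real thermochemical structure is); weight on
# scaffold-unique dimensions would make the target unlearnable from other
# scaffolds by construction and the experiment would measure extrapolation,
# not recovery.  The structural part is scaled to twice the spread of the
# temperature part, emulating the structure-dominated variance of real
# partition-function data (where a temperature-only baseline explains
# little).  Noiseless by construction, so the generator defines truth.
make_planted_qest_task <- function(n_reactions = 200, n_temps = 10, seed = 11,
                                   cfg = feature_config(n_centers = 16),
                                   temp_coef = 1500) {
  spec <- fixture_spec(n_reactions = n_reactions, seed = seed,
                       n_temps = n_temps)
  rxns <- make_reaction_set(spec)
  plan <- scaffold_split(rxns, test_frac = 0.1, n_folds = 5, seed = seed)
  structures <- unlist(lapply(rxns, function(r) {
    list(r$reactant, r$ts, r$product)
  }), recursive = FALSE)
  names(structures) <- vapply(structures, function(s) s$id, character(1))
  F <- t(vapply(structures, function(s) encoded_bond_features(s, cfg)$values,
                numeric(cfg$length)))
  w <- .with_planted_seed(seed, stats::rnorm(ncol(F)))
  w[colMeans(F > 0) < 0.5] <- 0
  sraw <- as.numeric(F %*% w)
  # structural spread = 2x the temperature-part spread (sd of 1/T uniform on
  # (1/t_max, 1/t_min) is range/sqrt(12))
  temp_sd <- temp_coef * (1 / 50 - 1 / 2000) / sqrt(12)
  w <- w * 2 * temp_sd / stats::sd(sraw)
  struct <- as.numeric(F %*% w)
  names(struct) <- rownames(F)
  rows <- do.call(rbind, lapply(rxns, function(r) {
    do.call(rbind, lapply(list(r$reactant, r$ts, r$product), function(s) {
      data.frame(structure_id = s$id, reaction_id = r$reaction_id,
                 role = s$role, inv_T_K = 1 / r$temperatures,
                 log_q = struct[s$id] + temp_coef / r$temperatures)
    }))
  }))
  rownames(rows) <- NULL
  list(reactions = rxns, structures = structures, rows = rows, plan = plan,
       cfg = cfg, weights = w, temp_coef = temp_coef)
}

.with_planted_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed + 77000)
  force(expr)
}

planted_test_frame <- function(task) {
  task$rows[task$rows$reaction_id %in% task$plan$test_ids, , drop = FALSE]
}

planted_dev_frame <- function(task) {
  task$rows[task$rows$reaction_id %in% names(task$plan$folds), , drop = FALSE]
}

predict_qest_frame <- function(bundle, task, frame) {
  unlist(lapply(seq_len(nrow(frame)), function(i) {
    s <- task$structures[[frame$structure_id[i]]]
    predict_qest(bundle, s, 1 / frame$inv_T_K[i])
  }))
}
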