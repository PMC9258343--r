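# Feed-forward partition-function estimators.
#
# Qest:  [min-max scaled EncodedBond features || 1/T] -> normalized log Q.
# QesTS: [product-reactant difference features || log Q_R || log Q_P || 1/T]
#        (no input standardization) -> normalized log Q_TS.
# Double: Qest supplies log Q_R and log Q_P to QesTS, so no transition-state
#        information of any kind enters the inputs.
# Null:  log Q = m * (1/T) + b, ordinary least squares on the development
#        set; equivalent to assuming Q_TS/Q_R = 1 in the TST prefactor.

#' Network hyperparameter specification
#'
#' A single-hidden-layer feed-forward network with skip-layer (direct
#' input-to-output) connections, logistic hidden activation, linear output,
#' L2 weight decay and BFGS training -- deterministic given the seed.  All
#' fields are recorded in the trained bundle for reproducibility.
#'
#' @param hidden_units hidden layer width (default 8; the skip connections
#'   carry the affine backbone, so a narrow hidden layer optimizes more
#'   reliably than a wide one at these data scales).
#' @param weight_decay L2 regularization strength (default 1e-6).
#' @param max_iterations BFGS iteration cap (default 1500; full-batch BFGS
#'   on thousands of weights needs the headroom).
#' @param seed integer seed; member initializations are fanned out from it.
#' @param n_networks ensemble size (default 5).  Each member trains from an
#'   independent initialization and predictions are averaged: single BFGS
#'   solutions carry initialization-dependent biases on out-of-scaffold
#'   molecules that largely cancel in the mean.
#' @return an object of class `qest_spec`.
#' @export
estimator_spec <- function(hidden_units = 8, weight_decay = 1e-6,
                           max_iterations = 1500, seed = 1, n_networks = 5) {
  sp <- list(hidden_units = as.integer(hidden_units),
             weight_decay = weight_decay,
             max_iterations = as.integer(max_iterations),
             seed = as.integer(seed), n_networks = as.integer(n_networks),
             activation = "logistic", skip_layer = TRUE, output = "linear")
  class(sp) <- "qest_spec"
  sp
}

.train_net <- function(X, y, spec) {
  lapply(seq_len(spec$n_networks), function(k) {
    .with_seed(.fanout_seed(spec$seed, paste0("member-", k)),
      nnet::nnet(x = as.matrix(X), y = matrix(y, ncol = 1),
                 size = spec$hidden_units, linout = TRUE, skip = TRUE,
                 decay = spec$weight_decay, maxit = spec$max_iterations,
                 trace = FALSE, MaxNWts = 1e6, reltol = 1e-10))
  })
}

.net_predict <- function(net, X) {
  X <- as.matrix(X)
  preds <- vapply(net, function(m) as.numeric(stats::predict(m, X)),
                  numeric(nrow(X)))
  if (nrow(X) == 1) mean(preds) else rowMeans(preds)
}

.guard_leakage <- function(ids, split, what) {
  leak <- intersect(unique(ids), split$test_ids)
  if (length(leak) > 0) {
    stop("leakage: ", what, " contains hold-out reaction id(s): ",
         paste(utils::head(leak, 3), collapse = ", "))
  }
}

# feature matrix for a set of structures, rows named by structure id
.feature_matrix <- function(structures, cfg) {
  M <- t(vapply(structures, function(s) encoded_bond_features(s, cfg)$values,
                numeric(cfg$length)))
  rownames(M) <- vapply(structures, function(s) s$id, character(1))
  M
}

.row_folds <- function(reaction_ids, split) {
  f <- split$folds[reaction_ids]
  if (anyNA(f)) {
    stop("reaction id(s) missing from the development fold plan: ",
         paste(utils::head(unique(reaction_ids[is.na(f)]), 3), collapse = ", "))
  }
  unname(f)
}

.make_bundle <- function(kind, net, input_scaler, target_scaler, fcfg, spec,
                         validation_mae, manifest) {
  b <- list(kind = kind, network = net, input_scaler = input_scaler,
            target_scaler = target_scaler, feature_config = fcfg,
            feature_config_hash = fcfg$hash, spec = spec,
            validation_mae = validation_mae, training_manifest = manifest)
  class(b) <- "qest_bundle"
  b
}

#' @export
print.qest_bundle <- function(x, ...) {
  cat(sprintf("<qest_bundle %s> %d hidden units, validation MAE %.4f (log Q)\n",
              x$kind, x$spec$hidden_units, x$validation_mae))
  invisible(x)
}

#' Train the Qest molecular partition-function estimator
#'
#' Learns log Q from a structure's EncodedBond features and the inverse
#' temperature.  Inputs are min-max scaled and the target standardized,
#' both fitted on the training folds only.  Any hold-out reaction id in
#' the supplied rows aborts with a leakage error.  The bundle records the
#' validation MAE measured on one held-out development fold.
#'
#' @param rows development dataset rows from [build_q_dataset()].
#' @param structures list of `qest_structure` covering every
#'   `structure_id` in `rows`.
#' @param split a `qest_split`.
#' @param fcfg a `qest_feature_config`.
#' @param spec a `qest_spec`.
#' @param validation_fold fold index held out for validation (default: the
#'   highest fold index present).
#' @return a trained `qest_bundle` of kind `"qest"`.
#' @export
train_qest <- function(rows, structures, split, fcfg = feature_config(),
                       spec = estimator_spec(), validation_fold = NULL) {
  .guard_leakage(rows$reaction_id, split, "training rows")
  folds <- .row_folds(rows$reaction_id, split)
  validation_fold <- validation_fold %||% max(folds)
  sid <- vapply(structures, function(s) s$id, character(1))
  names(structures) <- sid
  need <- unique(rows$structure_id)
  missing <- setdiff(need, sid)
  if (length(missing) > 0) stop("structures missing for id(s): ",
                                paste(utils::head(missing, 3), collapse = ", "))
  F <- .feature_matrix(structures[need], fcfg)
  X <- cbind(F[rows$structure_id, , drop = FALSE], inv_T = rows$inv_T_K)
  y <- rows$log_q
  tr <- folds != validation_fold
  if (!any(tr) || !any(!tr)) stop("validation fold leaves no training or no validation rows")
  # scalers may see the whole development set (never the hold-out); the
  # network itself trains on the non-validation folds only
  in_sc <- fit_scaler("minmax_input", X)
  tg_sc <- fit_scaler("target_norm", y[tr])
  net <- .train_net(apply_scaler(in_sc, X[tr, , drop = FALSE]),
                    apply_scaler(tg_sc, y[tr]), spec)
  pred_val <- invert_scaler(tg_sc, .net_predict(net, apply_scaler(in_sc, X[!tr, , drop = FALSE])))
  vmae <- mean(abs(pred_val - y[!tr]))
  .make_bundle("qest", net, in_sc, tg_sc, fcfg, spec, vmae,
               list(n_train = sum(tr), n_validation = sum(!tr),
                    validation_fold = validation_fold,
                    n_structures = length(need)))
}

#' Predict log Q with a trained Qest bundle
#'
#' @param bundle a `qest_bundle` of kind `"qest"`.
#' @param s a `qest_structure`.
#' @param temperature numeric vector of temperatures, K.
#' @return de-normalized log Q predictions, one per temperature.
#' @export
predict_qest <- function(bundle, s, temperature) {
  stopifnot(inherits(bundle, "qest_bundle"))
  if (bundle$kind != "qest") stop("bundle kind is '", bundle$kind, "', expected 'qest'")
  fv <- encoded_bond_features(s, bundle$feature_config)
  if (fv$config_hash != bundle$feature_config_hash) {
    stop("feature configuration hash mismatch")
  }
  X <- cbind(matrix(fv$values, nrow = length(temperature),
                    ncol = length(fv$values), byrow = TRUE),
             inv_T = 1 / temperature)
  invert_scaler(bundle$target_scaler,
                .net_predict(bundle$network, apply_scaler(bundle$input_scaler, X)))
}

# assemble the QesTS design rows for one reaction at its temperatures
.qests_design <- function(r, fcfg, standard_pressure, with_target = TRUE,
                          log_q_r = NULL, log_q_p = NULL, temperatures = NULL) {
  temps <- temperatures %||% r$temperatures
  if (length(temps) == 0) stop("reaction ", r$reaction_id, " carries no temperatures")
  dfv <- difference_features(encoded_bond_features(r$product, fcfg),
                             encoded_bond_features(r$reactant, fcfg))
  if (is.null(log_q_r) || is.null(log_q_p)) {
    tr <- .pf_terms(r$reactant)
    tp <- .pf_terms(r$product)
    log_q_r <- vapply(temps, function(T_K) {
      .pf_eval(tr, thermo_state(T_K, standard_pressure))$log_q_total
    }, numeric(1))
    log_q_p <- vapply(temps, function(T_K) {
      .pf_eval(tp, thermo_state(T_K, standard_pressure))$log_q_total
    }, numeric(1))
  }
  X <- cbind(matrix(dfv$values, nrow = length(temps), ncol = length(dfv$values),
                    byrow = TRUE),
             log_q_r = log_q_r, log_q_p = log_q_p, inv_T = 1 / temps)
  y <- NULL
  if (with_target) {
    tts <- .pf_terms(r$ts)
    y <- vapply(temps, function(T_K) {
      .pf_eval(tts, thermo_state(T_K, standard_pressure))$log_q_total
    }, numeric(1))
  }
  list(X = X, y = y)
}

#' Train the QesTS transition-state estimator
#'
#' Learns log Q_TS from the product-reactant difference features, the
#' reactant and product log partition functions, and 1/T.  Inputs are not
#' standardized (the difference features are peaked around zero and the
#' screened identity scaling works best); the target is standardized.
#'
#' @param reactions development `qest_reaction` records carrying their
#'   sampled temperatures.
#' @param split a `qest_split`.
#' @param fcfg a `qest_feature_config`.
#' @param spec a `qest_spec`.
#' @param validation_fold as in [train_qest()].
#' @param standard_pressure Pa, used when computing the input/target
#'   partition functions.
#' @param targets optional named list, reaction id -> numeric vector of
#'   log Q_TS targets aligned with the reaction's temperatures, e.g. from a
#'   precomputed dataset; when `NULL` the targets are computed from the
#'   transition-state structures.
#' @return a trained `qest_bundle` of kind `"qests"`.
#' @export
train_qests <- function(reactions, split, fcfg = feature_config(),
                        spec = estimator_spec(), validation_fold = NULL,
                        standard_pressure = 1e5, targets = NULL) {
  ids <- vapply(reactions, function(r) r$reaction_id, character(1))
  .guard_leakage(ids, split, "training reactions")
  rfold <- .row_folds(ids, split)
  validation_fold <- validation_fold %||% max(rfold)
  parts <- lapply(reactions, .qests_design, fcfg = fcfg,
                  standard_pressure = standard_pressure,
                  with_target = is.null(targets))
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  y <- if (is.null(targets)) {
    unlist(lapply(parts, `[[`, "y"))
  } else {
    unlist(lapply(seq_along(reactions), function(i) {
      tv <- targets[[ids[i]]]
      if (length(tv) != length(reactions[[i]]$temperatures)) {
        stop("targets for ", ids[i], " misaligned with its temperatures")
      }
      tv
    }))
  }
  folds <- rep(rfold, vapply(parts, function(p) nrow(p$X), integer(1)))
  tr <- folds != validation_fold
  if (!any(tr) || !any(!tr)) stop("validation fold leaves no training or no validation rows")
  in_sc <- fit_scaler("identity")
  tg_sc <- fit_scaler("target_norm", y[tr])
  net <- .train_net(X[tr, , drop = FALSE], apply_scaler(tg_sc, y[tr]), spec)
  pred_val <- invert_scaler(tg_sc, .net_predict(net, X[!tr, , drop = FALSE]))
  vmae <- mean(abs(pred_val - y[!tr]))
  .make_bundle("qests", net, in_sc, tg_sc, fcfg, spec, vmae,
               list(n_train = sum(tr), n_validation = sum(!tr),
                    validation_fold = validation_fold,
                    n_reactions = length(reactions)))
}

#' Predict log Q_TS with a trained QesTS bundle
#'
#' @param bundle a `qest_bundle` of kind `"qests"`.
#' @param reactant,product `qest_structure` objects.
#' @param log_q_r,log_q_p reactant/product log partition functions, one
#'   per temperature (recycled if scalar).
#' @param temperature numeric vector, K.
#' @return log Q_TS predictions, one per temperature.
#' @export
predict_qests <- function(bundle, reactant, product, log_q_r, log_q_p,
                          temperature) {
  stopifnot(inherits(bundle, "qest_bundle"))
  if (bundle$kind != "qests") stop("bundle kind is '", bundle$kind, "', expected 'qests'")
  n <- length(temperature)
  log_q_r <- rep_len(log_q_r, n)
  log_q_p <- rep_len(log_q_p, n)
  dfv <- difference_features(encoded_bond_features(product, bundle$feature_config),
                             encoded_bond_features(reactant, bundle$feature_config))
  X <- cbind(matrix(dfv$values, nrow = n, ncol = length(dfv$values), byrow = TRUE),
             log_q_r = log_q_r, log_q_p = log_q_p, inv_T = 1 / temperature)
  invert_scaler(bundle$target_scaler,
                .net_predict(bundle$network, apply_scaler(bundle$input_scaler, X)))
}

#' The Double predictor: QesTS fed with Qest partition functions
#'
#' Qest predicts the reactant and product log partition functions from
#' their geometries; these, the difference features, and 1/T feed QesTS.
#' The composition needs only the reactant and product geometries -- no
#' transition-state structure or computed partition function appears
#' anywhere in its inputs.
#'
#' @param qest_bundle trained `"qest"` bundle.
#' @param qests_bundle trained `"qests"` bundle.
#' @param reactant,product `qest_structure` objects.
#' @param temperature numeric vector, K.
#' @return log Q_TS predictions, one per temperature.
#' @export
predict_double <- function(qest_bundle, qests_bundle, reactant, product,
                           temperature) {
  lqr <- predict_qest(qest_bundle, reactant, temperature)
  lqp <- predict_qest(qest_bundle, product, temperature)
  predict_qests(qests_bundle, reactant, product, lqr, lqp, temperature)
}

#' Fit the null linear baseline log Q = m (1/T) + b
#'
#' Ordinary least squares of log Q on inverse temperature over the
#' development rows.  Applying the null model to both the transition state
#' and the reactant makes the TST prefactor ratio exactly 1.
#'
#' @param rows development dataset rows.
#' @return an object of class `qest_null` with `slope` (K) and
#'   `intercept`.
#' @export
fit_null_model <- function(rows) {
  if (length(unique(rows$inv_T_K)) < 2) {
    stop("degenerate design: need at least two distinct 1/T values")
  }
  fit <- stats::lm(log_q ~ inv_T_K, data = rows)
  m <- list(slope = unname(stats::coef(fit)[2]),
            intercept = unname(stats::coef(fit)[1]))
  class(m) <- "qest_null"
  m
}

#' @rdname fit_null_model
#' @param model a `qest_null`.
#' @param inverse_temperature 1/T values, 1/K.
#' @export
predict_null <- function(model, inverse_temperature) {
  stopifnot(inherits(model, "qest_null"))
  model$slope * inverse_temperature + model$intercept
}

#' Evaluate predictions: MAE, MAE as percent of target SD, binned errors
#'
#' The headline convention: mean absolute error on log Q (or log k), and
#' the same MAE expressed as a percentage of the standard deviation of the
#' evaluated targets.  When inverse temperatures are supplied, per-bin
#' MAEs over equal-width 1/T bins are reported as well; the bin MAEs
#' weighted by bin counts recompose the overall MAE exactly.
#'
#' @param predictions,truths aligned numeric vectors.
#' @param inverse_temperature optional 1/T per pair, for binned errors.
#' @param n_bins number of equal-width 1/T bins (default 20).
#' @return an object of class `qest_evaluation`: `mae`, `mae_pct_of_std`,
#'   `n_evaluated`, and (if binned) a data.frame `bins` with columns
#'   `lower`, `upper`, `n`, `mae`.
#' @export
evaluate_predictions <- function(predictions, truths,
                                 inverse_temperature = NULL, n_bins = 20) {
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    stop("predictions and truths must be non-empty and aligned")
  }
  err <- abs(predictions - truths)
  mae <- mean(err)
  sd_t <- stats::sd(truths)
  res <- list(mae = mae,
              mae_pct_of_std = if (is.na(sd_t) || sd_t == 0) NA_real_ else 100 * mae / sd_t,
              n_evaluated = length(truths), bins = NULL)
  if (!is.null(inverse_temperature)) {
    br <- seq(min(inverse_temperature), max(inverse_temperature),
              length.out = n_bins + 1)
    bin <- findInterval(inverse_temperature, br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    res$bins <- do.call(rbind, lapply(seq_len(n_bins), function(k) {
      idx <- bin == k
      data.frame(lower = br[k], upper = br[k + 1], n = sum(idx),
                 mae = if (any(idx)) mean(err[idx]) else NA_real_)
    }))
  }
  class(res) <- "qest_evaluation"
  res
}

#' @export
print.qest_evaluation <- function(x, ...) {
  cat(sprintf("<qest_evaluation> MAE %.4f (%.2f%% of target SD), n = %d\n",
              x$mae, x$mae_pct_of_std, x$n_evaluated))
  invisible(x)
}

# ---- bundle persistence -----------------------------------------------------

#' Save / load a trained estimator bundle
#'
#' A bundle directory holds `manifest.json` (kind, hyperparameters,
#' feature configuration, training manifest), `scalers.json`, and the
#' network weights; loading reproduces predictions exactly.
#'
#' @param bundle a `qest_bundle`.
#' @param path directory to create.
#' @return `load_bundle` returns the `qest_bundle`.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "qest_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fc <- bundle$feature_config
  jsonlite::write_json(
    list(kind = bundle$kind, spec = unclass(bundle$spec),
         validation_mae = bundle$validation_mae,
         training_manifest = bundle$training_manifest,
         feature_config = list(elements = fc$elements, r_min = fc$r_min,
                               r_max = fc$r_max, n_centers = fc$n_centers,
                               kernel_width = fc$kernel_width)),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(input = unclass(bundle$input_scaler),
                            target = unclass(bundle$target_scaler)),
                       file.path(path, "scalers.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(bundle$network, file.path(path, "network.rds"))
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  scal <- jsonlite::read_json(file.path(path, "scalers.json"),
                              simplifyVector = TRUE)
  fc <- man$feature_config
  fcfg <- feature_config(elements = fc$elements, r_min = fc$r_min,
                         r_max = fc$r_max, n_centers = fc$n_centers,
                         kernel_width = fc$kernel_width)
  spec <- estimator_spec(hidden_units = man$spec$hidden_units,
                         weight_decay = man$spec$weight_decay,
                         max_iterations = man$spec$max_iterations,
                         seed = man$spec$seed)
  restore_scaler <- function(x) {
    sc <- x
    if (!is.null(sc$mins)) sc$mins <- as.numeric(sc$mins)
    if (!is.null(sc$maxs)) sc$maxs <- as.numeric(sc$maxs)
    class(sc) <- "qest_scaler"
    sc
  }
  .make_bundle(man$kind, readRDS(file.path(path, "network.rds")),
               restore_scaler(scal$input), restore_scaler(scal$target),
               fcfg, spec, man$validation_mae, man$training_manifest)
}
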