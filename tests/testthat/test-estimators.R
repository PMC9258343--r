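test_that("null model recovers exact linear parameters and flat targets", {
  inv_t <- 1 / c(60, 120, 300, 700, 1500)
  rows <- data.frame(inv_T_K = inv_t, log_q = 5000 * inv_t + 3)
  nm <- fit_null_model(rows)
  expect_equal(nm$slope, 5000, tolerance = 1e-8)
  expect_equal(nm$intercept, 3, tolerance = 1e-8)
  expect_equal(predict_null(nm, inv_t), rows$log_q, tolerance = 1e-8)

  flat <- data.frame(inv_T_K = inv_t, log_q = rep(7.5, 5))
  nf <- fit_null_model(flat)
  expect_equal(nf$slope, 0, tolerance = 1e-10)
  expect_equal(nf$intercept, 7.5, tolerance = 1e-10)
  expect_error(fit_null_model(data.frame(inv_T_K = rep(0.01, 3),
                                         log_q = 1:3)), "degenerate")
})

test_that("evaluation reports MAE, percent of SD, and exact bin decomposition", {
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "non-empty")
  ev0 <- evaluate_predictions(1:5, 1:5)
  expect_equal(ev0$mae, 0)
  expect_equal(ev0$mae_pct_of_std, 0)

  # folded-normal check: predicting the mean of standard-normal targets
  set.seed(2)
  y <- rnorm(2e5)
  ev <- evaluate_predictions(rep(mean(y), length(y)), y)
  expect_equal(ev$mae_pct_of_std, 100 * sqrt(2 / pi), tolerance = 0.01)

  inv_t <- runif(500, 1 / 2000, 1 / 50)
  pred <- rnorm(500)
  truth <- rnorm(500)
  evb <- evaluate_predictions(pred, truth, inverse_temperature = inv_t,
                              n_bins = 10)
  ok <- !is.na(evb$bins$mae)
  expect_equal(sum(evb$bins$mae[ok] * evb$bins$n[ok]) / sum(evb$bins$n[ok]),
               evb$mae, tolerance = 1e-10)
  expect_equal(sum(evb$bins$n), 500)
})

qest_task <- make_planted_qest_task(n_reactions = 60, n_temps = 4, seed = 19,
                                    cfg = feature_config(n_centers = 8))

test_that("Qest recovers a planted feature -> log Q map on held-out scaffolds", {
  dev <- planted_dev_frame(qest_task)
  tst <- planted_test_frame(qest_task)
  b <- train_qest(dev, qest_task$structures, qest_task$plan, qest_task$cfg,
                  estimator_spec(seed = 3, max_iterations = 500))
  pred <- predict_qest_frame(b, qest_task, tst)
  ev <- evaluate_predictions(pred, tst$log_q)
  expect_lt(ev$mae_pct_of_std, 10)
  # correlation with truth is essentially perfect on a noiseless planted map
  expect_gt(cor(pred, tst$log_q), 0.99)

  nm <- fit_null_model(dev)
  evn <- evaluate_predictions(predict_null(nm, tst$inv_T_K), tst$log_q)
  expect_gt(evn$mae, 3 * ev$mae)
})

test_that("training is seed-deterministic and predictions are repeatable and smooth", {
  dev <- planted_dev_frame(qest_task)
  sp <- estimator_spec(seed = 5, max_iterations = 60)
  b1 <- train_qest(dev, qest_task$structures, qest_task$plan, qest_task$cfg, sp)
  b2 <- train_qest(dev, qest_task$structures, qest_task$plan, qest_task$cfg, sp)
  expect_identical(b1$validation_mae, b2$validation_mae)
  s <- qest_task$structures[[1]]
  expect_identical(predict_qest(b1, s, 300), predict_qest(b1, s, 300))
  expect_identical(predict_qest(b1, s, c(300, 500)),
                   predict_qest(b2, s, c(300, 500)))
  # finite-difference smoothness in temperature
  p <- predict_qest(b1, s, c(400, 400.1))
  expect_lt(abs(diff(p)) / 0.1, 10)
})

test_that("shuffled feature-target pairing destroys learnability", {
  dev <- planted_dev_frame(qest_task)
  tst <- planted_test_frame(qest_task)
  shuffled <- dev
  set.seed(6)
  # permute the structural signal while keeping the temperature column:
  # reassign structure ids randomly across rows
  shuffled$structure_id <- sample(shuffled$structure_id)
  b <- train_qest(shuffled, qest_task$structures, qest_task$plan,
                  qest_task$cfg, estimator_spec(seed = 3, max_iterations = 200))
  pred <- predict_qest_frame(b, qest_task, tst)
  ev <- evaluate_predictions(pred, tst$log_q)
  nm <- fit_null_model(dev)
  evn <- evaluate_predictions(predict_null(nm, tst$inv_T_K), tst$log_q)
  # no better than the temperature-only baseline (comfortably same order)
  expect_gt(ev$mae, 0.5 * evn$mae)
})

test_that("leakage of hold-out reactions into training aborts", {
  bad <- qest_task$rows  # includes test reactions
  expect_error(train_qest(bad, qest_task$structures, qest_task$plan,
                          qest_task$cfg, estimator_spec(seed = 1)),
               "leakage")
  expect_error(train_qests(qest_task$reactions, qest_task$plan,
                           qest_task$cfg, estimator_spec(seed = 1)),
               "leakage")
})

test_that("QesTS recovers a planted (mean + difference-map) target", {
  cfg <- qest_task$cfg
  dev_rxns <- qest_task$reactions[vapply(qest_task$reactions, function(r) {
    r$reaction_id %in% names(qest_task$plan$folds)
  }, logical(1))]
  tst_rxns <- qest_task$reactions[vapply(qest_task$reactions, function(r) {
    r$reaction_id %in% qest_task$plan$test_ids
  }, logical(1))]
  set.seed(41)
  wd <- rnorm(cfg$length) * 5
  planted <- function(r) {
    dfv <- difference_features(encoded_bond_features(r$product, cfg),
                               encoded_bond_features(r$reactant, cfg))
    tr <- total_log_q_vec(r$reactant, r$temperatures)
    tp <- total_log_q_vec(r$product, r$temperatures)
    (tr + tp) / 2 + sum(dfv$values * wd)
  }
  targets <- lapply(qest_task$reactions, planted)
  names(targets) <- vapply(qest_task$reactions, function(r) r$reaction_id,
                           character(1))
  b <- train_qests(dev_rxns, qest_task$plan, cfg,
                   estimator_spec(seed = 9, max_iterations = 500),
                   targets = targets[names(qest_task$plan$folds)])
  pred <- unlist(lapply(tst_rxns, function(r) {
    tr <- total_log_q_vec(r$reactant, r$temperatures)
    tp <- total_log_q_vec(r$product, r$temperatures)
    predict_qests(b, r$reactant, r$product, tr, tp, r$temperatures)
  }))
  truth <- unlist(targets[vapply(tst_rxns, function(r) r$reaction_id,
                                 character(1))])
  ev <- evaluate_predictions(pred, truth)
  expect_lt(ev$mae_pct_of_std, 10)
  expect_gt(cor(pred, truth), 0.99)
})

test_that("zero difference vectors make QesTS depend only on (log Q_R, log Q_P, 1/T)", {
  cfg <- qest_task$cfg
  dev_rxns <- qest_task$reactions[vapply(qest_task$reactions, function(r) {
    r$reaction_id %in% names(qest_task$plan$folds)
  }, logical(1))]
  b <- train_qests(dev_rxns, qest_task$plan, cfg,
                   estimator_spec(seed = 2, max_iterations = 60))
  r1 <- dev_rxns[[1]]; r2 <- dev_rxns[[2]]
  # same structure as reactant and product -> zero difference features;
  # two different molecules give identical predictions at matched inputs
  p1 <- predict_qests(b, r1$reactant, r1$reactant, 10, 12, c(300, 600))
  p2 <- predict_qests(b, r2$reactant, r2$reactant, 10, 12, c(300, 600))
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("Double composes Qest into QesTS and never touches a TS structure", {
  dev <- planted_dev_frame(qest_task)
  dev_rxns <- qest_task$reactions[vapply(qest_task$reactions, function(r) {
    r$reaction_id %in% names(qest_task$plan$folds)
  }, logical(1))]
  bq <- train_qest(dev, qest_task$structures, qest_task$plan, qest_task$cfg,
                   estimator_spec(seed = 3, max_iterations = 60))
  bt <- train_qests(dev_rxns, qest_task$plan, qest_task$cfg,
                    estimator_spec(seed = 2, max_iterations = 60))
  r <- dev_rxns[[3]]
  temps <- c(250, 800)
  # compositional contract: Double == QesTS fed with Qest predictions
  lqr <- predict_qest(bq, r$reactant, temps)
  lqp <- predict_qest(bq, r$product, temps)
  expect_identical(predict_double(bq, bt, r$reactant, r$product, temps),
                   predict_qests(bt, r$reactant, r$product, lqr, lqp, temps))
  # interface-level: no transition-state structure or partition function
  # can be passed -- the only inputs are bundles, two geometries, T
  expect_setequal(names(formals(predict_double)),
                  c("qest_bundle", "qests_bundle", "reactant", "product",
                    "temperature"))
})

test_that("bundles round trip through disk with identical predictions", {
  dev <- planted_dev_frame(qest_task)
  b <- train_qest(dev, qest_task$structures, qest_task$plan, qest_task$cfg,
                  estimator_spec(seed = 3, max_iterations = 60))
  dir <- tempfile("bundle-")
  save_bundle(b, dir)
  b2 <- load_bundle(dir)
  s <- qest_task$structures[[5]]
  expect_equal(predict_qest(b2, s, c(100, 400, 1500)),
               predict_qest(b, s, c(100, 400, 1500)), tolerance = 1e-10)
  expect_identical(b2$kind, "qest")
  expect_equal(b2$validation_mae, b$validation_mae, tolerance = 1e-12)
  expect_identical(b2$feature_config_hash, b$feature_config_hash)
})
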