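test_that("undersampling keeps n_photo phototrophs and all other classes", {
  tt <- tiny_training()
  ds <- undersample(tt$scaled, 10, seed = 5)
  expect_equal(unname(table(ds$label)["phototrophy"]), 10L)
  expect_equal(unname(table(ds$label)["mixotrophy"]),
               unname(table(tt$scaled$label)["mixotrophy"]))
  expect_equal(unname(table(ds$label)["heterotrophy"]),
               unname(table(tt$scaled$label)["heterotrophy"]))

  # identity at the full count, determinism under the seed
  full <- undersample(tt$scaled, sum(tt$scaled$label == "phototrophy"), seed = 5)
  expect_equal(sort(full$id), sort(tt$scaled$id))
  expect_equal(undersample(tt$scaled, 10, seed = 5)$id, ds$id)
  expect_error(undersample(tt$scaled, 10000, seed = 5), "exceeds")
})

test_that("F1 evaluation matches hand-computed confusion arithmetic", {
  # phototrophy: TP=8, FP=2, FN=2 -> precision = recall = F1 = 0.8
  true <- c(rep("phototrophy", 10), rep("heterotrophy", 10))
  pred <- c(rep("phototrophy", 8), rep("heterotrophy", 2),
            rep("heterotrophy", 8), rep("phototrophy", 2))
  ev <- evaluate_f1(true, pred)
  expect_equal(ev$per_class$f1[ev$per_class$class == "phototrophy"], 0.8)
  expect_equal(ev$weighted_f1, 0.8)
  expect_equal(unname(ev$confusion["phototrophy", "phototrophy"]), 8)

  perfect <- evaluate_f1(c("mixotrophy", "heterotrophy"),
                         c("mixotrophy", "heterotrophy"))
  expect_equal(perfect$weighted_f1, 1)
  expect_equal(
    perfect$per_class$f1[perfect$per_class$support > 0], c(1, 1)
  )

  # single class present, all predicted as it: weighted F1 = 1
  one <- evaluate_f1(rep("phototrophy", 5), rep("phototrophy", 5))
  expect_equal(one$weighted_f1, 1)

  expect_error(evaluate_f1(character(), character()), "empty")
  expect_error(evaluate_f1("phototrophy", c("phototrophy", "mixotrophy")),
               "length")
})

test_that("classifier emits valid probability vectors and is deterministic", {
  tt <- tiny_training()
  clf <- fit_trophic_classifier(tt$scaled$x, tt$scaled$label)
  p <- predict_proba(clf, tt$scaled$x)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_equal(colnames(p), TROPHIC_MODES)
  clf2 <- fit_trophic_classifier(tt$scaled$x, tt$scaled$label)
  expect_equal(p, predict_proba(clf2, tt$scaled$x))
})

test_that("permutation importance: formula, zero-variance, and planted signal", {
  # formula check: importance = (F1 - F1_shuffled) / F1
  expect_equal((0.9 - 0.6) / 0.9, 1 / 3, tolerance = 1e-12)

  tt <- tiny_training()
  # add a constant feature: shuffling it is a no-op, importance exactly 0
  x <- cbind(tt$scaled$x, CONST01 = 0.5)
  lp <- labeled_profiles(x, as.character(tt$scaled$label))
  imp <- permutation_importance(lp, n_splits = 4, seed = 11)
  const_rows <- imp$per_split[imp$per_split$pfam_acc == "CONST01", ]
  expect_equal(const_rows$importance, rep(0, 4))

  # planted discriminative features outrank pure noise on average
  signal_mean <- mean(imp$mean$mean_importance[imp$mean$pfam_acc %in% tt$signal])
  noise_pfams <- setdiff(imp$mean$pfam_acc, c(tt$signal, tt$ctg, "CONST01"))
  noise_mean <- mean(imp$mean$mean_importance[imp$mean$pfam_acc %in% noise_pfams])
  expect_gt(signal_mean, 0)
  expect_lt(abs(noise_mean), 0.05)

  single_class <- labeled_profiles(x[lp$label == "phototrophy", ],
                                   rep("phototrophy",
                                       sum(lp$label == "phototrophy")))
  expect_error(permutation_importance(single_class), "2 classes")
})

test_that("feature retention follows the any-positive-dataset rule monotonically", {
  m <- function(...) tibble::tibble(pfam_acc = c("PFA", "PFB", "PFC"),
                                    mean_importance = c(...))
  ds1 <- m(-0.01, 0.002, 0)
  ds2 <- m(0.002, -0.1, 0)
  ds3 <- m(-0.03, -0.2, -1e-6)
  expect_equal(select_features(list(ds1, ds2, ds3)), c("PFA", "PFB"))
  # all non-positive -> dropped
  expect_equal(select_features(list(ds3)), character())
  # monotone: adding a dataset where a Pfam qualifies never removes features
  with_more <- select_features(list(ds1, ds2, ds3, m(0, 0, 0.5)))
  expect_true(all(select_features(list(ds1, ds2, ds3)) %in% with_more))
  expect_true("PFC" %in% with_more)
  expect_error(select_features(list()), "no importance")
})

test_that("grid search equals an independent exhaustive loop on a toy grid", {
  tt <- tiny_training()
  grid <- data.frame(
    n_estimators = c(5, 30),
    max_depth = c(2, 3),
    learning_rate = c(0.3, 0.3),
    gamma = c(0, 0),
    reg_lambda = c(0.5, 0.5)
  )
  gs <- grid_search(tt$scaled, grid, k = 3, seed = 9)

  # oracle: re-run the same stratified folds through a hand-rolled loop
  fold <- protroph:::stratified_folds(tt$scaled$label, 3,
                                      protroph:::substream_seed(9, "grid-folds"))
  oracle <- sapply(seq_len(nrow(grid)), function(g) {
    mean(sapply(1:3, function(f) {
      clf <- fit_trophic_classifier(tt$scaled$x[fold != f, ],
                                    tt$scaled$label[fold != f],
                                    as.list(grid[g, ]))
      pred <- protroph:::predict_label(clf, tt$scaled$x[fold == f, ])
      ev <- evaluate_f1(tt$scaled$label[fold == f], pred)
      ev$weighted_f1
    }))
  })
  expect_equal(gs$results$mean_f1, oracle, tolerance = 1e-12)
  expect_equal(gs$best_index, which(oracle == max(oracle))[1])

  single <- grid[1, , drop = FALSE]
  expect_equal(grid_search(tt$scaled, single, k = 3, seed = 9)$best_index, 1L)

  # the published grid enumerates 3*3*4*3*3 combinations
  expect_equal(nrow(default_hyperparam_grid()), 324)

  expect_error(grid_search(tt$scaled, grid, k = 50), "50")
})

test_that("stratified cross-validation preserves class balance and scores sanely", {
  tt <- tiny_training()
  cv <- cross_validate(tt$scaled, n_splits = 4, seed = 21)
  expect_equal(sort(unique(cv$per_split$class)),
               sort(c(TROPHIC_MODES, "weighted")))
  expect_true(all(cv$per_split$f1 >= 0 & cv$per_split$f1 <= 1))

  # label shuffling drives weighted F1 toward the class-frequency baseline
  shuffled <- labeled_profiles(
    tt$scaled$x,
    sample(as.character(tt$scaled$label)),
    tt$scaled$id
  )
  cv_null <- cross_validate(shuffled, n_splits = 4, seed = 22)
  w_null <- cv_null$summary$mean_f1[cv_null$summary$class == "weighted"]
  w_real <- cv$summary$mean_f1[cv$summary$class == "weighted"]
  expect_gt(w_real, w_null)
  expect_lt(w_null, 0.75)
})

test_that("prediction accuracy supports replicate and per-culture levels", {
  # 6 replicates over 3 cultures; culture B has one wrong replicate
  tbl <- tibble::tibble(
    culture_id = c("A", "A", "B", "B", "C", "C"),
    predicted = c("phototrophy", "phototrophy", "mixotrophy", "heterotrophy",
                  "heterotrophy", "mixotrophy"),
    expected = c("phototrophy", "phototrophy", "mixotrophy", "mixotrophy",
                 "heterotrophy|mixotrophy", "heterotrophy|mixotrophy")
  )
  expect_equal(prediction_accuracy(tbl, "replicate"), 5 / 6)
  expect_equal(prediction_accuracy(tbl, "culture"), 2 / 3)
})
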