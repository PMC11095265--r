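test_that("train/test split is disjoint, exhaustive, stratified and seeded", {
  rd <- rule_data()
  sp <- split_train_test(rd$matrix, rd$phenotypes, 0.7, seed = 3)
  n <- nrow(rd$matrix)
  expect_equal(length(sp$train$y) + length(sp$test$y), n)
  expect_equal(length(sp$train$y), floor(0.7 * n))
  expect_length(intersect(sp$train$genome_ids, sp$test$genome_ids), 0)
  # per-class train fraction within one genome of the global fraction
  for (cls in 0:1) {
    ncls <- sum(c(sp$train$y, sp$test$y) == cls)
    expect_lt(abs(sum(sp$train$y == cls) - 0.7 * ncls), 1 + 1e-9)
  }
  sp2 <- split_train_test(rd$matrix, rd$phenotypes, 0.7, seed = 3)
  expect_identical(sp$train$genome_ids, sp2$train$genome_ids)
  sp3 <- split_train_test(rd$matrix, rd$phenotypes, 0.7, seed = 4)
  expect_false(identical(sp$train$genome_ids, sp3$train$genome_ids))
})

test_that("a 1225-genome 70:30 split yields 857 train / 368 test", {
  big <- simulate_gene_content(1225, seed = 2)
  sp <- split_train_test(big$matrix, big$phenotypes, 0.7, seed = 1)
  expect_equal(length(sp$train$y), 857L)
  expect_equal(length(sp$test$y), 368L)
})

test_that("degenerate splits are rejected", {
  m <- matrix(0:1, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
  ph <- setNames(c("motile", rep("nonmotile", 3)), rownames(m))
  expect_error(split_train_test(m, ph, 0.5, stratified = TRUE), ">= 2 members")
  expect_error(split_train_test(m, ph[-1], 0.5), "without phenotype")
})

test_that("cross-validation finds a low-loss round count on separable data", {
  set.seed(8)
  x <- matrix(rbinom(400, 1, 0.5), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), paste0("f", 1:4)))
  y <- x[, 1]   # label equals one feature: perfectly separable
  cv <- cross_validate(x, y, k = 5, nrounds_max = 120, seed = 2)
  expect_lt(cv$best_logloss, 0.1)
  expect_error(cross_validate(x, y, k = 1), ">= 2")
  expect_error(cross_validate(x, y, k = 101), "exceeds")
  expect_error(cross_validate(x, rep(1, 100)), "single-class")
  # leave-one-out is a valid boundary case
  cv_loo <- cross_validate(x[1:12, ], y[1:12], k = 12, nrounds_max = 10, seed = 2)
  expect_true(cv_loo$best_nrounds >= 1)
})

test_that("training learns a single informative feature exactly", {
  set.seed(10)
  x <- matrix(rbinom(600, 1, 0.5), 150, 4,
              dimnames = list(sprintf("g%03d", 1:150), paste0("f", 1:4)))
  y <- x[, 2]
  m <- train_motility_model(x, y, nrounds = 30, seed = 1)
  pred <- predict(m, x)
  expect_equal(as.integer(pred$label == "motile"), unname(y))
  fi <- feature_importance(m)
  expect_equal(fi$gene_id[1], "f2")
  expect_equal(fi$importance[1], 1.0, tolerance = 1e-9)
  expect_error(train_motility_model(x, rep(0, 150)), "single-class")
  expect_error(train_motility_model(x, y, nrounds = 0), ">= 1")
})

test_that("training loss is non-increasing and training is seed-deterministic", {
  rd <- rule_data()
  sp <- split_train_test(rd$matrix, rd$phenotypes, 0.7, seed = 3)
  params <- list(eta = 0.2, max_depth = 4, min_child_weight = 1,
                 subsample = 0.8, colsample_bytree = 0.8, gamma = 0)
  m1 <- train_motility_model(sp$train$x, sp$train$y, params, nrounds = 60, seed = 9)
  expect_true(all(diff(m1$train_log$train_logloss) <= 1e-9))
  m2 <- train_motility_model(sp$train$x, sp$train$y, params, nrounds = 60, seed = 9)
  expect_identical(predict(m1, sp$test$x)$probability,
                   predict(m2, sp$test$x)$probability)
})

test_that("the classifier recovers a deterministic gene rule on held-out genomes", {
  rd <- rule_data()
  sp <- split_train_test(rd$matrix, rd$phenotypes, 0.7, seed = 3)
  cv <- cross_validate(sp$train$x, sp$train$y, k = 5, nrounds_max = 300, seed = 3)
  m <- train_motility_model(sp$train$x, sp$train$y, nrounds = cv$best_nrounds,
                            seed = 3)
  ev <- evaluate_model(m, sp$test$x, sp$test$y)
  expect_gte(ev$accuracy, 0.95)
  expect_gte(ev$sensitivity, 0.95)
  expect_gte(ev$specificity, 0.95)
  expect_equal(sum(ev$confusion), length(sp$test$y))
  # every panel gene informs the rule given enough rounds
  fi <- feature_importance(m)
  expect_setequal(fi$gene_id, colnames(rd$matrix))
  expect_equal(sum(fi$importance), 1, tolerance = 1e-9)
  # extreme gene content drives extreme predictions
  all_present <- matrix(1L, 1, 21, dimnames = list("hi", colnames(rd$matrix)))
  all_absent <- matrix(0L, 1, 21, dimnames = list("lo", colnames(rd$matrix)))
  expect_equal(predict(m, all_present)$label, "motile")
  expect_equal(predict(m, all_absent)$label, "nonmotile")
})

test_that("prediction handles missing and extra features with warnings", {
  rd <- rule_data()
  m <- train_motility_model(rd$matrix, as.integer(rd$phenotypes == "motile"),
                            nrounds = 20, seed = 2)
  x <- rd$matrix[1:5, ]
  expect_warning(p1 <- predict(m, x[, 1:18]), "treated as 0")
  expect_equal(nrow(p1), 5L)
  extra <- cbind(x, unexpected = 1L)
  expect_warning(p2 <- predict(m, extra), "unknown to the model")
  expect_equal(p2$probability, predict(m, x)$probability)
})

test_that("evaluation metrics match their definitions on forced predictions", {
  rd <- rule_data()
  y <- as.integer(rd$phenotypes == "motile")
  m <- train_motility_model(rd$matrix, y, nrounds = 60, seed = 2)
  ev <- suppressWarnings(evaluate_model(m, rd$matrix, y))  # training data: near-perfect
  expect_gte(ev$accuracy, 0.99)
  expect_warning(evaluate_model(m, rd$matrix[1:4, ], y[1:4]), "training set")
  expect_error(evaluate_model(m, rd$matrix[0, ], integer(0)), "empty test set")
  # degenerate predictor on a balanced set: accuracy 0.5, specificity 0
  xb <- rbind(matrix(1L, 10, 21), matrix(1L, 10, 21))
  dimnames(xb) <- list(sprintf("b%02d", 1:20), colnames(rd$matrix))
  yb <- rep(c(1L, 0L), each = 10)
  mv <- train_motility_model(
    rbind(matrix(1L, 5, 21, dimnames = list(sprintf("t%d", 1:5), colnames(rd$matrix))),
          matrix(0L, 5, 21, dimnames = list(sprintf("u%d", 1:5), colnames(rd$matrix)))),
    rep(c(1L, 0L), each = 5), nrounds = 10, seed = 1)
  evb <- evaluate_model(mv, xb, yb)   # predicts motile for every all-ones row
  expect_equal(evb$accuracy, 0.5)
  expect_equal(evb$specificity, 0)
  expect_equal(evb$sensitivity, 1)
})

test_that("label permutation collapses held-out accuracy to chance", {
  balanced <- simulate_gene_content(600, prob_carrier = 0.5, seed = 5)
  ph <- balanced$phenotypes
  set.seed(6)
  ph[] <- sample(ph)
  sp <- split_train_test(balanced$matrix, ph, 0.7, seed = 6)
  m <- train_motility_model(sp$train$x, sp$train$y, nrounds = 50, seed = 6)
  acc <- evaluate_model(m, sp$test$x, sp$test$y)$accuracy
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("hyperparameter tuning is budgeted, seeded and at least as good as defaults", {
  rd <- rule_data()
  sp <- split_train_test(rd$matrix, rd$phenotypes, 0.7, seed = 3)
  x <- sp$train$x[1:150, ]; y <- sp$train$y[1:150]
  t1 <- tune_hyperparameters(x, y, budget = 1, k = 3, nrounds_max = 40, seed = 5)
  expect_equal(nrow(t1$history), 1L)
  t2 <- tune_hyperparameters(x, y, budget = 4, k = 3, nrounds_max = 40, seed = 5)
  t3 <- tune_hyperparameters(x, y, budget = 4, k = 3, nrounds_max = 40, seed = 5)
  expect_identical(t2$params, t3$params)
  # the default point anchors the search: tuned CV loss <= default CV loss
  cv_def <- cross_validate(x, y, default_hyperparams(), k = 3,
                           nrounds_max = 40, seed = 5 + 1)
  expect_lte(t2$logloss, cv_def$best_logloss + 1e-12)
  expect_error(tune_hyperparameters(x, y, bounds = list(), budget = 2),
               "empty")
  expect_error(tune_hyperparameters(x, y, budget = 0), ">= 1")
})

test_that("models survive JSON serialization with identical predictions", {
  rd <- rule_data()
  y <- as.integer(rd$phenotypes == "motile")
  m <- train_motility_model(rd$matrix, y, nrounds = 25, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  save_motility_model(m, f)
  m2 <- load_motility_model(f)
  expect_equal(predict(m2, rd$matrix)$probability,
               predict(m, rd$matrix)$probability, tolerance = 1e-12)
  expect_identical(m2$feature_names, m$feature_names)
})
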