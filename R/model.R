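#' Stratified train/test split of a labelled gene-content matrix
#'
#' Partitions genomes into disjoint, exhaustive train and test sets. The
#' total training size is `floor(train_fraction * n)`; under stratification
#' it is allocated to classes by largest remainder so each class's train
#' fraction is within one genome of the global fraction. Reproducible under
#' a fixed seed.
#'
#' @param matrix binary gene-content matrix (genomes x genes).
#' @param phenotypes named label vector (`motile`/`nonmotile`).
#' @param train_fraction fraction in (0, 1); default 0.70.
#' @param seed integer seed.
#' @param stratified stratify by phenotype class (default `TRUE`).
#' @return list with elements `train` and `test`, each a list
#'   `(x, y, genome_ids)` where `y` is 0/1 (motile = 1).
#' @export
split_train_test <- function(matrix, phenotypes, train_fraction = 0.70,
                             seed = 1L, stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  missing <- setdiff(rownames(matrix), names(phenotypes))
  if (length(missing)) {
    stop("genomes without phenotype: ", paste(missing, collapse = ", "))
  }
  ids <- rownames(matrix)
  y <- as.integer(phenotypes[ids] == "motile")
  n <- length(ids)
  n_train <- floor(train_fraction * n)
  set.seed(seed)
  if (stratified) {
    cls <- split(seq_len(n), y)
    if (any(lengths(cls) < 2L)) {
      stop("each class needs >= 2 members for a stratified split")
    }
    quota <- train_fraction * lengths(cls)
    take <- floor(quota)
    rem <- n_train - sum(take)
    if (rem > 0) {
      extra <- order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1L
    }
    train_idx <- sort(unlist(mapply(function(i, k) sample(i, k),
                                    cls, take, SIMPLIFY = FALSE),
                             use.names = FALSE))
  } else {
    train_idx <- sort(sample(n, n_train))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  mk <- function(i) list(x = matrix[i, , drop = FALSE], y = y[i],
                         genome_ids = ids[i])
  list(train = mk(train_idx), test = mk(test_idx))
}

#' Default boosting hyperparameters and their search bounds
#'
#' Parameters follow the xgboost naming convention: `eta` (learning rate),
#' `max_depth`, `min_child_weight`, `subsample`, `colsample_bytree`
#' (per-tree column subsampling) and `gamma` (minimum split loss).
#'
#' @return `default_hyperparams()`: named list of parameter values.
#' @export
default_hyperparams <- function() {
  list(eta = 0.1, max_depth = 4L, min_child_weight = 1,
       subsample = 1, colsample_bytree = 1, gamma = 0)
}

#' @rdname default_hyperparams
#' @return `hyperparam_bounds()`: named list of `c(lower, upper)` bounds.
#' @export
hyperparam_bounds <- function() {
  list(eta = c(0.01, 0.3), max_depth = c(2, 8), min_child_weight = c(1, 10),
       subsample = c(0.5, 1), colsample_bytree = c(0.5, 1), gamma = c(0, 5))
}

.as_xgb_params <- function(params) {
  params$max_depth <- as.integer(round(params$max_depth))
  c(params, list(objective = "binary:logistic", nthread = 1L))
}

.check_labels <- function(y) {
  if (length(unique(y)) < 2L) stop("training labels are single-class")
}

#' k-fold cross-validation for the optimal boosting round count
#'
#' Runs k-fold cross-validation with the binary logistic objective and
#' returns the boosting round minimizing the mean held-out logistic loss.
#'
#' @param x binary feature matrix.
#' @param y 0/1 labels (motile = 1).
#' @param params hyperparameter list (see [default_hyperparams()]).
#' @param k number of folds (`2 <= k <= n`); `k = n` is leave-one-out.
#' @param nrounds_max maximum rounds examined.
#' @param seed integer seed (fold assignment and subsampling).
#' @return list with `best_nrounds`, `best_logloss` and the per-round
#'   evaluation log.
#' @export
cross_validate <- function(x, y, params = default_hyperparams(), k = 5L,
                           nrounds_max = 200L, seed = 1L) {
  .check_labels(y)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(y)) stop("k exceeds the number of training genomes")
  set.seed(seed)
  cv <- xgboost::xgb.cv(params = .as_xgb_params(params),
                        data = xgboost::xgb.DMatrix(
                          data.matrix(x), label = y, nthread = 1L),
                        nrounds = nrounds_max, nfold = k,
                        metrics = "logloss", verbose = 0,
                        early_stopping_rounds = 25L)
  log <- cv$evaluation_log
  best <- which.min(log$test_logloss_mean)
  list(best_nrounds = as.integer(log$iter[best]),
       best_logloss = as.numeric(log$test_logloss_mean[best]),
       evaluation_log = as.data.frame(log))
}

.sample_params <- function(u, bounds) {
  p <- mapply(function(ui, b) b[1] + ui * (b[2] - b[1]), u, bounds,
              SIMPLIFY = FALSE)
  names(p) <- names(bounds)
  p
}

.cv_score <- function(x, y, params, k, nrounds_max, seed) {
  cv <- cross_validate(x, y, params, k = k, nrounds_max = nrounds_max,
                       seed = seed)
  list(loss = cv$best_logloss, nrounds = cv$best_nrounds)
}

#' Bayesian hyperparameter optimization by cross-validated loss
#'
#' Searches the hyperparameter box for the point minimizing k-fold
#' cross-validated logistic loss. A Latin-hypercube initial design seeds a
#' Gaussian-process surrogate (squared-exponential kernel on unit-scaled
#' parameters) whose expected improvement selects each subsequent
#' evaluation. When `budget` is below `random_floor` the surrogate is
#' skipped and the search is purely random. Deterministic under `seed`.
#'
#' @param x,y training features and 0/1 labels.
#' @param bounds named list of `c(lower, upper)`; see [hyperparam_bounds()].
#' @param budget total number of cross-validated evaluations (>= 1).
#' @param k CV folds.
#' @param nrounds_max maximum boosting rounds per evaluation.
#' @param seed integer seed.
#' @param random_floor below this budget, fall back to random search.
#' @return list with `params` (best point, including the matching
#'   `nrounds`), `logloss`, and the evaluation `history` data frame.
#' @export
tune_hyperparameters <- function(x, y, bounds = hyperparam_bounds(),
                                 budget = 30L, k = 5L, nrounds_max = 200L,
                                 seed = 1L, random_floor = 10L) {
  if (!length(bounds)) stop("empty hyperparameter bounds")
  if (budget < 1L) stop("budget must be >= 1")
  .check_labels(y)
  d <- length(bounds)
  set.seed(seed)
  n_init <- if (budget < random_floor) budget else max(d + 1L, ceiling(budget / 3))
  n_init <- min(n_init, budget)
  # anchor the design at the default parameter point so the search never
  # returns something worse than the defaults on the same folds
  defaults <- default_hyperparams()
  u_default <- vapply(names(bounds), function(k) {
    v <- defaults[[k]] %||% mean(bounds[[k]])
    min(1, max(0, (v - bounds[[k]][1]) / diff(bounds[[k]])))
  }, numeric(1))
  U <- rbind(u_default, lhs::randomLHS(n_init, d))[seq_len(n_init), , drop = FALSE]
  evals <- vector("list", budget)
  score_one <- function(u, i) {
    p <- .sample_params(u, bounds)
    s <- .cv_score(x, y, p, k, nrounds_max, seed + i)
    c(p, list(nrounds = s$nrounds, logloss = s$loss))
  }
  for (i in seq_len(n_init)) evals[[i]] <- score_one(U[i, ], i)
  if (budget > n_init && budget >= random_floor) {
    for (i in (n_init + 1L):budget) {
      U_obs <- U
      losses <- vapply(evals[seq_len(i - 1L)], `[[`, numeric(1), "logloss")
      cand <- matrix(runif(500L * d), ncol = d)
      u_next <- .gp_ei_argmax(U_obs, losses, cand)
      U <- rbind(U, u_next)
      evals[[i]] <- score_one(u_next, i)
    }
  } else if (budget > n_init) {
    for (i in (n_init + 1L):budget) {
      u <- runif(d)
      U <- rbind(U, u)
      evals[[i]] <- score_one(u, i)
    }
  }
  hist <- do.call(rbind, lapply(evals, function(e) as.data.frame(e)))
  best <- which.min(hist$logloss)
  best_params <- evals[[best]]
  list(params = best_params[setdiff(names(best_params), "logloss")],
       logloss = hist$logloss[best],
       history = hist)
}

# Expected-improvement argmax under a simple GP surrogate with fixed
# length-scale (0.3 on the unit cube) and a small nugget.
.gp_ei_argmax <- function(U, losses, cand) {
  ell <- 0.3
  sig2 <- stats::var(losses)
  if (!is.finite(sig2) || sig2 == 0) sig2 <- 1e-6
  sqdist <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  }
  K <- sig2 * exp(-sqdist(U, U) / (2 * ell^2)) + diag(1e-6 * sig2, nrow(U))
  Ks <- sig2 * exp(-sqdist(cand, U) / (2 * ell^2))
  mu0 <- mean(losses)
  a <- solve(K, losses - mu0)
  mu <- mu0 + Ks %*% a
  Kinv_Kst <- solve(K, t(Ks))
  s2 <- pmax(sig2 - colSums(t(Ks) * Kinv_Kst), 1e-12)
  s <- sqrt(s2)
  fmin <- min(losses)
  z <- (fmin - mu) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  cand[which.max(ei), ]
}

#' Train the boosted motility classifier
#'
#' Fits a gradient-boosted regression-tree ensemble with the binary logistic
#' objective on binary gene features. The per-round training logistic loss is
#' recorded; it is non-increasing over rounds.
#'
#' @param x binary feature matrix (genomes x panel genes).
#' @param y 0/1 labels (motile = 1).
#' @param params hyperparameter list.
#' @param nrounds number of boosting rounds (>= 1).
#' @param seed integer seed.
#' @return a `motility_model`: list with the fitted booster, the feature
#'   names (the panel), hyperparameters, round count, training log and the
#'   training genome ids.
#' @export
train_motility_model <- function(x, y, params = default_hyperparams(),
                                 nrounds = 100L, seed = 1L) {
  .check_labels(y)
  if (nrounds < 1L) stop("nrounds must be >= 1")
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(data.matrix(x), label = y, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = c(.as_xgb_params(params), list(eval_metric = "logloss")),
    data = dtrain, nrounds = as.integer(nrounds),
    evals = list(train = dtrain), verbose = 0)
  log <- tryCatch(as.data.frame(attributes(booster)$evaluation_log),
                  error = function(e) NULL)
  structure(list(booster = booster,
                 feature_names = colnames(x),
                 params = params,
                 nrounds = as.integer(nrounds),
                 train_log = log,
                 train_genome_ids = rownames(x),
                 seed = seed),
            class = "motility_model")
}

#' @export
print.motility_model <- function(x, ...) {
  cat(sprintf("<motility_model> %d boosting rounds on %d gene features (%d training genomes)\n",
              x$nrounds, length(x$feature_names),
              length(x$train_genome_ids)))
  invisible(x)
}

.align_features <- function(newdata, feature_names) {
  newdata <- data.matrix(newdata)
  extra <- setdiff(colnames(newdata), feature_names)
  if (length(extra)) {
    warning("ignoring ", length(extra), " feature(s) unknown to the model: ",
            paste(head(extra, 5L), collapse = ", "))
  }
  missing <- setdiff(feature_names, colnames(newdata))
  if (length(missing)) {
    warning("panel gene(s) absent from input treated as 0: ",
            paste(head(missing, 5L), collapse = ", "))
    add <- matrix(0, nrow(newdata), length(missing),
                  dimnames = list(rownames(newdata), missing))
    newdata <- cbind(newdata, add)
  }
  newdata[, feature_names, drop = FALSE]
}

#' Predict flagellar motility for genomes
#'
#' @param object a `motility_model`.
#' @param newdata binary feature matrix over the panel genes; missing panel
#'   genes are treated as absent (with a warning), unknown extra features
#'   are ignored (with a warning).
#' @param ... unused.
#' @return data frame with `genome_id`, `probability` and `label`
#'   (`motile` iff probability > 0.5; a tie at exactly 0.5 is `nonmotile`).
#' @export
predict.motility_model <- function(object, newdata, ...) {
  xm <- .align_features(newdata, object$feature_names)
  p <- predict(object$booster, xgboost::xgb.DMatrix(xm, nthread = 1L))
  data.frame(genome_id = if (is.null(rownames(xm))) seq_len(nrow(xm)) else rownames(xm),
             probability = as.numeric(p),
             label = ifelse(p > 0.5, "motile", "nonmotile"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene importance of a trained model
#'
#' Importance is the normalized total loss reduction (gain) attributed to
#' each feature; values sum to 1 over features with nonzero gain and are
#' returned in descending order.
#'
#' @param model a `motility_model`.
#' @return data frame with `gene_id` and `importance`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "motility_model"))
  imp <- xgboost::xgb.importance(model = model$booster)
  data.frame(gene_id = imp$Feature, importance = imp$Gain,
             stringsAsFactors = FALSE)
}

#' Evaluate a trained model on a labelled test set
#'
#' @param model a `motility_model`.
#' @param x binary test features.
#' @param y 0/1 test labels (motile = 1).
#' @return list with `accuracy`, `sensitivity` (motile recall),
#'   `specificity` (nonmotile recall) and the `confusion` counts
#'   (`tp`, `fp`, `tn`, `fn`).
#' @export
evaluate_model <- function(model, x, y) {
  if (!nrow(x)) stop("empty test set")
  overlap <- intersect(rownames(x), model$train_genome_ids)
  if (length(overlap)) {
    warning(length(overlap), " test genome(s) were in the training set")
  }
  pred <- predict(model, x)
  yhat <- as.integer(pred$label == "motile")
  tp <- sum(yhat == 1 & y == 1); tn <- sum(yhat == 0 & y == 0)
  fp <- sum(yhat == 1 & y == 0); fn <- sum(yhat == 0 & y == 1)
  list(accuracy = (tp + tn) / length(y),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Serialize / load a motility model as JSON
#'
#' The booster is stored in xgboost's own JSON model dialect, wrapped in a
#' single JSON document together with the panel, hyperparameters and
#' training metadata, so the whole model stays a text file.
#'
#' @param model a `motility_model`.
#' @param path output `.json` path.
#' @return invisibly, `path` (saver); a `motility_model` (loader).
#' @export
save_motility_model <- function(model, path) {
  stopifnot(inherits(model, "motility_model"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  xgboost::xgb.save(model$booster, tmp)
  doc <- list(booster_json = paste(readLines(tmp, warn = FALSE), collapse = "\n"),
              feature_names = model$feature_names,
              params = model$params,
              nrounds = model$nrounds,
              seed = model$seed,
              train_genome_ids = model$train_genome_ids)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_motility_model
#' @export
load_motility_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(doc$booster_json, tmp)
  booster <- xgboost::xgb.load(tmp)
  structure(list(booster = booster,
                 feature_names = doc$feature_names,
                 params = as.list(doc$params),
                 nrounds = as.integer(doc$nrounds),
                 train_log = NULL,
                 train_genome_ids = doc$train_genome_ids,
                 seed = doc$seed),
            class = "motility_model")
}
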