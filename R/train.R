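#' Labeled expression profiles for classifier training
#'
#' Container pairing a samples-by-Pfam expression matrix with per-sample
#' trophic-mode labels.
#'
#' @param x Numeric matrix, samples in rows, Pfam features in columns.
#' @param label Character or factor vector of trophic-mode labels (see
#'   [TROPHIC_MODES]).
#' @param id Optional sample identifiers (defaults to row names or indices).
#' @return An object of class `labeled_profiles`: a list with elements `x`,
#'   `label` (factor with levels [TROPHIC_MODES]) and `id`.
#' @export
labeled_profiles <- function(x, label, id = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(label))
  label <- as.character(label)
  unknown <- setdiff(unique(label), TROPHIC_MODES)
  if (length(unknown) > 0) {
    stop("unknown trophic-mode label(s): ", paste(unknown, collapse = ", "))
  }
  id <- id %||% rownames(x) %||% as.character(seq_len(nrow(x)))
  structure(
    list(x = x, label = factor(label, levels = TROPHIC_MODES), id = id),
    class = "labeled_profiles"
  )
}

#' @export
print.labeled_profiles <- function(x, ...) {
  cat("<labeled_profiles> ", nrow(x$x), " profiles x ", ncol(x$x), " Pfams; ",
      paste(sprintf("%s=%d", levels(x$label), tabulate(x$label, 3)),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

subset_profiles <- function(lp, i) {
  labeled_profiles(lp$x[i, , drop = FALSE], as.character(lp$label[i]), lp$id[i])
}

#' Undersample the phototrophic majority class
#'
#' The training corpus is imbalanced toward phototrophy, so feature selection
#' runs on versions of the dataset in which a random subset of the
#' phototrophic profiles (sizes 50, 80, 100, 120 by default elsewhere) is kept
#' alongside every mixotrophic and heterotrophic profile.
#'
#' @param lp A [labeled_profiles()] object.
#' @param n_photo Number of phototrophic profiles to keep (sampled without
#'   replacement).
#' @param seed Integer seed controlling the subset.
#' @return A `labeled_profiles` object with `n_photo` phototrophic profiles
#'   and all others.
#' @export
undersample <- function(lp, n_photo, seed) {
  stopifnot(inherits(lp, "labeled_profiles"))
  photo <- which(lp$label == "phototrophy")
  if (n_photo > length(photo)) {
    stop("n_photo (", n_photo, ") exceeds available phototrophic profiles (",
         length(photo), ")")
  }
  keep <- withr::with_seed(seed, sample(photo, n_photo))
  subset_profiles(lp, sort(c(keep, which(lp$label != "phototrophy"))))
}

#' Default gradient-boosting hyperparameters
#'
#' Mid-grid values used when no grid search is run: 100 boosting rounds,
#' maximum depth 10, learning rate 0.1, gamma 0.5, L2 regularization 0.5.
#'
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function() {
  list(n_estimators = 100, max_depth = 10, learning_rate = 0.1,
       gamma = 0.5, reg_lambda = 0.5)
}

#' Hyperparameter grid for the gradient-boosting classifier
#'
#' The full Cartesian grid evaluated by [grid_search()]: n_estimators
#' (10, 100, 1000), max_depth (3, 10, 20), learning_rate (0.05, 0.1, 0.15,
#' 0.2), gamma (0, 0.5, 1), reg_lambda (0, 0.5, 1) - 324 combinations. Row
#' order defines the tie-break (first row wins).
#'
#' @return Data frame with one row per hyperparameter combination.
#' @export
default_hyperparam_grid <- function() {
  expand.grid(
    n_estimators = c(10, 100, 1000),
    max_depth = c(3, 10, 20),
    learning_rate = c(0.05, 0.1, 0.15, 0.2),
    gamma = c(0, 0.5, 1),
    reg_lambda = c(0, 0.5, 1),
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Fit the gradient-boosted multiclass classifier
#'
#' Thin wrapper over xgboost's `multi:softprob` objective with the package's
#' fixed class order ([TROPHIC_MODES]). Single-threaded and deterministic for
#' a given input.
#'
#' @param x Numeric feature matrix (samples x Pfams), already scaled or
#'   binarized as desired.
#' @param label Factor/character vector of trophic-mode labels.
#' @param hyperparams Named list as from [default_hyperparams()].
#' @param nthread Number of xgboost threads (default 1, reproducible).
#' @return List with elements `model` (an `xgb.Booster`) and `classes`.
#' @export
fit_trophic_classifier <- function(x, label, hyperparams = default_hyperparams(),
                                   nthread = 1) {
  label <- factor(as.character(label), levels = TROPHIC_MODES)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(label) - 1L)
  model <- xgboost::xgb.train(
    params = list(
      objective = "multi:softprob",
      num_class = length(TROPHIC_MODES),
      max_depth = as.integer(hyperparams$max_depth),
      eta = hyperparams$learning_rate,
      gamma = hyperparams$gamma,
      lambda = hyperparams$reg_lambda,
      nthread = nthread,
      seed = 0
    ),
    data = dtrain,
    nrounds = as.integer(hyperparams$n_estimators),
    verbose = 0
  )
  list(model = model, classes = TROPHIC_MODES)
}

#' Class-probability predictions from a fitted classifier
#'
#' @param clf Result of [fit_trophic_classifier()].
#' @param x Feature matrix with the same columns used in training.
#' @return Matrix of class probabilities (rows sum to 1), columns named by
#'   trophic mode.
#' @export
predict_proba <- function(clf, x) {
  p <- stats::predict(clf$model, xgboost::xgb.DMatrix(x))
  p <- matrix(p, nrow = nrow(x), ncol = length(clf$classes), byrow = FALSE)
  # xgboost returns an n x num_class matrix already; the matrix() call above
  # only normalizes the case where a plain vector comes back for n = 1
  colnames(p) <- clf$classes
  # float32 softmax sums deviate from 1 at ~1e-8; renormalize onto the simplex
  p / rowSums(p)
}

predict_label <- function(clf, x) {
  p <- predict_proba(clf, x)
  factor(clf$classes[max.col(p, ties.method = "first")], levels = TROPHIC_MODES)
}

#' Multiclass precision, recall, and F1
#'
#' Standard one-vs-rest definitions per class, plus the support-weighted mean
#' F1 (each class weighted by its number of true instances) and the confusion
#' matrix. Classes with no true or predicted instances get an F1 of 0.
#'
#' @param true,pred Equal-length vectors of trophic-mode labels.
#' @param levels Class order (default [TROPHIC_MODES]).
#' @return List with `per_class` (tibble: class, precision, recall, f1,
#'   support), `weighted_f1`, and `confusion` (true classes in rows).
#' @export
evaluate_f1 <- function(true, pred, levels = TROPHIC_MODES) {
  if (length(true) == 0) stop("cannot evaluate F1 on empty label vectors")
  if (length(true) != length(pred)) stop("label vectors differ in length")
  true <- factor(as.character(true), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  cm <- table(true = true, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) == 0, 0, tp / colSums(cm))
  rec <- ifelse(rowSums(cm) == 0, 0, tp / rowSums(cm))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  support <- as.numeric(rowSums(cm))
  list(
    per_class = tibble(class = levels, precision = unname(prec),
                       recall = unname(rec), f1 = unname(f1),
                       support = support),
    weighted_f1 = if (sum(support) == 0) 0 else sum(f1 * support) / sum(support),
    confusion = cm
  )
}

weighted_f1 <- function(true, pred, levels = TROPHIC_MODES) {
  evaluate_f1(true, pred, levels)$weighted_f1
}

#' Permutation feature importance by mean decrease in F1
#'
#' For each of `n_splits` random train/test splits (70/30 by default, not
#' stratified), the classifier is fitted on the training part and the weighted
#' F1 on the held-out part is recorded. Then, for every Pfam, that feature's
#' held-out values are shuffled across samples, predictions are recomputed,
#' and the importance is `(F1 - F1_shuffled) / F1` (defined as 0 when the
#' baseline F1 is 0). A positive importance means shuffling the feature
#' degraded performance. Per-feature scores are averaged across splits.
#'
#' @param lp A [labeled_profiles()] object (scaled or binarized expression).
#' @param n_splits Number of random splits (default 10).
#' @param test_frac Held-out fraction per split (default 0.30).
#' @param hyperparams Classifier hyperparameters.
#' @param seed Integer seed; splits and shuffles draw from named substreams.
#' @param chunk_size Number of features whose shuffled copies are scored in
#'   one prediction call (memory/speed trade-off only).
#' @return List with `mean` (tibble: pfam_acc, mean_importance) and
#'   `per_split` (tibble: pfam_acc, split, importance, f1_base).
#' @export
permutation_importance <- function(lp, n_splits = 10, test_frac = 0.30,
                                   hyperparams = default_hyperparams(),
                                   seed = 1, chunk_size = 200) {
  stopifnot(inherits(lp, "labeled_profiles"))
  if (length(unique(lp$label)) < 2) {
    stop("permutation importance requires at least 2 classes")
  }
  n <- nrow(lp$x)
  n_test <- max(1L, round(test_frac * n))
  pfams <- colnames(lp$x)
  per_split <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    split_seed <- substream_seed(seed, paste0("importance-split-", s))
    test_idx <- withr::with_seed(split_seed, sample(n, n_test))
    train_idx <- setdiff(seq_len(n), test_idx)
    clf <- fit_trophic_classifier(lp$x[train_idx, , drop = FALSE],
                                  lp$label[train_idx], hyperparams)
    x_test <- lp$x[test_idx, , drop = FALSE]
    y_test <- lp$label[test_idx]
    f1_base <- weighted_f1(y_test, predict_label(clf, x_test))
    imp <- numeric(length(pfams))
    shuffle_seed <- substream_seed(seed, paste0("importance-shuffle-", s))
    perms <- withr::with_seed(
      shuffle_seed,
      lapply(seq_along(pfams), function(i) sample(n_test))
    )
    # shuffling a feature that appears in no tree split cannot change any
    # prediction, so its importance is exactly 0; only used features need
    # re-prediction
    used <- tryCatch(
      unique(xgboost::xgb.importance(model = clf$model)$Feature),
      error = function(e) pfams
    )
    active <- which(pfams %in% used)
    for (start in seq_len(ceiling(length(active) / chunk_size))) {
      cols <- active[((start - 1) * chunk_size + 1):
                       min(start * chunk_size, length(active))]
      stacked <- x_test[rep(seq_len(n_test), length(cols)), , drop = FALSE]
      for (k in seq_along(cols)) {
        rows <- (k - 1) * n_test + seq_len(n_test)
        stacked[rows, cols[k]] <- x_test[perms[[cols[k]]], cols[k]]
      }
      pred <- predict_label(clf, stacked)
      for (k in seq_along(cols)) {
        rows <- (k - 1) * n_test + seq_len(n_test)
        f1_shuf <- weighted_f1(y_test, pred[rows])
        imp[cols[k]] <- if (f1_base == 0) 0 else (f1_base - f1_shuf) / f1_base
      }
    }
    per_split[[s]] <- tibble(pfam_acc = pfams, split = s, importance = imp,
                             f1_base = f1_base)
  }
  per_split <- bind_rows(per_split)
  means <- per_split %>%
    group_by(.data$pfam_acc) %>%
    summarise(mean_importance = mean(.data$importance), .groups = "drop")
  list(mean = means, per_split = per_split)
}

#' Select feature Pfams from importance runs on undersampled datasets
#'
#' A Pfam enters the feature set if shuffling it degraded the classifier's F1
#' on average (mean importance strictly positive under this package's sign
#' convention, where importance = (F1 - F1_shuffled)/F1) in at least one of
#' the undersampled datasets - i.e. if its inclusion improved model
#' performance by any magnitude somewhere.
#'
#' @param importances List of results from [permutation_importance()] (or of
#'   their `mean` tibbles), one per undersampled dataset.
#' @return Sorted character vector of retained Pfam accessions.
#' @export
select_features <- function(importances) {
  if (length(importances) == 0) stop("no importance records supplied")
  means <- lapply(importances, function(im) {
    if (is.list(im) && !is.data.frame(im) && !is.null(im$mean)) im$mean else as_tibble(im)
  })
  kept <- unique(unlist(lapply(means, function(m) {
    m$pfam_acc[m$mean_importance > 0]
  })))
  sort(kept)
}

stratified_folds <- function(label, k, seed) {
  fold <- integer(length(label))
  withr::with_seed(seed, {
    for (cls in levels(label)) {
      idx <- which(label == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Exhaustive hyperparameter grid search with stratified k-fold CV
#'
#' Evaluates every row of the hyperparameter grid by mean weighted F1 across
#' stratified k-fold cross-validation and returns the best row; ties are
#' broken by grid order (first row wins).
#'
#' @param lp A [labeled_profiles()] object.
#' @param grid Data frame of hyperparameter combinations (default
#'   [default_hyperparam_grid()]); columns must match
#'   [default_hyperparams()] names.
#' @param k Number of folds (default 5); every class must have at least `k`
#'   members.
#' @param seed Integer seed for fold assignment.
#' @return List with `best` (named list of hyperparameters), `best_index`,
#'   and `results` (grid with a `mean_f1` column).
#' @export
grid_search <- function(lp, grid = default_hyperparam_grid(), k = 5, seed = 1) {
  stopifnot(inherits(lp, "labeled_profiles"))
  counts <- table(droplevels(lp$label))
  if (any(counts < k)) {
    stop("stratified ", k, "-fold CV impossible: class(es) with < ", k,
         " members: ", paste(names(counts)[counts < k], collapse = ", "))
  }
  fold <- stratified_folds(lp$label, k, substream_seed(seed, "grid-folds"))
  mean_f1 <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- as.list(grid[g, , drop = FALSE])
    f1s <- vapply(seq_len(k), function(f) {
      train <- which(fold != f)
      test <- which(fold == f)
      clf <- fit_trophic_classifier(lp$x[train, , drop = FALSE],
                                    lp$label[train], hp)
      weighted_f1(lp$label[test], predict_label(clf, lp$x[test, , drop = FALSE]))
    }, numeric(1))
    mean(f1s)
  }, numeric(1))
  best_index <- which.max(mean_f1)
  list(
    best = as.list(grid[best_index, , drop = FALSE]),
    best_index = best_index,
    results = cbind(grid, mean_f1 = mean_f1)
  )
}

stratified_shuffle_split <- function(label, train_frac, seed, max_retries = 20) {
  n <- length(label)
  for (attempt in seq_len(max_retries)) {
    idx_train <- withr::with_seed(seed + attempt - 1L, {
      unlist(lapply(levels(label), function(cls) {
        idx <- which(label == cls)
        if (length(idx) == 0) return(integer(0))
        n_tr <- round(train_frac * length(idx))
        n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
        if (n_tr < 1L) integer(0) else sample(idx, n_tr)
      }))
    })
    idx_test <- setdiff(seq_len(n), idx_train)
    present <- levels(droplevels(label))
    if (all(present %in% label[idx_test]) && all(present %in% label[idx_train])) {
      if (attempt > 1) {
        message("split regenerated (", attempt - 1, " retr",
                if (attempt == 2) "y" else "ies",
                ") to keep every class in train and test")
      }
      return(list(train = sort(idx_train), test = sort(idx_test)))
    }
  }
  stop("could not produce a stratified split with every class in both parts")
}

#' Cross-validated performance of the trophic-mode classifier
#'
#' Random stratified train/test splits (83/17 by default; class proportions
#' preserved, splits are independent draws rather than a partition). Reports
#' per-mode and support-weighted F1 with means and standard errors over
#' splits. Any split that drops a class from its test part is regenerated
#' under a new sub-seed (and logged via `message()`).
#'
#' @param lp A [labeled_profiles()] object.
#' @param n_splits Number of splits (default 6).
#' @param train_frac Fraction used for training in each split (default 0.83).
#' @param hyperparams Classifier hyperparameters.
#' @param seed Integer seed.
#' @param train_subfrac Fraction of each split's training part actually used
#'   (stratified subsample; default 1). Used by [learning_curve()].
#' @return List with `per_split` (tibble: split, class, f1, weighted_f1) and
#'   `summary` (tibble: class - per mode plus `"weighted"` - mean_f1, se_f1).
#' @export
cross_validate <- function(lp, n_splits = 6, train_frac = 0.83,
                           hyperparams = default_hyperparams(), seed = 1,
                           train_subfrac = 1) {
  stopifnot(inherits(lp, "labeled_profiles"))
  rows <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sp <- stratified_shuffle_split(
      lp$label, train_frac, substream_seed(seed, paste0("cv-split-", s))
    )
    train <- sp$train
    if (train_subfrac < 1) {
      sub_seed <- substream_seed(seed, paste0("cv-subsample-", s))
      train <- withr::with_seed(sub_seed, {
        unlist(lapply(levels(lp$label), function(cls) {
          idx <- train[lp$label[train] == cls]
          if (length(idx) == 0) return(integer(0))
          sample(idx, max(1L, round(train_subfrac * length(idx))))
        }))
      })
    }
    clf <- fit_trophic_classifier(lp$x[train, , drop = FALSE],
                                  lp$label[train], hyperparams)
    pred <- predict_label(clf, lp$x[sp$test, , drop = FALSE])
    ev <- evaluate_f1(lp$label[sp$test], pred)
    rows[[s]] <- ev$per_class %>%
      select("class", "f1") %>%
      bind_rows(tibble(class = "weighted", f1 = ev$weighted_f1)) %>%
      mutate(split = s)
  }
  per_split <- bind_rows(rows)
  summary <- per_split %>%
    group_by(.data$class) %>%
    summarise(
      mean_f1 = mean(.data$f1),
      se_f1 = stats::sd(.data$f1) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  list(per_split = per_split, summary = summary)
}

#' Learning curve over the training fraction
#'
#' Repeats [cross_validate()] while using only a fraction of each split's
#' training part, tracing how held-out F1 grows with training-set size.
#'
#' @param lp A [labeled_profiles()] object.
#' @param fractions Training fractions to evaluate (default 0.25 to 1).
#' @param ... Passed to [cross_validate()].
#' @return Tibble with columns `fraction`, `class`, `mean_f1`, `se_f1`.
#' @export
learning_curve <- function(lp, fractions = c(0.25, 0.5, 0.75, 1), ...) {
  bind_rows(lapply(fractions, function(fr) {
    cv <- cross_validate(lp, train_subfrac = fr, ...)
    mutate(cv$summary, fraction = fr)
  }))
}

#' Accuracy of predictions against expected trophic modes
#'
#' For held-out culture transcriptomes the expected mode can be a set (e.g.
#' "phototrophy or mixotrophy" when the culture's behavior is ambiguous); a
#' prediction is correct if it falls in the set. Accuracy is reported per
#' individual transcriptome (`level = "replicate"`) or per culture, counting
#' a culture correct only when all of its replicates are correct
#' (`level = "culture"`).
#'
#' @param predictions Data frame with columns `culture_id`, `predicted`, and
#'   `expected` (character; alternatives separated by `|`).
#' @param level `"replicate"` or `"culture"`.
#' @return Proportion correct in \[0, 1\].
#' @export
prediction_accuracy <- function(predictions,
                                level = c("replicate", "culture")) {
  level <- match.arg(level)
  predictions <- as_tibble(predictions)
  correct <- mapply(function(p, e) {
    p %in% strsplit(e, "|", fixed = TRUE)[[1]]
  }, predictions$predicted, predictions$expected)
  if (level == "replicate") {
    mean(correct)
  } else {
    predictions %>%
      mutate(correct = correct) %>%
      group_by(.data$culture_id) %>%
      summarise(all_correct = all(.data$correct), .groups = "drop") %>%
      pull("all_correct") %>%
      mean()
  }
}
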