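#' Nested Monte-Carlo cross-validation scheme
#'
#' Protocol parameters for the supervised analyses: a class-proportional
#' 66.67/33.33 split into a training/test pool and an untouched validation
#' set, 4 outer Monte-Carlo resamples x 25 inner repeats (100 runs in
#' total), random 80% subsamples on both sides of each run, and a seeded
#' random hyperparameter search with 5-fold inner cross-validation.
#'
#' @param holdout_fraction Fraction of cases reserved as the untouched
#'   validation set.
#' @param outer_repeats Outer Monte-Carlo holdout resamples.
#' @param inner_repeats Inner repeats per outer resample.
#' @param train_subsample Fraction of the training/test pool resampled in
#'   each run.
#' @param validation_subsample Fraction of the validation set drawn fresh in
#'   each run for performance measurement.
#' @param tuning_budget Number of random-search hyperparameter draws; 0
#'   skips the search and uses the default random-forest configuration.
#' @param tuning_folds Folds of the inner tuning cross-validation.
#' @param seed Integer seed; all resampling and tuning derive from it.
#' @return Object of class `cv_scheme`.
#' @export
cv_scheme <- function(holdout_fraction = 1 / 3, outer_repeats = 4,
                      inner_repeats = 25, train_subsample = 0.8,
                      validation_subsample = 0.8, tuning_budget = 50,
                      tuning_folds = 5, seed = 42L) {
  for (f in c(holdout_fraction, train_subsample, validation_subsample)) {
    if (f <= 0 || f >= 1) stop("fractions must lie in (0,1)", call. = FALSE)
  }
  if (outer_repeats < 1 || inner_repeats < 1) {
    stop("repeats must be >= 1", call. = FALSE)
  }
  structure(list(holdout_fraction = holdout_fraction,
                 outer_repeats = as.integer(outer_repeats),
                 inner_repeats = as.integer(inner_repeats),
                 train_subsample = train_subsample,
                 validation_subsample = validation_subsample,
                 tuning_budget = as.integer(tuning_budget),
                 tuning_folds = as.integer(tuning_folds),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recall over the classes present in
#' `y_true`; 0.5 is chance level for two classes regardless of imbalance.
#'
#' @param y_true,y_pred Class labels of equal length.
#' @return Value in 0-1.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  classes <- unique(y_true)
  mean(vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1)))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' case scores higher than a random negative one, ties counting one half.
#'
#' @param y_true Binary labels; `positive` names the positive class
#'   (default: the last factor level).
#' @param scores Numeric scores, higher meaning more positive.
#' @param positive The positive class label.
#' @return Value in 0-1.
#' @export
roc_auc <- function(y_true, scores, positive = NULL) {
  y_true <- as.factor(y_true)
  if (is.null(positive)) positive <- levels(y_true)[nlevels(y_true)]
  pos <- y_true == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Class-proportional holdout split
#'
#' Splits cases into a training/test pool and a validation holdout,
#' preserving class proportions to within one case per class.
#'
#' @param y Class label per case; at least two classes must be present.
#' @param scheme A [cv_scheme()]; `holdout_fraction` and `seed` are used.
#' @param seed Optional seed overriding the scheme's.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_holdout <- function(y, scheme = cv_scheme(), seed = NULL) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("single-class data cannot be split class-proportionally", call. = FALSE)
  }
  set.seed(if (is.null(seed)) scheme$seed else seed)
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_train <- round(length(idx) * (1 - scheme$holdout_fraction))
    n_train <- min(max(n_train, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_train))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(y), train))
}

# default random-forest configuration and the random-search grid
.rf_default_params <- function(p) {
  list(num.trees = 300L, mtry = max(1L, floor(sqrt(p))),
       min.node.size = 1L, max.depth = 0L)
}

.rf_sample_params <- function(p) {
  list(num.trees = sample(c(100L, 200L, 300L, 400L, 500L), 1),
       mtry = sample.int(p, 1),
       min.node.size = sample(c(1L, 2L, 5L, 10L), 1),
       max.depth = sample(c(0L, 3L, 6L, 12L), 1))
}

.rf_fit <- function(X, y, params, seed) {
  ranger::ranger(x = as.data.frame(X), y = y, probability = TRUE,
                 num.trees = params$num.trees, mtry = min(params$mtry, ncol(X)),
                 min.node.size = params$min.node.size,
                 max.depth = params$max.depth,
                 seed = seed, num.threads = 1)
}

.rf_prob <- function(fit, X, positive) {
  pr <- stats::predict(fit, data = as.data.frame(X), num.threads = 1)$predictions
  pr[, positive]
}

.rf_class <- function(fit, X) {
  pr <- stats::predict(fit, data = as.data.frame(X), num.threads = 1)$predictions
  factor(colnames(pr)[max.col(pr, ties.method = "first")], levels = colnames(pr))
}

# stratified fold ids for tuning CV
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Tune and train a random-forest classifier
#'
#' Seeded uniform random search over number of trees, features per split,
#' minimal node size and tree depth, scored by stratified k-fold
#' cross-validated balanced accuracy; the best configuration is refit on all
#' of the data as a probability forest.
#'
#' @param X Feature matrix or data frame.
#' @param y Class labels (coerced to factor; >= 2 classes).
#' @param scheme A [cv_scheme()]; `tuning_budget`, `tuning_folds` and `seed`
#'   are used.
#' @param seed Optional seed overriding the scheme's.
#' @return Object of class `rf_model`: the fitted `ranger` forest (`fit`),
#'   the chosen hyperparameters (`params`), their cross-validated balanced
#'   accuracy (`cv_score`) and the factor levels (`classes`).
#' @export
tune_and_train <- function(X, y, scheme = cv_scheme(), seed = NULL) {
  X <- as.data.frame(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (nrow(X) != length(y)) stop("X and y disagree in length", call. = FALSE)
  seed <- if (is.null(seed)) scheme$seed else as.integer(seed)
  set.seed(seed)

  best <- .rf_default_params(ncol(X))
  best_score <- -Inf
  if (scheme$tuning_budget > 0) {
    k <- min(scheme$tuning_folds, min(table(y)))
    folds <- if (k >= 2) .stratified_folds(y, k) else NULL
    for (b in seq_len(scheme$tuning_budget)) {
      params <- .rf_sample_params(ncol(X))
      if (is.null(folds)) { # too few cases per class to cross-validate
        score <- 0
      } else {
        score <- mean(vapply(seq_len(k), function(f) {
          tr <- folds != f
          fit <- .rf_fit(X[tr, , drop = FALSE], y[tr], params, seed + b)
          balanced_accuracy(y[!tr], .rf_class(fit, X[!tr, , drop = FALSE]))
        }, numeric(1)))
      }
      if (score > best_score) {
        best_score <- score
        best <- params
      }
    }
  }
  fit <- .rf_fit(X, y, best, seed)
  structure(list(fit = fit, params = best, cv_score = best_score,
                 classes = levels(y)),
            class = "rf_model")
}

#' @rdname tune_and_train
#' @param object,newdata,type Standard predict arguments; `type` is
#'   `"class"` or `"prob"` (probability of the last class level).
#' @param ... Unused.
#' @export
predict.rf_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "class") {
    .rf_class(object$fit, newdata)
  } else {
    .rf_prob(object$fit, newdata, object$classes[length(object$classes)])
  }
}

#' Permutation importance of each feature
#'
#' The importance of a feature is the mean drop in balanced accuracy when
#' its column is shuffled, over `n_repeats` independent shuffles, relative
#' to the intact-data score of the fitted classifier.
#'
#' @param model An [tune_and_train()] model (or any object with a
#'   `predict(model, X, type = "class")` method).
#' @param X,y Data the importance is measured on (conventionally the
#'   training/test pool).
#' @param n_repeats Number of shuffles per feature.
#' @param seed Integer seed.
#' @return Data frame `feature, mean_importance, sd` (one row per feature,
#'   input column order), with attribute `n_repeats`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 50, seed = 42L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  set.seed(seed)
  baseline <- balanced_accuracy(y, predict(model, X, type = "class"))
  # all shuffles of one feature are scored in a single stacked prediction
  stack_idx <- rep(seq_len(n), times = n_repeats)
  block <- rep(seq_len(n_repeats), each = n)
  res <- lapply(seq_len(ncol(X)), function(j) {
    Xs <- X[stack_idx, , drop = FALSE]
    perm <- unlist(lapply(seq_len(n_repeats), function(k) sample.int(n)))
    Xs[[j]] <- X[[j]][perm]
    pred <- predict(model, Xs, type = "class")
    drops <- vapply(seq_len(n_repeats), function(k) {
      baseline - balanced_accuracy(y, pred[block == k])
    }, numeric(1))
    c(mean(drops), stats::sd(drops))
  })
  out <- data.frame(
    feature = colnames(X),
    mean_importance = vapply(res, `[`, numeric(1), 1),
    sd = vapply(res, `[`, numeric(1), 2),
    stringsAsFactors = FALSE
  )
  attr(out, "n_repeats") <- n_repeats
  out
}

#' Computed ABC analysis
#'
#' Algorithmic partition of positive values into the "important few" (A),
#' intermediate (B) and "trivial many" (C). Items are sorted in decreasing
#' order; the ABC curve plots the cumulative value fraction against the
#' cumulative item fraction. The A|B boundary is the curve point closest to
#' the ideal (0,1); the B|C boundary is the last item before the curve's
#' marginal segment slope drops below 1 (the break-even point past which an
#' item contributes less than an equal share). Boundaries are ordered
#' A|B <= B|C by taking min and max.
#'
#' @param values Named numeric vector of item values. Negative values are
#'   clipped to 0 (with a message); at least one value must be positive.
#' @return Object of class `abc_partition`: character vectors `A`, `B`, `C`
#'   (disjoint, covering all items), the `curve` (data frame of cumulative
#'   fractions), and `boundaries` (item counts at A|B and B|C).
#' @export
cabc <- function(values) {
  if (is.null(names(values))) names(values) <- paste0("item_", seq_along(values))
  if (any(values < 0)) {
    message("clipping ", sum(values < 0), " negative value(s) to 0")
    values <- pmax(values, 0)
  }
  if (all(values <= 0)) stop("all values are <= 0", call. = FALSE)
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  n <- length(v)
  total <- sum(v)
  cum_items <- seq_len(n) / n
  cum_value <- cumsum(v) / total

  dist_to_ideal <- sqrt(cum_items^2 + (1 - cum_value)^2)
  ab <- which.min(dist_to_ideal)
  slopes <- (v / total) * n          # marginal segment slope of the curve
  first_flat <- which(slopes < 1)
  bc <- if (length(first_flat) == 0) n else first_flat[1] - 1L

  lo <- min(ab, bc)
  hi <- max(ab, bc)
  items <- names(v)
  structure(list(
    A = items[seq_len(lo)],
    B = if (hi > lo) items[(lo + 1):hi] else character(0),
    C = if (hi < n) items[(hi + 1):n] else character(0),
    curve = data.frame(item_fraction = c(0, cum_items),
                       value_fraction = c(0, cum_value)),
    boundaries = c(ab = lo, bc = hi)
  ), class = "abc_partition")
}

#' Nested Monte-Carlo cross-validated performance
#'
#' Runs `outer_repeats x inner_repeats` evaluation runs. Each outer repeat
#' draws a fresh class-proportional holdout split; each inner repeat
#' resamples the training/test pool (stratified `train_subsample` fraction),
#' re-tunes and trains the classifier on the resample, and scores balanced
#' accuracy and ROC-AUC on a fresh stratified `validation_subsample`
#' fraction of the untouched validation set. With
#' `permute_features = TRUE`, every feature column of the training resample
#' is independently shuffled before fitting — an overfitting control that
#' should perform at chance (balanced accuracy about 0.5).
#'
#' @param X Feature matrix or data frame.
#' @param y Binary class labels.
#' @param features Columns of `X` to use (names or indices); defaults to all.
#' @param scheme A [cv_scheme()].
#' @param permute_features Shuffle training feature columns before fitting.
#' @return Object of class `performance_distribution`: `runs` (data frame
#'   with one row per run), `median` and `ci` (2.5th/97.5th percentiles) for
#'   balanced accuracy and ROC-AUC, and the scheme's repeat counts.
#' @export
nested_cv_evaluate <- function(X, y, features = NULL, scheme = cv_scheme(),
                               permute_features = FALSE) {
  X <- as.data.frame(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need both classes", call. = FALSE)
  if (is.null(features)) features <- colnames(X)
  X <- X[, features, drop = FALSE]
  positive <- levels(y)[nlevels(y)]

  runs <- vector("list", scheme$outer_repeats * scheme$inner_repeats)
  run <- 0L
  for (outer in seq_len(scheme$outer_repeats)) {
    split <- split_holdout(y, scheme, seed = scheme$seed + 7919L * outer)
    y_val_all <- y[split$validation]
    if (nlevels(droplevels(y_val_all)) < 2) {
      stop("validation set is single-class", call. = FALSE)
    }
    for (inner in seq_len(scheme$inner_repeats)) {
      run_seed <- scheme$seed + 7919L * outer + 104729L * inner
      set.seed(run_seed)
      pool <- .stratified_subsample(y, split$train, scheme$train_subsample)
      val <- .stratified_subsample(y, split$validation, scheme$validation_subsample)
      X_tr <- X[pool, , drop = FALSE]
      if (permute_features) {
        for (j in seq_len(ncol(X_tr))) X_tr[[j]] <- sample(X_tr[[j]])
      }
      model <- tune_and_train(X_tr, y[pool], scheme, seed = run_seed)
      cls <- predict(model, X[val, , drop = FALSE], type = "class")
      prob <- predict(model, X[val, , drop = FALSE], type = "prob")
      run <- run + 1L
      runs[[run]] <- data.frame(
        outer = outer, inner = inner,
        balanced_accuracy = balanced_accuracy(y[val], cls),
        roc_auc = roc_auc(y[val], prob, positive = positive)
      )
    }
  }
  runs <- do.call(rbind, runs)
  summarize <- function(v) {
    c(median = stats::median(v),
      stats::quantile(v, c(0.025, 0.975), type = 7))
  }
  structure(list(
    runs = runs,
    median = c(balanced_accuracy = stats::median(runs$balanced_accuracy),
               roc_auc = stats::median(runs$roc_auc)),
    ci = rbind(balanced_accuracy = summarize(runs$balanced_accuracy)[2:3],
               roc_auc = summarize(runs$roc_auc)[2:3]),
    outer_repeats = scheme$outer_repeats,
    inner_repeats = scheme$inner_repeats,
    permuted = permute_features
  ), class = "performance_distribution")
}

# stratified subsample of `fraction` of the cases in `idx`
.stratified_subsample <- function(y, idx, fraction) {
  out <- integer(0)
  for (cl in levels(y)) {
    cl_idx <- idx[y[idx] == cl]
    n_take <- max(1L, round(length(cl_idx) * fraction))
    out <- c(out, sample(cl_idx, min(n_take, length(cl_idx))))
  }
  sort(out)
}

#' Feature attribution for cluster membership
#'
#' One-vs-rest analysis of each cluster on the four DAS28-CRP components of
#' an equalized (augmented) dataset: for every cluster label, a classifier
#' is tuned on the training pool of a class-proportional split, permutation
#' importance over the 4 components is computed, the components are
#' categorized by [cabc()], and the top-ranked component alone is evaluated
#' under [nested_cv_evaluate()] (optionally together with the permuted
#' control).
#'
#' @param data4 Matrix or data frame of the four components (n x 4).
#' @param cluster Cluster label per row.
#' @param scheme A [cv_scheme()].
#' @param n_repeats Permutation-importance repeats.
#' @param evaluate Run the nested cross-validated single-feature evaluation
#'   (slower); otherwise only importances are returned.
#' @param permuted_control Also evaluate the permuted-feature control.
#' @return Named list (one element per cluster label) of lists with
#'   `importance`, `abc`, `top_feature`, and (if evaluated) `performance`
#'   and `performance_permuted`.
#' @export
cluster_membership_importance <- function(data4, cluster, scheme = cv_scheme(),
                                          n_repeats = 50, evaluate = TRUE,
                                          permuted_control = FALSE) {
  data4 <- as.data.frame(data4)
  labels <- sort(unique(cluster))
  if (length(labels) < 2) {
    stop("need at least 2 clusters for one-vs-rest attribution", call. = FALSE)
  }
  out <- list()
  for (k in labels) {
    y <- factor(ifelse(cluster == k, "member", "other"),
                levels = c("other", "member"))
    split <- split_holdout(y, scheme, seed = scheme$seed + k)
    model <- tune_and_train(data4[split$train, , drop = FALSE], y[split$train],
                            scheme, seed = scheme$seed + k)
    imp <- permutation_importance(model, data4[split$train, , drop = FALSE],
                                  y[split$train], n_repeats = n_repeats,
                                  seed = scheme$seed + k)
    abc <- cabc(setNames(imp$mean_importance, imp$feature))
    top <- imp$feature[which.max(imp$mean_importance)]
    entry <- list(importance = imp, abc = abc, top_feature = top)
    if (evaluate) {
      entry$performance <- nested_cv_evaluate(data4, y, features = top,
                                              scheme = scheme)
      if (permuted_control) {
        entry$performance_permuted <- nested_cv_evaluate(
          data4, y, features = top, scheme = scheme, permute_features = TRUE)
      }
    }
    out[[paste0("cluster_", k)]] <- entry
  }
  out
}
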