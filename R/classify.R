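#' Experiment specifications
#'
#' The three outcome-prediction tasks:
#' \describe{
#'   \item{1}{binary: complete recovery (rating 4) vs incomplete or no
#'     recovery (ratings 1-3), on all samples.}
#'   \item{2}{3-class: ratings 1 vs 2 vs 3, on the non-recovered subset.}
#'   \item{3}{4-class: ratings 1 through 4, on all samples.}
#' }
#'
#' @param id experiment id (1, 2 or 3).
#' @return list with `id`, `domain` (predicate on ratings), `map`
#'   (rating -> integer class label), and `classes`.
#' @export
experiment_spec <- function(id) {
  id <- as.integer(id)
  switch(as.character(id),
    "1" = list(id = 1L, domain = function(r) r %in% 1:4,
               map = function(r) as.integer(r == 4L), classes = 0:1),
    "2" = list(id = 2L, domain = function(r) r %in% 1:3,
               map = function(r) as.integer(r), classes = 1:3),
    "3" = list(id = 3L, domain = function(r) r %in% 1:4,
               map = function(r) as.integer(r), classes = 1:4),
    dv_stop("dyadvox_config_error", "unknown experiment id %s", id))
}

#' Default RBF-SVM hyperparameter grid
#'
#' C in \{1, 10, 100, 1000, 10000\} and gamma in
#' \{1e-4, 1e-3, 1e-2, 1e-1, 1\}; contains (C = 1000, gamma = 0.001).
#'
#' @return list with `cost` and `gamma` vectors.
#' @export
default_svm_grid <- function() {
  list(cost = c(1, 10, 100, 1000, 10000),
       gamma = c(1e-4, 1e-3, 1e-2, 1e-1, 1))
}

#' Couple-grouped fold assignment
#'
#' Partitions samples into `n_folds` cross-validation folds such that both
#' samples of a couple (26-week and 2-year outcomes) always share a fold;
#' fold sizes are balanced within one couple. The draw is re-attempted (up
#' to `max_tries`) until every training split contains every class present
#' in the data.
#'
#' @param couple_ids character vector, one entry per sample.
#' @param y class labels, one per sample.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed.
#' @param max_tries redraw limit for the class-presence check.
#' @return integer fold id per sample.
#' @export
make_grouped_folds <- function(couple_ids, y, n_folds = 10L, seed = NULL,
                               max_tries = 100L) {
  couples <- unique(couple_ids)
  if (n_folds > length(couples))
    dv_stop("dyadvox_config_error", "n_folds = %d exceeds %d couples",
            n_folds, length(couples))
  classes <- sort(unique(y))
  for (try in seq_len(max_tries)) {
    perm <- with_seed(if (is.null(seed)) NULL else seed + (try - 1L) * 7919L,
                      sample(couples))
    fold_of_couple <- stats::setNames(rep(seq_len(n_folds),
                                          length.out = length(couples)), perm)
    folds <- unname(fold_of_couple[couple_ids])
    ok <- all(vapply(seq_len(n_folds), function(f)
      all(classes %in% y[folds != f]), logical(1)))
    if (ok) return(as.integer(folds))
  }
  dv_stop("dyadvox_stratification_error",
          "could not build folds with all classes in every training split")
}

# Plain per-sample folds (inner CV), round-robin within class.
simple_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

#' Median imputation fit on the training split only
#'
#' @param train,test numeric matrices (columns = features).
#' @return list with imputed `train`, `test`, the medians, and `fitted_on`
#'   (the training row names, recorded for leakage audits).
#' @export
impute_fit_apply <- function(train, test = NULL) {
  med <- apply(train, 2L, function(col) {
    m <- stats::median(col[is.finite(col)])
    if (!is.finite(m)) 0 else m
  })
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      bad <- !is.finite(m[, j])
      if (any(bad)) m[bad, j] <- med[j]
    }
    m
  }
  list(train = fill(train), test = if (!is.null(test)) fill(test),
       medians = med, fitted_on = rownames(train))
}

#' Feature z-normalization fit on the training split only
#'
#' Per-feature mean and SD are estimated from the training matrix and
#' applied to both matrices; zero-SD features map to 0 everywhere.
#'
#' @param train,test numeric matrices.
#' @return list with scaled `train`, `test`, `center`, `scale`, and
#'   `fitted_on` (training row names, for leakage audits).
#' @export
normalize_fit_apply <- function(train, test = NULL) {
  center <- colMeans(train)
  scale <- apply(train, 2L, stats::sd)
  scale_eff <- ifelse(is.finite(scale) & scale > 0, scale, Inf)
  tf <- function(m) sweep(sweep(m, 2L, center), 2L, scale_eff, `/`)
  list(train = tf(train), test = if (!is.null(test)) tf(test),
       center = center, scale = scale, fitted_on = rownames(train))
}

# ---- one-against-all RBF SVM ------------------------------------------

# decision values for the first-named class of an e1071 binary model,
# robust to libsvm's label-appearance ordering.
decision_for <- function(model, x, positive) {
  p <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  lab <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  if (lab[1] == positive) dv[, 1] else -dv[, 1]
}

svm_ova_train <- function(x, y, cost, gamma) {
  classes <- sort(unique(y))
  models <- lapply(classes, function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(x, yb, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE)
  })
  structure(list(classes = classes, models = models,
                 cost = cost, gamma = gamma), class = "svm_ova")
}

#' @export
predict.svm_ova <- function(object, newdata, ...) {
  dv <- vapply(seq_along(object$classes), function(k)
    decision_for(object$models[[k]], newdata, "pos"),
    numeric(nrow(newdata)))
  dv <- matrix(dv, nrow = nrow(newdata))
  # margin-argmax; ties toward the lowest class rating
  pick <- apply(dv, 1L, function(row) which(row == max(row))[1])
  object$classes[pick]
}

cv_accuracy <- function(X, y, folds, cost, gamma) {
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    m <- svm_ova_train(X[tr, , drop = FALSE], y[tr], cost, gamma)
    mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Inner k-fold cross-validation accuracy over the (C, gamma) grid on the
#' training split; ties resolve to the smallest C, then the smallest gamma.
#' If the inner split leaves a training fold without all classes, the search
#' falls back to 3 folds.
#'
#' @param X training matrix (normalized).
#' @param y training labels (>= 2 classes).
#' @param grid list with `cost` and `gamma` candidate vectors
#'   (deduplicated; default [default_svm_grid()]).
#' @param inner_folds inner CV folds (default 5).
#' @param seed RNG seed for the inner split.
#' @return list with `cost`, `gamma`, and the inner `accuracy` matrix.
#' @export
grid_search_svm <- function(X, y, grid = default_svm_grid(),
                            inner_folds = 5L, seed = NULL) {
  if (length(unique(y)) < 2L)
    dv_stop("dyadvox_input_error", "grid search needs >= 2 classes")
  costs <- sort(unique(grid$cost))
  gammas <- sort(unique(grid$gamma))
  if (length(costs) == 0L || length(gammas) == 0L)
    dv_stop("dyadvox_config_error", "empty hyperparameter grid")
  folds <- with_seed(seed, simple_folds(y, inner_folds))
  degen <- any(vapply(unique(folds), function(f)
    length(unique(y[folds != f])) < 2L, logical(1)))
  if (degen) {
    dv_log("grid_search_svm: degenerate inner folds; falling back to 3")
    folds <- with_seed(seed, simple_folds(y, 3L))
  }
  acc <- matrix(NA_real_, length(costs), length(gammas),
                dimnames = list(costs, gammas))
  for (i in seq_along(costs))
    for (j in seq_along(gammas))
      acc[i, j] <- cv_accuracy(X, y, folds, costs[i], gammas[j])
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(cost = costs[best[1]], gamma = gammas[best[2]], accuracy = acc)
}

#' Run one classification experiment with couple-grouped cross-validation
#'
#' For each of `n_folds` outer folds (couple-grouped): median imputation,
#' z-normalization, MIM feature selection with the number of features chosen
#' by inner cross-validation, hyperparameter grid search, training, and
#' prediction of the held-out fold -- every statistic fitted on the training
#' split only. Returns pooled out-of-fold predictions with per-fold
#' accuracies and an audit trail of which sample ids each fitted statistic
#' touched.
#'
#' @param corpus a `dyad_corpus`.
#' @param feature_set one of `"codes"`, `"static"`, `"dynamic"`,
#'   `"acoustic_all"`, `"all"`.
#' @param experiment experiment id (1, 2, 3) or an [experiment_spec()].
#' @param seed RNG seed governing fold assignment, inner splits and grid
#'   search.
#' @param features optional precomputed feature matrix (rows = sample ids)
#'   to avoid re-assembly.
#' @param n_folds outer folds (default 10).
#' @param grid hyperparameter grid (default [default_svm_grid()]).
#' @param k_grid candidate selected-feature counts (default 5-25% of the
#'   dimension).
#' @param bins MIM discretization bins.
#' @return a `cv_result`: list with `predictions`, `truth` (named by sample
#'   id), `fold` assignment, `fold_stats` (per-fold accuracy/F-score),
#'   `audit`, `experiment`, `feature_set`.
#' @export
run_experiment <- function(corpus, feature_set = "static", experiment = 1L,
                           seed = 1L, features = NULL, n_folds = 10L,
                           grid = default_svm_grid(), k_grid = NULL,
                           bins = 10L) {
  spec <- if (is.list(experiment)) experiment else experiment_spec(experiment)
  ratings <- corpus_ratings(corpus)
  keep <- spec$domain(ratings)
  ids <- names(ratings)[keep]
  y <- spec$map(ratings[keep])
  couple_ids <- vapply(corpus$samples, `[[`, "", "couple_id")[keep]
  if (is.null(features)) features <- assemble_feature_matrix(corpus, feature_set)
  X <- features[ids, , drop = FALSE]

  folds <- make_grouped_folds(couple_ids, y, n_folds, seed = seed)
  preds <- stats::setNames(rep(NA_integer_, length(y)), ids)
  audit <- vector("list", n_folds)
  model_info <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    if (!any(te)) { audit[[f]] <- list(empty = TRUE); next }
    sub_seed <- seed + f * 131L
    imp <- impute_fit_apply(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    nrm <- normalize_fit_apply(imp$train, imp$test)
    scores <- mim_scores(nrm$train, y[tr], bins = bins)
    ksel <- choose_k_by_cv(nrm$train, y[tr], k_grid = k_grid, scores = scores,
                           seed = sub_seed)
    sel <- select_top_k(scores, ksel$k)
    Xtr <- nrm$train[, sel, drop = FALSE]
    Xte <- nrm$test[, sel, drop = FALSE]
    gs <- grid_search_svm(Xtr, y[tr], grid = grid, seed = sub_seed + 1L)
    model <- svm_ova_train(Xtr, y[tr], gs$cost, gs$gamma)
    preds[te] <- predict(model, Xte)
    audit[[f]] <- list(
      train_ids = ids[tr], test_ids = ids[te],
      stats_fitted_on = unique(c(imp$fitted_on, nrm$fitted_on, ids[tr])))
    model_info[[f]] <- list(k = ksel$k, cost = gs$cost, gamma = gs$gamma)
  }

  res <- structure(list(predictions = preds, truth = stats::setNames(y, ids),
                        fold = stats::setNames(folds, ids),
                        audit = audit, model_info = model_info,
                        experiment = spec$id, feature_set = feature_set,
                        seed = seed),
                   class = "cv_result")
  res$fold_stats <- per_fold_stats(res)
  res
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- accuracy_summary(x)
  cat(sprintf("<cv_result: experiment %d, %s features, %d samples>\n",
              x$experiment, x$feature_set, length(x$truth)))
  cat(sprintf("  accuracy %.1f%% (SD %.1f) over %d folds\n",
              acc[["mean"]], acc[["sd"]], length(unique(x$fold))))
  invisible(x)
}
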