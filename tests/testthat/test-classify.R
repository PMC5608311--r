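test_that("grouped folds keep couples together and are reproducible", {
  couple_ids <- rep(sprintf("C%02d", 1:15), c(rep(2, 10), rep(1, 5)))
  y <- rep(c(0, 1), length.out = length(couple_ids))
  f1 <- make_grouped_folds(couple_ids, y, n_folds = 5, seed = 3)
  f2 <- make_grouped_folds(couple_ids, y, n_folds = 5, seed = 3)
  expect_identical(f1, f2)
  for (cid in unique(couple_ids))
    expect_length(unique(f1[couple_ids == cid]), 1L)
  # every training split sees both classes
  for (f in 1:5) expect_setequal(unique(y[f1 != f]), c(0, 1))

  # 10 couples, 10 folds: one couple per fold
  f3 <- make_grouped_folds(sprintf("C%02d", 1:10), rep(0:1, 5),
                           n_folds = 10, seed = 1)
  expect_equal(sort(unname(f3)), 1:10)

  expect_error(make_grouped_folds(c("A", "B"), c(0, 1), n_folds = 5),
               class = "dyadvox_config_error")
})

test_that("normalization fits on the training split only", {
  tr <- matrix(c(2, 4, 1, 1), 2, 2,
               dimnames = list(c("s1", "s2"), NULL))
  te <- matrix(c(3, 9), 1, 2)
  nm <- normalize_fit_apply(tr, te)
  expect_equal(unname(nm$train[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(nm$test[1, 1]), 0)           # (3 - 3)/sd
  expect_true(all(nm$train[, 2] == 0))             # constant column
  expect_true(all(nm$test[, 2] == 0))
  expect_identical(nm$fitted_on, c("s1", "s2"))
  # rescaling by the stored parameters is the identity on train
  back <- sweep(sweep(nm$train, 2, ifelse(nm$scale > 0, nm$scale, 1), `*`),
                2, nm$center, `+`)
  expect_equal(unname(back), unname(tr), tolerance = 1e-12)
})

test_that("median imputation uses training medians", {
  tr <- matrix(c(1, 3, NA, 10, 20, 30), 3, 2)
  te <- matrix(c(NA, NA), 1, 2)
  im <- impute_fit_apply(tr, te)
  expect_equal(unname(im$train[3, 1]), 2)
  expect_equal(unname(im$test[1, ]), c(2, 20))
})

test_that("grid search separates Gaussian blobs and resolves ties lawfully", {
  set.seed(41)
  X <- rbind(matrix(rnorm(60 * 2), 60, 2), matrix(rnorm(60 * 2, 4), 60, 2))
  y <- rep(0:1, each = 60)
  gs <- grid_search_svm(X, y, seed = 2)
  expect_gte(max(gs$accuracy), 0.95)

  dup <- list(cost = c(10, 10, 1), gamma = c(0.1, 0.1))
  gs2 <- grid_search_svm(X, y, grid = dup, seed = 2)
  gs3 <- grid_search_svm(X, y, grid = list(cost = c(1, 10), gamma = 0.1),
                         seed = 2)
  expect_equal(gs2[c("cost", "gamma")], gs3[c("cost", "gamma")])

  grid <- default_svm_grid()
  expect_true(1000 %in% grid$cost && 0.001 %in% grid$gamma)
  expect_error(grid_search_svm(X, y, grid = list(cost = numeric(0),
                                                 gamma = 0.1)),
               class = "dyadvox_config_error")
})

test_that("one-against-all prediction covers multiclass with low-rating ties", {
  set.seed(42)
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(40 * 2, sd = 0.5), 40, 2), 2, centers[k, ], `+`)))
  y <- rep(1:3, each = 40)
  m <- dyadvox:::svm_ova_train(X, y, cost = 10, gamma = 0.5)
  expect_gte(mean(predict(m, X) == y), 0.95)
})

test_that("a leaked class-coded feature is found and exploited perfectly", {
  sim <- simulate_feature_corpus(sim_config(n_couples = 30, effect_size = 0),
                                 seed = 8)
  spec <- experiment_spec(1)
  m <- assemble_feature_matrix(sim$corpus, "codes")
  leak <- spec$map(corpus_ratings(sim$corpus))
  m2 <- cbind(m, leak_feature = leak + 0)
  res <- run_experiment(sim$corpus, "codes", 1, seed = 2, features = m2,
                        n_folds = 5, grid = fast_grid(), k_grid = c(5, 20))
  expect_equal(unname(accuracy_summary(res)[["mean"]]), 100)
})

test_that("experiments produce leak-free, complete out-of-fold predictions", {
  sim <- shared_sim()
  m <- assemble_feature_matrix(sim$corpus, "codes")
  res <- run_experiment(sim$corpus, "codes", 1, seed = 7, features = m,
                        n_folds = 5, grid = fast_grid(), k_grid = c(10, 30))
  expect_false(any(is.na(res$predictions)))
  expect_identical(names(res$predictions), names(res$truth))
  for (a in res$audit) {
    expect_length(intersect(a$stats_fitted_on, a$test_ids), 0L)
    expect_setequal(c(a$train_ids, a$test_ids), names(res$truth))
  }
  # determinism
  res2 <- run_experiment(sim$corpus, "codes", 1, seed = 7, features = m,
                         n_folds = 5, grid = fast_grid(), k_grid = c(10, 30))
  expect_identical(res$predictions, res2$predictions)
})

test_that("experiment 2's domain is exactly experiment 1's negative class", {
  sim <- shared_sim()
  r <- corpus_ratings(sim$corpus)
  s1 <- experiment_spec(1); s2 <- experiment_spec(2)
  neg1 <- names(r)[s1$map(r) == 0 & s1$domain(r)]
  dom2 <- names(r)[s2$domain(r)]
  expect_setequal(neg1, dom2)
  expect_error(experiment_spec(9), class = "dyadvox_config_error")
})
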