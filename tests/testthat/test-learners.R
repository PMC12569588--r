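test_that("default grids expose the documented hyperparameter space", {
  expect_equal(default_grid("knn"), list(n_neighbors = c(25, 75, 125)))
  expect_equal(default_grid("logistic_regression"),
               list(C = c(0.0001, 1, 10), penalty = c("l1", "l2")))
  expect_equal(default_grid("random_forest"),
               list(n_estimators = c(100, 200),
                    min_samples_leaf = c(1, 10, 50),
                    max_samples = c(0.75, 1.0)))
  expect_equal(nrow(ppmcc:::grid_points(learner_spec("random_forest"))), 12)
})

make_blobs <- function(n, p = 4, seed = 1) {
  # two well-separated gaussian blobs: linearly separable
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * p), n, p) + 2.5 * y
  list(x = x, y = as.integer(y))
}

test_that("all three families learn a separable problem", {
  d <- make_blobs(120, seed = 2)
  d_test <- make_blobs(60, seed = 3)
  for (fam in c("knn", "logistic_regression", "random_forest")) {
    params <- fixed_grid(fam)
    params$n_neighbors <- 5 # feasible for the small training set
    m <- fit_learner(fam, params, d$x, d$y, seed = 1)
    acc <- mean(predict(m, d_test$x) == d_test$y)
    expect_gt(acc, 0.9)
  }
  # determinism of the seeded forest
  m1 <- fit_learner("random_forest", fixed_grid("random_forest"), d$x, d$y, seed = 9)
  m2 <- fit_learner("random_forest", fixed_grid("random_forest"), d$x, d$y, seed = 9)
  expect_identical(predict(m1, d_test$x), predict(m2, d_test$x))
})

test_that("random forest respects min_samples_leaf smoothing", {
  d <- make_blobs(200, seed = 4)
  deep <- random_forest(d$x, d$y, n_estimators = 20, min_samples_leaf = 1,
                        seed = 1)
  stump <- random_forest(d$x, d$y, n_estimators = 20, min_samples_leaf = 100,
                         seed = 1)
  n_nodes <- function(m) mean(vapply(m$forest, function(t) length(t$feature),
                                     integer(1)))
  expect_gt(n_nodes(deep), n_nodes(stump))
})

test_that("grid_search agrees with brute-force re-scoring", {
  d <- make_blobs(120, seed = 5)
  folds <- random_folds(120, k = 3, seed = 5)
  spec <- learner_spec("logistic_regression")
  res <- grid_search(spec, folds, d$x, d$y, criterion = "mcc", seed = 5)

  # independent oracle: refit every grid point on every fold and average
  pts <- expand.grid(C = c(0.0001, 1, 10), penalty = c("l1", "l2"),
                     stringsAsFactors = FALSE)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    mean(vapply(folds, function(f) {
      m <- fit_learner("logistic_regression", as.list(pts[i, ]),
                       d$x[f$train, ], d$y[f$train])
      cm <- confusion_counts(d$y[f$valid], predict(m, d$x[f$valid, ]))
      mcc(cm)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$scores$mean_score, oracle, tolerance = 1e-12)
  expect_equal(res$best_index, which.max(oracle))
  expect_equal(unname(unlist(res$best)),
               unname(unlist(pts[which.max(oracle), ])))
})

test_that("grid_search handles single points, infeasible points, degeneracy", {
  d <- make_blobs(40, seed = 6)
  folds <- random_folds(40, k = 2, seed = 6)

  single <- grid_search(learner_spec("knn", grid = list(n_neighbors = 3)),
                        folds, d$x, d$y)
  expect_equal(single$best$n_neighbors, 3)
  expect_false(anyNA(single$scores$mean_score)) # scores actually computed

  expect_warning(
    res <- grid_search(learner_spec("knn", grid = list(n_neighbors = c(3, 1000))),
                       folds, d$x, d$y),
    "skipped")
  expect_equal(res$best$n_neighbors, 3)
  expect_true(is.na(res$scores$mean_score[2]))

  # one degenerate inner fold -> warning but a usable result
  y_deg <- d$y
  bad_folds <- list(list(train = which(d$y == 1)[1:10], valid = 1:10),
                    folds[[1]])
  expect_warning(ok <- grid_search(learner_spec("knn", grid = list(n_neighbors = 3)),
                                   bad_folds, d$x, y_deg),
                 "single-class")
  expect_equal(ok$scores$n_folds_used, 1L)

  all_bad <- list(list(train = which(d$y == 1)[1:10], valid = 1:10))
  expect_error(grid_search(learner_spec("knn", grid = list(n_neighbors = 3)),
                           all_bad, d$x, y_deg),
               "single-class")
})

test_that("fit_predict_outer covers each interaction once and spots leakage", {
  g <- small_world(40, 240, seed = 44)
  ds <- g$dataset
  y <- ds$interactions$label
  # leaked design: the label is a feature
  x <- cbind(y, rnorm(length(y)))
  plan <- make_plan(ds, "random", k_outer = 3, k_inner = 0, seed = 44)
  rf_grid <- c(fixed_grid("random_forest"), list(mtry = 2)) # see both features
  preds <- fit_predict_outer(plan,
                             learner_spec("random_forest", grid = rf_grid),
                             x, y, ds, seed = 44)
  expect_s3_class(preds, "prediction_set")
  expect_equal(sort(preds$index), seq_len(n_interactions(ds)))
  expect_equal(mean(preds$pred == preds$truth), 1.0)
  expect_equal(sort(unique(preds$fold)), 1:3)

  # grid search engaged when the plan has inner folds and a multi-point grid
  plan2 <- make_plan(ds, "random", k_outer = 2, k_inner = 2, seed = 45)
  preds2 <- fit_predict_outer(plan2,
                              learner_spec("knn", grid = list(n_neighbors = c(1, 5))),
                              x, y, ds, seed = 45)
  expect_length(attr(preds2, "chosen"), 2)
  expect_true(all(vapply(attr(preds2, "chosen"),
                         function(p) p$n_neighbors %in% c(1, 5), logical(1))))
})

test_that("random labels score near zero pooled MCC", {
  g <- generate_dataset(bias_spec(n_proteins = 100, n_interactions = 400,
                                  frac_pure = 0, beta_a = 1000, beta_b = 1000,
                                  seed = 46)) # labels ~ fair coin flips
  ds <- g$dataset
  emb <- generate_embeddings(ds$proteins, "identity", dim = 8, seed = 46)
  des <- build_design(ds, emb, "concat")
  plan <- make_plan(ds, "random", k_outer = 3, k_inner = 0, seed = 46)
  preds <- fit_predict_outer(plan,
                             learner_spec("knn", grid = list(n_neighbors = 25)),
                             des$x, des$y, ds, seed = 46)
  # permutation-null band: sd(MCC) ~ 1/sqrt(n), n = 400 -> 4 sd = 0.2
  expect_lt(abs(mcc_of(preds)), 0.2)
})

test_that("positivity baseline matches hand-derived predictions", {
  b <- baseline_fit(toy6_dataset(), mode = "single_item")
  # training positivities: A 1/3, B 1, C 1/3, D 1/3; global 0.5
  expect_equal(unname(b$positivity[c("A", "B", "C", "D")]),
               c(1 / 3, 1, 1 / 3, 1 / 3))
  expect_equal(b$global, 0.5)

  held_out <- data.frame(protein_a = c("B", "A", "E"),
                         protein_b = c("A", "B", "F"))
  # B leads -> 1 > 0.5 positive; A leads -> 1/3 negative;
  # both unseen -> global 0.5, tie -> negative
  expect_equal(baseline_predict(b, held_out), c(1L, 0L, 0L))

  bp <- baseline_fit(toy6_dataset(), mode = "pair_mean")
  # (B,A): (1 + 1/3)/2 = 2/3 -> positive; (A,C): 1/3 -> negative
  expect_equal(baseline_predict(bp, data.frame(protein_a = c("B", "A"),
                                               protein_b = c("A", "C"))),
               c(1L, 0L))

  # pure-positive protein leads every pair to a positive call
  expect_equal(baseline_predict(b, data.frame(protein_a = rep("B", 3),
                                              protein_b = c("C", "D", "Q"))),
               rep(1L, 3))
})

test_that("single_item baseline is constant per first protein", {
  g <- small_world(40, 240, seed = 47)
  plan <- make_plan(g$dataset, "random", k_outer = 3, k_inner = 0, seed = 47)
  preds <- baseline_fit_predict_outer(plan, g$dataset, mode = "single_item")
  per_first <- split(preds$pred, paste(preds$protein_a, preds$fold))
  expect_true(all(vapply(per_first, function(v) length(unique(v)) == 1,
                         logical(1))))
})
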