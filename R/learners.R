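#' Learner families and hyperparameter grids
#'
#' Three classical classifier families are provided, with default grids
#' matching the nested-CV protocol used at benchmark scale:
#'
#' * `knn`: `n_neighbors` in \{25, 75, 125\} (backed by FNN neighbour
#'   search; majority vote, ties predict negative).
#' * `logistic_regression`: `C` in \{0.0001, 1, 10\} crossed with `penalty`
#'   in \{l1, l2\} (backed by glmnet with `lambda = 1/(C * n)`,
#'   `alpha = 1` for l1 / `0` for l2, no standardisation — the coordinate
#'   -descent analogue of the scikit-learn objective the grid refers to).
#' * `random_forest`: `n_estimators` in \{100, 200\}, `min_samples_leaf`
#'   in \{1, 10, 50\}, `max_samples` in \{0.75, 1.0\}
#'   (see [random_forest()]).
#'
#' @param family one of `"knn"`, `"logistic_regression"`, `"random_forest"`.
#' @return `default_grid()`: named list of parameter value vectors.
#' @export
default_grid <- function(family = c("knn", "logistic_regression", "random_forest")) {
  family <- match.arg(family)
  switch(family,
         knn = list(n_neighbors = c(25, 75, 125)),
         logistic_regression = list(C = c(0.0001, 1, 10),
                                    penalty = c("l1", "l2")),
         random_forest = list(n_estimators = c(100, 200),
                              min_samples_leaf = c(1, 10, 50),
                              max_samples = c(0.75, 1.0)))
}

#' @param grid named list of parameter value vectors (defaults to the
#'   family's [default_grid()]); a single-value-per-parameter grid fixes the
#'   hyperparameters and disables tuning.
#' @rdname default_grid
#' @return `learner_spec()`: an object of class `learner_spec`.
#' @export
learner_spec <- function(family = c("knn", "logistic_regression", "random_forest"),
                         grid = NULL) {
  family <- match.arg(family)
  grid <- grid %||% default_grid(family)
  stopifnot(is.list(grid), length(grid) >= 1, all(lengths(grid) >= 1),
            !is.null(names(grid)), all(nzchar(names(grid))))
  structure(list(family = family, grid = grid), class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec> %s, %d grid point(s)\n", x$family,
              nrow(grid_points(x))))
  invisible(x)
}

# Full grid as a data.frame, one row per configuration; row order is the
# documented tie-break order (first row wins).
grid_points <- function(spec) {
  expand.grid(spec$grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

infeasible_error <- function(msg) {
  stop(errorCondition(msg, class = c("ppmcc_infeasible", "error", "condition")))
}

#' Fit one learner configuration
#'
#' Low-level fit/predict pair behind [grid_search()] and
#' [fit_predict_outer()].  `fit_learner()` returns an object of class
#' `fitted_ppi_model` whose `predict` method maps a feature matrix to hard
#' 0/1 labels.
#'
#' @param family learner family, see [default_grid()].
#' @param params named list (or one-row data.frame) of hyperparameters.
#' @param x numeric feature matrix.
#' @param y integer 0/1 labels.
#' @param seed integer seed (used by the random-forest family).
#' @return A `fitted_ppi_model`.
#' @export
fit_learner <- function(family, params, x, y, seed = 1) {
  params <- as.list(params)
  y <- as.integer(y)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2) {
    infeasible_error("degenerate training set: single class")
  }
  fit <- switch(
    family,
    knn = {
      k <- as.integer(params$n_neighbors)
      if (k > nrow(x)) {
        infeasible_error(sprintf(
          "n_neighbors = %d exceeds training size %d", k, nrow(x)))
      }
      list(x = x, y = y, k = k)
    },
    logistic_regression = {
      alpha <- switch(as.character(params$penalty), l1 = 1, l2 = 0,
                      stop("unknown penalty: ", params$penalty))
      lambda <- 1 / (params$C * nrow(x))
      glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                     lambda = lambda, standardize = FALSE)
    },
    random_forest = random_forest(
      x, y,
      n_estimators = params$n_estimators %||% 100,
      min_samples_leaf = params$min_samples_leaf %||% 1,
      max_samples = params$max_samples %||% 1.0,
      mtry = params$mtry, seed = seed),
    stop("unknown learner family: ", family)
  )
  structure(list(family = family, params = params, fit = fit, seed = seed),
            class = "fitted_ppi_model")
}

#' @param object a `fitted_ppi_model`.
#' @param newdata numeric feature matrix.
#' @param ... ignored.
#' @rdname fit_learner
#' @export
predict.fitted_ppi_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  switch(
    object$family,
    knn = {
      f <- object$fit
      nn <- FNN::knnx.index(f$x, newdata, k = f$k)
      votes <- matrix(f$y[nn], nrow = nrow(newdata))
      as.integer(2L * rowSums(votes) > f$k) # tie -> negative
    },
    logistic_regression = {
      as.integer(predict(object$fit, newdata, type = "response")[, 1] > 0.5)
    },
    random_forest = predict(object$fit, newdata)
  )
}

#' Inner-CV grid search
#'
#' Scores every grid configuration by its mean criterion over the inner
#' validation folds and returns the best one; ties are broken by grid order
#' (first wins).  An inner fold whose training rows contain a single class
#' is skipped with a warning; a configuration that is infeasible on some
#' fold (e.g. more neighbours than training rows) is skipped entirely, with
#' a warning.  If no configuration can be scored the search fails.
#'
#' @param spec a [learner_spec()].
#' @param inner_folds list of folds (`train` / `valid` row indices of `x`).
#' @param x,y feature matrix and 0/1 labels the indices refer to.
#' @param criterion `"mcc"` (default, consistent with the evaluation
#'   metric) or `"accuracy"`.
#' @param seed integer seed.
#' @return List with `best` (named list of parameters), `best_index` (row
#'   in the score table), `scores` (data.frame: one row per configuration
#'   with its parameters, `mean_score`, `n_folds_used`), `criterion`.
#' @export
grid_search <- function(spec, inner_folds, x, y,
                        criterion = c("mcc", "accuracy"), seed = 1) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(spec, "learner_spec"), length(inner_folds) >= 1)
  y <- as.integer(y)
  pts <- grid_points(spec)

  degenerate <- vapply(inner_folds, function(f) {
    length(unique(y[f$train])) < 2
  }, logical(1))
  if (all(degenerate)) {
    stop("all inner folds have single-class training sets; cannot tune")
  }
  if (any(degenerate)) {
    warning(sum(degenerate), " inner fold(s) skipped: single-class training set")
  }
  usable <- which(!degenerate)

  score_one <- function(cfg_i, fold_i) {
    f <- inner_folds[[fold_i]]
    model <- fit_learner(spec$family, pts[cfg_i, , drop = FALSE],
                         x[f$train, , drop = FALSE], y[f$train],
                         seed = derive_seed(seed, cfg_i * 1000L + fold_i))
    pred <- predict(model, x[f$valid, , drop = FALSE])
    truth <- y[f$valid]
    if (criterion == "accuracy") {
      mean(pred == truth)
    } else {
      mcc(confusion_counts(truth, pred))
    }
  }

  mean_score <- rep(NA_real_, nrow(pts))
  n_used <- integer(nrow(pts))
  for (ci in seq_len(nrow(pts))) {
    scores <- numeric(0)
    feasible <- TRUE
    for (fi in usable) {
      s <- tryCatch(score_one(ci, fi),
                    ppmcc_infeasible = function(e) e)
      if (inherits(s, "condition")) {
        warning("grid point ", ci, " (", paste(names(pts),
                unlist(pts[ci, ]), sep = "=", collapse = ", "),
                ") skipped: ", conditionMessage(s))
        feasible <- FALSE
        break
      }
      scores <- c(scores, s)
    }
    if (feasible) {
      mean_score[ci] <- mean(scores)
      n_used[ci] <- length(scores)
    }
  }
  if (all(is.na(mean_score))) {
    stop("no feasible grid configuration could be scored")
  }
  best_index <- which.max(mean_score) # NA-safe: which.max ignores NA
  out <- cbind(pts, mean_score = mean_score, n_folds_used = n_used)
  list(best = as.list(pts[best_index, , drop = FALSE]),
       best_index = best_index, scores = out, criterion = criterion)
}

#' Nested cross-validated fit and predict
#'
#' For each outer fold of the plan: tune hyperparameters on the fold's
#' inner folds with [grid_search()] (skipped when the plan has no inner
#' folds or the grid has a single point — the first grid point is then
#' used), refit the chosen configuration on the full outer training set,
#' and predict the outer validation set.  All validation predictions are
#' pooled into one prediction set tagged by fold, the input the evaluation
#' metrics ([mcc_of()], [pp_mcc()]) consume.
#'
#' @param plan a [make_plan()] fold plan.
#' @param spec a [learner_spec()].
#' @param x,y design matrix and 0/1 labels, rows aligned with `ds`.
#' @param ds the [ppi_dataset] the plan was built on.
#' @param criterion inner-CV selection criterion, see [grid_search()].
#' @param seed integer seed.
#' @return A [prediction_set()] covering every outer validation
#'   interaction, with attribute `chosen` (per-fold selected parameters).
#' @export
fit_predict_outer <- function(plan, spec, x, y, ds,
                              criterion = c("mcc", "accuracy"), seed = 1) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(plan, "fold_plan"), inherits(spec, "learner_spec"),
            inherits(ds, "ppi_dataset"),
            nrow(x) == n_interactions(ds), length(y) == nrow(x))
  y <- as.integer(y)
  int <- ds$interactions
  pts <- grid_points(spec)
  records <- vector("list", length(plan$outer))
  chosen <- vector("list", length(plan$outer))

  for (i in seq_along(plan$outer)) {
    f <- plan$outer[[i]]
    params <- if (length(plan$inner[[i]]) >= 1 && nrow(pts) > 1) {
      grid_search(spec, plan$inner[[i]], x, y, criterion = criterion,
                  seed = derive_seed(seed, i))$best
    } else {
      as.list(pts[1, , drop = FALSE])
    }
    chosen[[i]] <- params
    model <- fit_learner(spec$family, params,
                         x[f$train, , drop = FALSE], y[f$train],
                         seed = derive_seed(seed, i))
    pred <- predict(model, x[f$valid, , drop = FALSE])
    records[[i]] <- data.frame(index = f$valid,
                               protein_a = int$protein_a[f$valid],
                               protein_b = int$protein_b[f$valid],
                               truth = y[f$valid],
                               pred = as.integer(pred),
                               fold = i)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  class(out) <- c("prediction_set", "data.frame")
  attr(out, "chosen") <- chosen
  out
}

#' Positivity-prior baseline
#'
#' A deliberately biology-free reference model that predicts a pair's label
#' from the training positivity (fraction of positive interactions) of its
#' member proteins — the bias a skewed dataset lets real models exploit.
#' Two modes:
#'
#' * `single_item`: positive iff the *first* protein's training positivity
#'   exceeds the threshold.  For a fixed first protein the prediction is
#'   constant, so a per-protein evaluation restricted to first-protein
#'   submatrices scores it at exactly 0 — the behaviour the per-protein
#'   metric is designed to expose.
#' * `pair_mean`: positive iff the mean of both proteins' positivities
#'   exceeds the threshold.
#'
#' A protein unseen in training falls back to the global training
#' positivity.  Exact-threshold ties predict negative.
#'
#' @param train a [ppi_dataset] of training interactions.
#' @param mode `"single_item"` or `"pair_mean"`.
#' @param threshold decision threshold (default 0.5).
#' @return An object of class `positivity_baseline`.
#' @export
baseline_fit <- function(train, mode = c("single_item", "pair_mean"),
                         threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "ppi_dataset"))
  s <- ppi_summary(train)
  positivity <- s$protein_stats$positivity
  names(positivity) <- s$protein_stats$protein
  structure(list(positivity = positivity,
                 global = s$n_positive / s$n_interactions,
                 mode = mode, threshold = threshold),
            class = "positivity_baseline")
}

#' @param b a `positivity_baseline`.
#' @param pairs data.frame with character columns `protein_a`, `protein_b`
#'   (extra columns ignored), or a [ppi_dataset].
#' @rdname baseline_fit
#' @return `baseline_predict()`: integer 0/1 vector, one per pair.
#' @export
baseline_predict <- function(b, pairs) {
  stopifnot(inherits(b, "positivity_baseline"))
  if (inherits(pairs, "ppi_dataset")) pairs <- pairs$interactions
  lookup <- function(p) {
    v <- b$positivity[p]
    v[is.na(v)] <- b$global
    unname(v)
  }
  score <- switch(b$mode,
                  single_item = lookup(pairs$protein_a),
                  pair_mean = (lookup(pairs$protein_a) + lookup(pairs$protein_b)) / 2)
  as.integer(score > b$threshold)
}

#' Cross-validated baseline predictions
#'
#' Runs the positivity baseline through the outer folds of a plan: fit on
#' each fold's training interactions, predict its validation interactions,
#' pool everything into a prediction set (the baseline has no
#' hyperparameters, so inner folds are ignored).
#'
#' @inheritParams fit_predict_outer
#' @param mode,threshold see [baseline_fit()].
#' @return A [prediction_set()].
#' @export
baseline_fit_predict_outer <- function(plan, ds,
                                       mode = c("single_item", "pair_mean"),
                                       threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "fold_plan"), inherits(ds, "ppi_dataset"))
  int <- ds$interactions
  records <- lapply(seq_along(plan$outer), function(i) {
    f <- plan$outer[[i]]
    b <- baseline_fit(ppi_dataset(int[f$train, , drop = FALSE]),
                      mode = mode, threshold = threshold)
    data.frame(index = f$valid,
               protein_a = int$protein_a[f$valid],
               protein_b = int$protein_b[f$valid],
               truth = int$label[f$valid],
               pred = baseline_predict(b, int[f$valid, , drop = FALSE]),
               fold = i)
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  class(out) <- c("prediction_set", "data.frame")
  out
}
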