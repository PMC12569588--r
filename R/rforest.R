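#' Random-forest classifier (built-in implementation)
#'
#' Bagged CART trees with gini splitting and per-node feature subsampling,
#' implemented in C++ because no tree learner is available among the
#' package's allowed dependencies.  Parameterisation follows the common
#' scikit-learn convention: `n_estimators` trees, each grown on
#' `round(max_samples * n)` bootstrap draws with replacement, leaves holding
#' at least `min_samples_leaf` node samples, `mtry = floor(sqrt(p))`
#' features considered per split by default.  Tree growth is deterministic
#' given `seed`; prediction is a majority vote (ties predict negative).
#'
#' @param x numeric feature matrix.
#' @param y integer labels (0/1).
#' @param n_estimators number of trees.
#' @param min_samples_leaf minimum node sample count in a leaf.
#' @param max_samples bootstrap fraction in (0, 1].
#' @param mtry features considered per split (default `floor(sqrt(ncol(x)))`).
#' @param max_depth depth cap.
#' @param seed integer seed.
#' @return An object of class `ppmcc_rf` with a `predict` method taking a
#'   feature matrix and returning 0/1 labels.
#' @export
random_forest <- function(x, y, n_estimators = 100, min_samples_leaf = 1,
                          max_samples = 1.0, mtry = NULL, max_depth = 30,
                          seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y %in% c(0L, 1L)),
            n_estimators >= 1, min_samples_leaf >= 1,
            max_samples > 0, max_samples <= 1)
  storage.mode(x) <- "double"
  mtry <- as.integer(mtry %||% max(1, floor(sqrt(ncol(x)))))
  forest <- rf_fit_cpp(x, as.integer(y), as.integer(n_estimators), mtry,
                       as.integer(min_samples_leaf), max_samples,
                       as.integer(max_depth), as.integer(seed))
  structure(list(forest = forest, p = ncol(x),
                 params = list(n_estimators = n_estimators,
                               min_samples_leaf = min_samples_leaf,
                               max_samples = max_samples, mtry = mtry,
                               max_depth = max_depth, seed = seed)),
            class = "ppmcc_rf")
}

#' @param object a `ppmcc_rf` model.
#' @param newdata numeric feature matrix with `ncol(x)` columns.
#' @param ... ignored.
#' @rdname random_forest
#' @export
predict.ppmcc_rf <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$p)
  storage.mode(newdata) <- "double"
  rf_predict_cpp(object$forest, newdata)
}
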