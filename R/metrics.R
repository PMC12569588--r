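#' Confusion counts and the Matthews correlation coefficient
#'
#' `confusion_counts()` tallies a 2x2 confusion matrix from hard 0/1
#' labels.  `mcc()` evaluates the Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#'
#' a correlation-like score in `[-1, 1]` that stays informative under class
#' imbalance.  When any of the four marginal sums is zero the quotient is
#' undefined and 0 is returned by convention (the score of a random or
#' constant predictor).  An all-zero matrix is an error.
#'
#' @param truth,pred integer 0/1 vectors of equal length.
#' @return `confusion_counts()`: named numeric vector `tp`, `tn`, `fp`, `fn`.
#' @examples
#' mcc(c(tp = 5, tn = 5, fp = 0, fn = 0))
#' mcc(c(tp = 1, tn = 1, fp = 1, fn = 0))
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(0L, 1L)), all(pred %in% c(0L, 1L)))
  c(tp = sum(truth == 1L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fp = sum(truth == 0L & pred == 1L),
    fn = sum(truth == 1L & pred == 0L))
}

#' @param cm named numeric vector or list with `tp`, `tn`, `fp`, `fn`.
#' @rdname confusion_counts
#' @return `mcc()`: a number in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  cm <- as.numeric(unlist(cm)[c("tp", "tn", "fp", "fn")])
  names(cm) <- c("tp", "tn", "fp", "fn")
  stopifnot(!anyNA(cm), all(cm >= 0))
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- cm[["tp"]]; tn <- cm[["tn"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

# Base metrics available for the per-protein machinery.  All use the same
# actual-class skip rule; zero predicted-class marginals fall back to the
# metric's own degenerate-value convention.
base_metric <- function(cm, metric) {
  tp <- cm[["tp"]]; tn <- cm[["tn"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]
  switch(metric,
         mcc = mcc(cm),
         f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
         balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2,
         youden = tp / (tp + fn) + tn / (tn + fp) - 1,
         stop("unknown base metric: ", metric))
}

#' Construct a prediction set
#'
#' The record format produced by [fit_predict_outer()] and consumed by the
#' evaluation metrics: one row per validated interaction with its
#' endpoints, true label, predicted label and outer fold id.
#'
#' @param protein_a,protein_b character endpoint identifiers.
#' @param truth,pred integer 0/1 labels.
#' @param fold integer outer fold ids (default 1).
#' @param index optional original interaction indices.
#' @return A data.frame of class `prediction_set`.
#' @export
prediction_set <- function(protein_a, protein_b, truth, pred, fold = 1L,
                           index = seq_along(truth)) {
  stopifnot(all(truth %in% c(0L, 1L)), all(pred %in% c(0L, 1L)))
  out <- data.frame(index = index,
                    protein_a = as.character(protein_a),
                    protein_b = as.character(protein_b),
                    truth = as.integer(truth), pred = as.integer(pred),
                    fold = as.integer(fold))
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Pooled (raw) MCC of a prediction set
#'
#' Aggregates all records — across outer folds — into a single confusion
#' matrix and returns its MCC.
#'
#' @param preds a [prediction_set()].
#' @return A number in `[-1, 1]`.
#' @export
mcc_of <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"), nrow(preds) > 0)
  mcc(confusion_counts(preds$truth, preds$pred))
}

#' Per-protein confusion submatrices
#'
#' Pools all records across outer folds first, then tallies for each
#' protein the confusion matrix of the validation interactions involving
#' it.  Every record credits *both* endpoint proteins (a self-interaction
#' credits its protein once), so a protein validated in several folds gets
#' one pooled matrix.  With `endpoint = "first"` records credit only
#' `protein_a` — the protein-centric "reference protein" view.
#'
#' @param preds a [prediction_set()].
#' @param endpoint `"both"` (default) or `"first"`.
#' @return data.frame with columns `protein`, `tp`, `tn`, `fp`, `fn`,
#'   `weight` (number of validation interactions involving the protein).
#' @export
per_protein_matrices <- function(preds, endpoint = c("both", "first")) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(preds, "prediction_set"), nrow(preds) > 0)
  if (endpoint == "both") {
    self <- preds$protein_a == preds$protein_b
    prot <- c(preds$protein_a, preds$protein_b[!self])
    truth <- c(preds$truth, preds$truth[!self])
    pred <- c(preds$pred, preds$pred[!self])
  } else {
    prot <- preds$protein_a
    truth <- preds$truth
    pred <- preds$pred
  }
  f <- factor(prot, levels = unique(prot))
  cell <- function(t, p) {
    as.integer(tapply(truth == t & pred == p, f, sum, default = 0L))
  }
  data.frame(protein = levels(f),
             tp = cell(1L, 1L), tn = cell(0L, 0L),
             fp = cell(0L, 1L), fn = cell(1L, 0L),
             weight = as.integer(tabulate(f)))
}

#' Per-protein MCC (pp_MCC)
#'
#' The bias-aware utility metric.  After pooling the outer validation
#' predictions, each protein's MCC is computed on its own confusion
#' submatrix, and the final score is the average over proteins weighted by
#' the number of validation interactions each protein appears in:
#'
#' \deqn{pp\_MCC = \frac{\sum_i w_i \, MCC_i}{\sum_i w_i}}
#'
#' **Skip rule**: a protein with no actual-positive interactions
#' (`tp + fn = 0`) or no actual-negative interactions (`tn + fp = 0`) in
#' validation is skipped — its recall or specificity has a zero denominator
#' — and excluded from the weighted average.  A zero *predicted*-class
#' marginal with both actual classes present is not a skip; the base
#' metric's degenerate convention applies (MCC = 0), which is exactly how a
#' per-protein-constant predictor is scored at 0.
#'
#' The same machinery supports other base metrics (`f1`,
#' `balanced_accuracy`, `youden`) under the identical skip rule.
#'
#' @param preds a [prediction_set()].
#' @param endpoint `"both"` (default): each record credits both endpoint
#'   proteins; `"first"`: only `protein_a` (protein-centric analyses).
#' @param metric base metric, default `"mcc"`.
#' @return An object of class `pp_mcc`: list with `value` (the weighted
#'   average), `metric`, `breakdown` (data.frame: `protein`, `tp`, `tn`,
#'   `fp`, `fn`, `metric_value`, `weight`, `skipped`), `n_scored`,
#'   `n_skipped`, `sum_weight` (over scored proteins).
#' @examples
#' ps <- prediction_set(c("A", "A", "A", "B", "B", "C"),
#'                      c("B", "C", "D", "C", "D", "D"),
#'                      truth = c(1, 0, 0, 1, 1, 0),
#'                      pred  = c(1, 1, 0, 0, 1, 0))
#' pp_mcc(ps)$value  # 1/3: B skipped (no actual negatives), weights 3,3,3
#' @export
pp_mcc <- function(preds, endpoint = c("both", "first"), metric = "mcc") {
  endpoint <- match.arg(endpoint)
  mats <- per_protein_matrices(preds, endpoint)
  skipped <- (mats$tp + mats$fn == 0L) | (mats$tn + mats$fp == 0L)
  metric_value <- rep(NA_real_, nrow(mats))
  for (i in which(!skipped)) {
    metric_value[i] <- base_metric(
      c(tp = mats$tp[i], tn = mats$tn[i], fp = mats$fp[i], fn = mats$fn[i]),
      metric)
  }
  if (all(skipped)) {
    stop("every protein is skipped: no protein has both actual classes ",
         "among its validation interactions, so no per-protein ", metric,
         " is defined")
  }
  breakdown <- cbind(mats, metric_value = metric_value, skipped = skipped)
  w <- mats$weight[!skipped]
  value <- sum(w * metric_value[!skipped]) / sum(w)
  structure(list(value = value, metric = metric, endpoint = endpoint,
                 breakdown = breakdown,
                 n_scored = sum(!skipped), n_skipped = sum(skipped),
                 sum_weight = sum(w)),
            class = "pp_mcc")
}

#' @export
print.pp_mcc <- function(x, ...) {
  cat(sprintf("<pp_%s> %.4f  (%d proteins scored, %d skipped, total weight %d)\n",
              x$metric, x$value, x$n_scored, x$n_skipped, x$sum_weight))
  invisible(x)
}

#' Paired comparison of a raw and an adjusted metric
#'
#' Classical paired t-test on matched per-configuration metric values
#' (e.g. raw MCC vs pp_MCC over the cells of an experiment), testing
#' whether the adjustment systematically changes the score.
#'
#' @param x,y numeric vectors of equal length (>= 2), matched by
#'   configuration.
#' @return List with `statistic` (t), `p_value` (two-sided), `df`,
#'   `mean_diff`.  All-zero or constant differences make the statistic
#'   undefined and raise an error rather than a guess.
#' @export
paired_metric_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 matched pairs")
  d <- x - y
  if (all(d == 0)) stop("all differences are zero; paired statistic undefined")
  if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    stop("all differences are identical (", d[1],
         "); paired t statistic is undefined (zero variance)")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

#' Write a per-protein metric breakdown as CSV
#'
#' @param x a [pp_mcc()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_breakdown <- function(x, path) {
  stopifnot(inherits(x, "pp_mcc"))
  utils::write.csv(x$breakdown, path, row.names = FALSE)
  invisible(path)
}
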