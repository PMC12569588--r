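#' Random interaction folds
#'
#' Shuffles the interaction indices with the given seed and partitions them
#' into `k` near-equal validation sets (remainder interactions go one per
#' fold starting from the first); each fold's training set is the
#' complement.  This is the classical random cross-validation layout whose
#' optimistic bias the unseen-protein construction and the pp_MCC metric
#' expose.
#'
#' @param ds a [ppi_dataset] (or an integer: the number of interactions).
#' @param k number of folds (`k = 1` is allowed for testing and yields an
#'   empty training set).
#' @param seed integer seed; folds are a pure function of `(ds, k, seed)`.
#' @return List of `k` folds, each a list with integer index vectors
#'   `train` and `valid` (disjoint; validation sets partition the dataset).
#' @export
random_folds <- function(ds, k, seed = 1) {
  n <- if (inherits(ds, "ppi_dataset")) n_interactions(ds) else as.integer(ds)
  stopifnot(k >= 1)
  if (k > n) stop("k (", k, ") exceeds the number of interactions (", n, ")")
  idx <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  lapply(seq_len(k), function(i) {
    valid <- sort(idx[starts[i]:ends[i]])
    list(train = sort(setdiff(seq_len(n), valid)), valid = valid)
  })
}

#' Remove training interactions that touch validation proteins
#'
#' The unseen-protein filter: for each fold, every training interaction
#' with at least one endpoint among the proteins appearing in that fold's
#' validation interactions is dropped.  Exposed separately so alternative
#' fold assignments (e.g. component-aligned folds) can be filtered too.
#'
#' @param folds list of folds as produced by [random_folds()].
#' @param ds the [ppi_dataset] the indices refer to.
#' @return Folds with filtered `train` sets; each fold gains
#'   `n_train_before` / `n_train_after` counts.
#' @export
filter_unseen <- function(folds, ds) {
  stopifnot(inherits(ds, "ppi_dataset"))
  int <- ds$interactions
  lapply(folds, function(f) {
    valid_prot <- unique(c(int$protein_a[f$valid], int$protein_b[f$valid]))
    keep <- !(int$protein_a[f$train] %in% valid_prot |
                int$protein_b[f$train] %in% valid_prot)
    list(train = f$train[keep], valid = f$valid,
         n_train_before = length(f$train), n_train_after = sum(keep))
  })
}

#' Unseen-protein interaction folds
#'
#' Starts from [random_folds()] and applies [filter_unseen()]: no protein
#' appearing in a fold's validation interactions occurs in any of its
#' training interactions.  Training sets shrink accordingly, which is why
#' this regime is typically run with many more folds than the random one
#' (50 vs 3 at benchmark scale) to keep training sizes comparable.
#'
#' @inheritParams random_folds
#' @return List of folds as in [random_folds()], with per-fold
#'   `n_train_before` / `n_train_after` retention counts.
#' @export
unseen_protein_folds <- function(ds, k, seed = 1) {
  stopifnot(inherits(ds, "ppi_dataset"), k >= 1)
  folds <- filter_unseen(random_folds(ds, k, seed), ds)
  empty <- which(vapply(folds, function(f) length(f$train) == 0L, logical(1)))
  if (length(empty)) {
    stop("unseen-protein fold ", empty[1], " of ", k, " has an empty training ",
         "set after filtering; use a larger k (smaller validation partitions)")
  }
  folds
}

#' Build a nested cross-validation plan
#'
#' Outer folds estimate performance; inner folds — constructed from each
#' outer fold's training interactions with the *same* split mode — drive
#' hyperparameter selection, so models are tuned under the regime they are
#' evaluated in.  Defaults follow the fold counts used at benchmark scale:
#' 3 outer / 3 inner for random splits, 50 outer / 40 inner for
#' unseen-protein splits (chosen there to give comparable training sizes).
#' `k_inner = 0` yields a plan without inner folds, for runs with fixed
#' hyperparameters.
#'
#' @param ds a [ppi_dataset].
#' @param mode `"random"` or `"unseen_protein"`.
#' @param k_outer,k_inner fold counts; `NULL` selects the mode's default.
#' @param seed integer seed.
#' @return An object of class `fold_plan`: list with `mode`, `outer` (list
#'   of folds with dataset-level indices), `inner` (one list of folds per
#'   outer fold, indices again dataset-level, drawn only from the parent's
#'   training indices), `k_outer`, `k_inner`, `seed`, `n`.
#' @export
make_plan <- function(ds, mode = c("random", "unseen_protein"),
                      k_outer = NULL, k_inner = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "ppi_dataset"))
  defaults <- if (mode == "random") c(3L, 3L) else c(50L, 40L)
  k_outer <- as.integer(k_outer %||% defaults[1])
  k_inner <- as.integer(k_inner %||% defaults[2])
  stopifnot(k_outer >= 1, k_inner >= 0)

  builder <- if (mode == "random") {
    function(d, k, s) random_folds(d, k, s)
  } else {
    function(d, k, s) unseen_protein_folds(d, k, s)
  }
  outer <- builder(ds, k_outer, seed)
  inner <- lapply(seq_along(outer), function(i) {
    if (k_inner == 0L) return(list())
    tr <- outer[[i]]$train
    sub <- ppi_dataset(ds$interactions[tr, , drop = FALSE])
    sub_folds <- builder(sub, k_inner, derive_seed(seed, i))
    lapply(sub_folds, function(f) {
      list(train = tr[f$train], valid = tr[f$valid])
    })
  })
  structure(list(mode = mode, outer = outer, inner = inner,
                 k_outer = k_outer, k_inner = k_inner, seed = seed,
                 n = n_interactions(ds)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  tr <- vapply(x$outer, function(f) length(f$train), integer(1))
  cat(sprintf("<fold_plan> mode=%s, %d outer x %d inner folds, n=%d\n",
              x$mode, x$k_outer, x$k_inner, x$n))
  cat(sprintf("  outer training sizes: min %d, mean %.0f, max %d\n",
              min(tr), mean(tr), max(tr)))
  invisible(x)
}

#' Serialize / load a fold plan as plain text
#'
#' One line per fold and role:
#' `<level>\t<outer id>\t<inner id or 0>\t<train|valid>\t<space-separated indices>`
#' preceded by a header line with mode, fold counts, seed and n.
#'
#' @param plan a `fold_plan`.
#' @param path file path.
#' @return `write_fold_plan()`: `path` invisibly; `read_fold_plan()`: the
#'   reconstructed `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#fold_plan\t%s\t%d\t%d\t%d\t%d",
                     plan$mode, plan$k_outer, plan$k_inner, plan$seed, plan$n),
             con)
  emit <- function(level, i, j, role, idx) {
    writeLines(paste(level, i, j, role, paste(idx, collapse = " "),
                     sep = "\t"), con)
  }
  for (i in seq_along(plan$outer)) {
    emit("outer", i, 0L, "train", plan$outer[[i]]$train)
    emit("outer", i, 0L, "valid", plan$outer[[i]]$valid)
    for (j in seq_along(plan$inner[[i]])) {
      emit("inner", i, j, "train", plan$inner[[i]][[j]]$train)
      emit("inner", i, j, "valid", plan$inner[[i]][[j]]$valid)
    }
  }
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "#fold_plan") stop("not a fold plan file: ", path)
  k_outer <- as.integer(hdr[3])
  k_inner <- as.integer(hdr[4])
  outer <- vector("list", k_outer)
  inner <- replicate(k_outer, list(), simplify = FALSE)
  for (ln in lines[-1]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    idx <- if (nchar(f[5])) as.integer(strsplit(f[5], " ", fixed = TRUE)[[1]]) else integer(0)
    i <- as.integer(f[2]); j <- as.integer(f[3])
    if (f[1] == "outer") {
      if (is.null(outer[[i]])) outer[[i]] <- list()
      outer[[i]][[f[4]]] <- idx
    } else {
      if (length(inner[[i]]) < j) inner[[i]][[j]] <- list()
      inner[[i]][[j]][[f[4]]] <- idx
    }
  }
  structure(list(mode = hdr[2], outer = outer, inner = inner,
                 k_outer = k_outer, k_inner = k_inner,
                 seed = as.integer(hdr[5]), n = as.integer(hdr[6])),
            class = "fold_plan")
}
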