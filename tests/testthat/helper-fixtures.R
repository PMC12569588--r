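# Shared fixtures and independent oracles.

# 6-interaction toy dataset used for hand-derived statistics:
#   A-B:+  A-C:-  A-D:-  B-C:+  B-D:+  C-D:-
toy6_dataset <- function() {
  ppi_dataset(data.frame(
    protein_a = c("A", "A", "A", "B", "B", "C"),
    protein_b = c("B", "C", "D", "C", "D", "D"),
    label = c(1, 0, 0, 1, 1, 0)))
}

# 6-record toy prediction set for the worked pp_MCC example:
# (true, pred): A-B(+,+) A-C(-,+) A-D(-,-) B-C(+,-) B-D(+,+) C-D(-,-)
toy6_predictions <- function() {
  prediction_set(protein_a = c("A", "A", "A", "B", "B", "C"),
                 protein_b = c("B", "C", "D", "C", "D", "D"),
                 truth = c(1, 0, 0, 1, 1, 0),
                 pred = c(1, 1, 0, 0, 1, 0))
}

# Independent brute-force pp_MCC oracle.  Re-derives each protein's records
# by scanning the full set, and computes each per-protein MCC as the Pearson
# correlation of the binary truth/pred vectors (the phi coefficient) — a
# different route from the package's confusion-matrix formula.
oracle_pp_mcc <- function(preds, endpoint = "both") {
  prots <- unique(c(preds$protein_a,
                    if (endpoint == "both") preds$protein_b else character(0)))
  vals <- numeric(0)
  ws <- numeric(0)
  for (p in prots) {
    sel <- if (endpoint == "both") {
      preds$protein_a == p | preds$protein_b == p
    } else {
      preds$protein_a == p
    }
    tr <- preds$truth[sel]
    pr <- preds$pred[sel]
    if (length(unique(tr)) < 2) next # skip rule: single actual class
    v <- suppressWarnings(stats::cor(tr, pr))
    if (is.na(v)) v <- 0 # constant predictions: zero predicted marginal
    vals <- c(vals, v)
    ws <- c(ws, sum(sel))
  }
  if (!length(vals)) stop("all proteins skipped")
  sum(ws * vals) / sum(ws)
}

# Random small prediction set (<= n_prot proteins, <= max_rec records) that
# is guaranteed to have at least one unskipped protein.
random_predset <- function(n_prot = 8, max_rec = 20) {
  repeat {
    m <- sample(2:max_rec, 1)
    prots <- LETTERS[seq_len(sample(2:n_prot, 1))]
    a <- sample(prots, m, replace = TRUE)
    b <- sample(prots, m, replace = TRUE) # self-pairs allowed
    truth <- sample(0:1, m, replace = TRUE)
    pred <- sample(0:1, m, replace = TRUE)
    ps <- prediction_set(a, b, truth, pred, fold = sample(1:3, m, replace = TRUE))
    ok <- any(vapply(unique(c(a, b)), function(p) {
      sel <- a == p | b == p
      length(unique(truth[sel])) == 2
    }, logical(1)))
    if (ok) return(ps)
  }
}

# Small synthetic dataset helper.
small_world <- function(n_prot = 40, n_int = 200, seed = 1, ...) {
  generate_dataset(bias_spec(n_proteins = n_prot, n_interactions = n_int,
                             seed = seed, ...))
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
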