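#' Combine two protein embeddings into a pair feature
#'
#' The three pair-combination operators used with protein language-model
#' embeddings: concatenation (vector "AB", length `2d`, first-listed protein
#' first), elementwise addition ("A + B") and elementwise multiplication
#' ("A * B"), both of length `d`.  Addition and multiplication are symmetric
#' under endpoint swap; concatenation is not — which is why interaction
#' pairs are kept ordered.
#'
#' @param a,b numeric vectors of equal length.
#' @param method `"concat"`, `"add"` or `"multiply"`.
#' @return Numeric vector with attribute `method`.
#' @examples
#' combine_pair(c(1, 2), c(3, 4), "concat")
#' combine_pair(c(2, -1), c(3, 5), "multiply")
#' @export
combine_pair <- function(a, b, method = c("concat", "add", "multiply")) {
  method <- match.arg(method)
  if (length(a) != length(b)) {
    stop("embedding length mismatch: ", length(a), " vs ", length(b))
  }
  out <- switch(method, concat = c(a, b), add = a + b, multiply = a * b)
  attr(out, "method") <- method
  out
}

#' Build the pair-feature design matrix for a dataset
#'
#' Looks up the embedding of each interaction's two endpoints in the store
#' and combines them with [combine_pair()] semantics, vectorised over the
#' whole dataset.  Row order equals interaction order.  With
#' `augment = TRUE` (off by default) each pair additionally contributes its
#' reversed orientation ("BA") — a data-augmentation variant that is
#' supported for completeness but not used by default.
#'
#' @param ds a [ppi_dataset].
#' @param store numeric matrix of per-protein embeddings, rownames =
#'   protein identifiers (see [generate_embeddings()], [read_embeddings()]).
#' @param method combination operator, see [combine_pair()].
#' @param augment also emit reversed pairs (doubles the rows; reversed rows
#'   follow the originals).
#' @return List with `x` (numeric matrix, `n x 2d` for concat else `n x d`),
#'   `y` (integer labels, positive = 1), and `method`.
#' @export
build_design <- function(ds, store, method = c("concat", "add", "multiply"),
                         augment = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "ppi_dataset"), is.matrix(store),
            !is.null(rownames(store)))
  int <- ds$interactions
  missing <- setdiff(ds$proteins, rownames(store))
  if (length(missing)) {
    stop("no embedding for protein(s): ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  }
  a <- int$protein_a
  b <- int$protein_b
  y <- int$label
  if (augment) {
    tmp <- a
    a <- c(a, b)
    b <- c(b, tmp)
    y <- c(y, y)
  }
  ea <- store[a, , drop = FALSE]
  eb <- store[b, , drop = FALSE]
  x <- switch(method,
              concat = cbind(ea, eb),
              add = ea + eb,
              multiply = ea * eb)
  dimnames(x) <- NULL
  list(x = x, y = as.integer(y), method = method)
}
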