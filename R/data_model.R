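#' Labelled protein-protein interaction dataset
#'
#' Container for a set of labelled protein pairs: one row per interaction
#' with the two endpoint identifiers and a binary label (1 = interacting /
#' positive, 0 = non-interacting / negative).  Pairs are stored *ordered*,
#' exactly as given: no canonicalisation of (A,B) versus (B,A), because
#' concatenation-based pair features distinguish orientation.  Identifiers
#' are case-sensitive opaque strings.
#'
#' Exact duplicate rows (same ordered pair, same label) are rejected by
#' default; set `duplicates = "deduplicate"` to keep the first occurrence.
#' The same ordered pair with *conflicting* labels is always an error.
#' Self-interactions (A,A) are permitted.
#'
#' @param interactions data.frame with character columns `protein_a`,
#'   `protein_b` and a `label` column coercible to 0/1.
#' @param sequences optional named character vector mapping protein
#'   identifiers to amino-acid sequences.
#' @param duplicates `"error"` (default) or `"deduplicate"`.
#' @param provenance free-form list recorded on the object (source path,
#'   dialect, dedup policy, generator spec, ...).
#'
#' @return An object of class `ppi_dataset`: a list with elements
#'   `interactions` (data.frame), `proteins` (character vector: the union of
#'   endpoints, in order of first appearance), `sequences`, `provenance`.
#' @examples
#' ds <- ppi_dataset(data.frame(protein_a = c("A", "A"),
#'                              protein_b = c("B", "C"),
#'                              label = c(1, 0)))
#' ds$proteins
#' @export
ppi_dataset <- function(interactions, sequences = NULL,
                        duplicates = c("error", "deduplicate"),
                        provenance = list()) {
  duplicates <- match.arg(duplicates)
  stopifnot(is.data.frame(interactions))
  required <- c("protein_a", "protein_b", "label")
  missing_cols <- setdiff(required, names(interactions))
  if (length(missing_cols)) {
    stop("interactions is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  interactions <- interactions[required]
  interactions$protein_a <- as.character(interactions$protein_a)
  interactions$protein_b <- as.character(interactions$protein_b)
  if (nrow(interactions)) {
    if (any(!nzchar(interactions$protein_a)) || any(!nzchar(interactions$protein_b))) {
      stop("protein identifiers must be non-empty strings")
    }
    lab <- interactions$label
    if (!all(lab %in% c(0, 1))) {
      stop("labels must be binary (0 = negative, 1 = positive); got: ",
           paste(unique(lab[!lab %in% c(0, 1)]), collapse = ", "))
    }
    interactions$label <- as.integer(lab)

    key <- paste(interactions$protein_a, interactions$protein_b, sep = "\r")
    full_key <- paste(key, interactions$label, sep = "\r")
    if (anyDuplicated(full_key)) {
      if (duplicates == "error") {
        stop("exact duplicate interaction rows present (e.g. row ",
             which(duplicated(full_key))[1],
             "); use duplicates = \"deduplicate\" to keep first occurrences")
      }
      keep <- !duplicated(full_key)
      interactions <- interactions[keep, , drop = FALSE]
      key <- key[keep]
      rownames(interactions) <- NULL
    }
    conflict <- duplicated(key) # same ordered pair left after exact dedup
    if (any(conflict)) {
      stop("conflicting labels for the same ordered pair: ",
           sub("\r", "-", key[which(conflict)[1]]))
    }
  } else {
    interactions$label <- integer(0)
  }
  rownames(interactions) <- NULL

  proteins <- unique(c(rbind(interactions$protein_a, interactions$protein_b)))
  provenance$duplicates <- duplicates
  structure(list(interactions = interactions, proteins = proteins,
                 sequences = sequences, provenance = provenance),
            class = "ppi_dataset")
}

#' @export
print.ppi_dataset <- function(x, ...) {
  cat(sprintf("<ppi_dataset> %d interactions (%d positive / %d negative), %d proteins\n",
              nrow(x$interactions), sum(x$interactions$label == 1L),
              sum(x$interactions$label == 0L), length(x$proteins)))
  if (!is.null(x$sequences)) cat(sprintf("  sequences: %d\n", length(x$sequences)))
  if (!is.null(x$provenance$path)) cat("  source:", x$provenance$path, "\n")
  invisible(x)
}

#' Number of interactions in a dataset
#' @param ds a [ppi_dataset].
#' @return Integer count.
#' @export
n_interactions <- function(ds) nrow(ds$interactions)

#' Label dialect for interaction tables
#'
#' Token sets accepted as positive/negative labels when parsing interaction
#' tables.  Matching is case-insensitive.  The defaults accept `1`/`0`,
#' `positive`/`negative` and `true`/`false`.
#'
#' @param positive,negative character vectors of accepted tokens.
#' @return A list with elements `positive` and `negative`.
#' @export
label_dialect <- function(positive = c("1", "positive", "true"),
                          negative = c("0", "negative", "false")) {
  list(positive = tolower(positive), negative = tolower(negative))
}

#' Read an interaction table
#'
#' Parses a delimited text file with one interaction per row: two protein
#' identifiers followed by a label.  A header row is auto-detected (its
#' third field is not a recognised label token).  Extra columns are ignored.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param header `"auto"` (default), `TRUE` or `FALSE`.
#' @param dialect a [label_dialect()].
#' @param duplicates duplicate-row policy, see [ppi_dataset()].
#' @return A [ppi_dataset]; empty file yields an empty dataset with a warning.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB\t1", "A\tC\t0"), f)
#' read_interactions(f)
#' @export
read_interactions <- function(path, sep = "\t", header = "auto",
                              dialect = label_dialect(),
                              duplicates = c("error", "deduplicate")) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty interaction file: ", path)
    return(ppi_dataset(data.frame(protein_a = character(0),
                                  protein_b = character(0),
                                  label = integer(0)),
                       provenance = list(path = path)))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)

  known <- c(dialect$positive, dialect$negative)
  first <- fields[[1]]
  has_header <- if (identical(header, "auto")) {
    length(first) >= 3 && !(tolower(trimws(first[3])) %in% known)
  } else {
    isTRUE(header)
  }
  offset <- as.integer(has_header)
  if (has_header) fields <- fields[-1]
  if (!length(fields)) {
    warning("interaction file has a header but no data rows: ", path)
    return(ppi_dataset(data.frame(protein_a = character(0),
                                  protein_b = character(0),
                                  label = integer(0)),
                       provenance = list(path = path)))
  }

  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed row at line ", which(nf < 3)[1] + offset,
         " of ", path, ": expected at least 3 fields, got ", nf[nf < 3][1])
  }
  a <- vapply(fields, function(f) trimws(f[1]), character(1))
  b <- vapply(fields, function(f) trimws(f[2]), character(1))
  tok <- tolower(vapply(fields, function(f) trimws(f[3]), character(1)))
  bad <- !(tok %in% known)
  if (any(bad)) {
    stop("unknown label token \"", tok[bad][1], "\" at line ",
         which(bad)[1] + offset, " of ", path)
  }
  ppi_dataset(data.frame(protein_a = a, protein_b = b,
                         label = as.integer(tok %in% dialect$positive)),
              duplicates = duplicates,
              provenance = list(path = path, sep = sep,
                                header = has_header))
}

#' Write an interaction table
#'
#' Inverse of [read_interactions()]: writes `protein_a`, `protein_b`,
#' `label` (1/0) columns.
#'
#' @param ds a [ppi_dataset].
#' @param path output file path.
#' @param sep field separator.
#' @param header write a header row (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(ds, path, sep = "\t", header = TRUE) {
  stopifnot(inherits(ds, "ppi_dataset"))
  write.table(ds$interactions, path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()].  Each record is
#' keyed by the header token before the first whitespace; sequences are
#' uppercased.  Duplicate identifiers are an error.
#'
#' @param path FASTA file path.
#' @return Named character vector, identifier -> amino-acid sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    stop("not a valid FASTA file (", path, "): ",
                         conditionMessage(e), call. = FALSE)
                  })
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Per-protein interaction statistics and dataset summary
#'
#' Computes, for every protein in the dataset, the number of positive and
#' negative interactions it participates in and its *positivity*
#' `n_pos / (n_pos + n_neg)` — the quantity whose skew drives the evaluation
#' bias this package corrects for.  Every interaction credits both endpoint
#' proteins; a self-interaction credits its protein once.
#'
#' @param ds a non-empty [ppi_dataset].
#' @return An object of class `ppi_summary`: list with counts
#'   (`n_proteins`, `n_interactions`, `n_positive`, `n_negative`,
#'   `n_only_positive`, `n_only_negative`, `n_mixed`), `pct_single_class`
#'   (percent of proteins whose interactions are all of one class, unrounded),
#'   and `protein_stats`, a data.frame with columns `protein`, `n_pos`,
#'   `n_neg`, `positivity`.
#' @examples
#' ds <- ppi_dataset(data.frame(protein_a = c("A", "A"),
#'                              protein_b = c("B", "C"),
#'                              label = c(1, 0)))
#' ppi_summary(ds)$protein_stats
#' @export
ppi_summary <- function(ds) {
  stopifnot(inherits(ds, "ppi_dataset"))
  int <- ds$interactions
  if (!nrow(int)) stop("cannot summarize an empty dataset")
  self <- int$protein_a == int$protein_b
  prot <- c(int$protein_a, int$protein_b[!self])
  lab <- c(int$label, int$label[!self])
  f <- factor(prot, levels = ds$proteins)
  n_pos <- as.integer(tapply(lab == 1L, f, sum, default = 0L))
  n_neg <- as.integer(tapply(lab == 0L, f, sum, default = 0L))
  stats <- data.frame(protein = ds$proteins, n_pos = n_pos, n_neg = n_neg,
                      positivity = n_pos / (n_pos + n_neg))
  only_pos <- sum(n_neg == 0L)
  only_neg <- sum(n_pos == 0L)
  out <- list(
    n_proteins = length(ds$proteins),
    n_interactions = nrow(int),
    n_positive = sum(int$label == 1L),
    n_negative = sum(int$label == 0L),
    n_only_positive = only_pos,
    n_only_negative = only_neg,
    n_mixed = length(ds$proteins) - only_pos - only_neg,
    pct_single_class = pct_single_class(only_pos, only_neg, length(ds$proteins)),
    protein_stats = stats
  )
  class(out) <- "ppi_summary"
  out
}

#' @export
print.ppi_summary <- function(x, ...) {
  cat(sprintf("<ppi_summary> %d proteins, %d interactions (%d+/%d-)\n",
              x$n_proteins, x$n_interactions, x$n_positive, x$n_negative))
  cat(sprintf("  only-positive %d, only-negative %d, mixed %d (%.2f %% single-class)\n",
              x$n_only_positive, x$n_only_negative, x$n_mixed,
              x$pct_single_class))
  invisible(x)
}

#' Percentage of single-class proteins
#'
#' The share of proteins whose interactions are all positive or all
#' negative: `100 * (n_only_positive + n_only_negative) / n_proteins`.
#'
#' @param n_only_positive,n_only_negative,n_proteins counts.
#' @return Percentage (unrounded).
#' @examples
#' pct_single_class(76, 280, 2497)
#' @export
pct_single_class <- function(n_only_positive, n_only_negative, n_proteins) {
  stopifnot(n_proteins > 0, n_only_positive >= 0, n_only_negative >= 0,
            n_only_positive + n_only_negative <= n_proteins)
  100 * (n_only_positive + n_only_negative) / n_proteins
}

#' Load a protein-disjoint gold-standard benchmark from disk
#'
#' Reads the three interaction lists (train / validation / test) and the
#' accompanying FASTA of a leakage-controlled PPI benchmark distribution,
#' and verifies that no protein occurs in more than one partition.  Overlap
#' is reported as a warning (naming the offending proteins), not an error,
#' so imperfect local copies can still be inspected.
#'
#' @param dir directory holding the files.
#' @param train,validation,test file names of the three interaction tables.
#' @param sequences file name of the FASTA of protein sequences, or `NULL`.
#' @param sep,dialect passed to [read_interactions()].
#' @return List with elements `train`, `validation`, `test`
#'   (each a [ppi_dataset]; sequences attached when available) and
#'   `disjoint` (logical).
#' @export
load_gold_standard <- function(dir, train = "train.tsv",
                               validation = "validation.tsv",
                               test = "test.tsv",
                               sequences = "sequences.fasta",
                               sep = "\t", dialect = label_dialect()) {
  paths <- file.path(dir, c(train, validation, test))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing gold-standard file(s): ",
                            paste(missing, collapse = ", "))
  seqs <- NULL
  if (!is.null(sequences)) {
    sp <- file.path(dir, sequences)
    if (!file.exists(sp)) stop("missing gold-standard sequence file: ", sp)
    seqs <- read_fasta(sp)
  }
  sets <- lapply(paths, read_interactions, sep = sep, dialect = dialect)
  names(sets) <- c("train", "validation", "test")
  if (!is.null(seqs)) for (i in seq_along(sets)) sets[[i]]$sequences <- seqs

  pairs <- list(c("train", "validation"), c("train", "test"),
                c("validation", "test"))
  disjoint <- TRUE
  for (p in pairs) {
    ov <- intersect(sets[[p[1]]]$proteins, sets[[p[2]]]$proteins)
    if (length(ov)) {
      disjoint <- FALSE
      warning(sprintf("protein overlap between %s and %s sets: %s%s",
                      p[1], p[2], paste(head(ov, 5), collapse = ", "),
                      if (length(ov) > 5) sprintf(" (and %d more)", length(ov) - 5) else ""))
    }
  }
  c(sets, list(sequences = seqs, disjoint = disjoint))
}
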