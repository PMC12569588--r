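#' Specification of a synthetic biased PPI world
#'
#' Describes the generative model behind [generate_dataset()]: a protein
#' universe with a skewed per-protein positivity distribution, a heavy-tailed
#' degree distribution, and labels drawn from a mixture of an
#' identity-driven component (each protein's target positivity) and a latent
#' interaction signal.
#'
#' Label model for a pair (i, j):
#' `P(positive) = lambda * sigmoid(z_i . z_j) + (1 - lambda) * (p_i + p_j)/2`
#' where `p_i` is protein i's target positivity and `z_i` its latent vector
#' (i.i.d. standard normal coordinates).  With `signal_weight = 0` the labels
#' carry no information beyond protein identity — the regime in which random
#' cross-validation splits inflate raw performance metrics.
#'
#' Defaults emulate the composition of widely used yeast PPI benchmarks at
#' desk scale: a near-balanced global label ratio, ~15 % of proteins purely
#' one class, a U-shaped positivity distribution (`Beta(0.5, 0.5)`: many
#' proteins strongly skewed), and a heavy-tailed degree law.
#'
#' @param n_proteins number of proteins.
#' @param n_interactions number of labelled pairs; must be at least
#'   `n_proteins` and at most `choose(n_proteins, 2)`.
#' @param frac_pure fraction of proteins whose target positivity is forced
#'   to exactly 0 or 1.
#' @param pure_balance fraction of the pure proteins that are pure-positive
#'   (default 0.5: split evenly).
#' @param beta_a,beta_b Beta shape parameters for the remaining proteins'
#'   target positivity.
#' @param signal_weight lambda in `[0, 1]`: weight of the latent interaction
#'   signal in the label model.
#' @param latent_dim dimension of the latent interaction vectors `z_i`.
#' @param degree_exponent exponent of the power-law degree weights
#'   (`weight of rank r` proportional to `r^-degree_exponent`; 0 = uniform).
#' @param seed integer random seed; generation is a pure function of the spec.
#' @return An object of class `bias_spec` (a validated list of the above).
#' @export
bias_spec <- function(n_proteins = 500, n_interactions = 10000,
                      frac_pure = 0.15, pure_balance = 0.5,
                      beta_a = 0.5, beta_b = 0.5,
                      signal_weight = 0, latent_dim = 8,
                      degree_exponent = 0.4, seed = 1) {
  stopifnot(n_proteins >= 2, n_interactions >= 1,
            frac_pure >= 0, frac_pure <= 1,
            pure_balance >= 0, pure_balance <= 1,
            beta_a > 0, beta_b > 0,
            signal_weight >= 0, signal_weight <= 1,
            latent_dim >= 1, degree_exponent >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_interactions = as.integer(n_interactions),
                 frac_pure = as.numeric(frac_pure),
                 pure_balance = as.numeric(pure_balance),
                 beta_a = as.numeric(beta_a), beta_b = as.numeric(beta_b),
                 signal_weight = as.numeric(signal_weight),
                 latent_dim = as.integer(latent_dim),
                 degree_exponent = as.numeric(degree_exponent),
                 seed = as.integer(seed)),
            class = "bias_spec")
}

#' Generate a synthetic biased interaction dataset
#'
#' Draws a simple graph (no self-pairs, no duplicate unordered pairs) on
#' `n_proteins` proteins in which every protein appears in at least one
#' interaction, endpoints are sampled proportional to power-law degree
#' weights, and labels follow the mixture model described in [bias_spec()].
#' The generator's latent state (target positivities and latent vectors) is
#' returned for parameter-recovery tests.
#'
#' @param spec a [bias_spec()].
#' @return List with elements `dataset` (a [ppi_dataset]; proteins are named
#'   `P0001`, `P0002`, ...) and `truth` (class `ground_truth`: data.frame
#'   `positivity` with per-protein target positivity `p_i`, matrix `latent`
#'   of latent vectors `z_i` in rows, and the `spec`).
#' @examples
#' gen <- generate_dataset(bias_spec(n_proteins = 20, n_interactions = 60))
#' gen$dataset
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "bias_spec"))
  n <- spec$n_proteins
  m <- spec$n_interactions
  if (m < n) {
    stop("infeasible spec: need n_interactions >= n_proteins (", m, " < ", n,
         ") so every protein can appear")
  }
  if (m > n * (n - 1) / 2) {
    stop("infeasible spec: n_interactions exceeds the number of distinct pairs")
  }
  ids <- sprintf("P%04d", seq_len(n))

  with_seed(spec$seed, {
    # per-protein target positivity: pure block + Beta-distributed remainder
    n_pure <- round(spec$frac_pure * n)
    n_pure_pos <- round(spec$pure_balance * n_pure)
    p <- rbeta(n, spec$beta_a, spec$beta_b)
    pure_idx <- sample.int(n, n_pure)
    if (n_pure > 0) {
      p[pure_idx] <- rep(0, n_pure)
      if (n_pure_pos > 0) p[pure_idx[seq_len(n_pure_pos)]] <- 1
    }
    z <- matrix(rnorm(n * spec$latent_dim), nrow = n,
                dimnames = list(ids, NULL))

    # heavy-tailed degree weights: rank^-gamma, ranks randomly assigned
    w <- sample(seq_len(n))^(-spec$degree_exponent)

    # coverage block: a random perfect-ish matching so degree >= 1 everywhere
    perm <- sample.int(n)
    half <- floor(n / 2)
    a <- perm[seq_len(half)]
    b <- perm[half + seq_len(half)]
    if (n %% 2 == 1) { # odd protein out: pair it with a random other protein
      last <- perm[n]
      mate <- sample(seq_len(n)[-last], 1)
      a <- c(a, last)
      b <- c(b, mate)
    }
    n_cover <- length(a)
    if (n_cover > m) stop("infeasible spec: too few interactions to cover proteins")

    seen <- new.env(hash = TRUE, size = 2L * m)
    pair_key <- function(i, j) paste0(min(i, j), "_", max(i, j))
    for (k in seq_len(n_cover)) assign(pair_key(a[k], b[k]), TRUE, envir = seen)

    # remaining pairs: endpoints ~ degree weights, rejection on collisions,
    # falling back to uniform sampling if the weighted proposal saturates
    need <- m - n_cover
    extra_a <- integer(need)
    extra_b <- integer(need)
    k <- 0L
    attempts <- 0L
    max_attempts <- 50L * need + 1000L
    prob <- w / sum(w)
    while (k < need) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) prob <- rep(1 / n, n)
      ij <- sample.int(n, 2, prob = prob)
      key <- pair_key(ij[1], ij[2])
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        k <- k + 1L
        extra_a[k] <- ij[1]
        extra_b[k] <- ij[2]
      }
    }
    ia <- c(a, extra_a)
    ib <- c(b, extra_b)

    lin <- (p[ia] + p[ib]) / 2
    lam <- spec$signal_weight
    prob_pos <- if (lam > 0) {
      lam * plogis(rowSums(z[ia, , drop = FALSE] * z[ib, , drop = FALSE])) +
        (1 - lam) * lin
    } else {
      lin
    }
    label <- rbinom(m, 1L, prob_pos)

    dataset <- ppi_dataset(
      data.frame(protein_a = ids[ia], protein_b = ids[ib], label = label),
      provenance = list(generator = "bias_spec", spec = unclass(spec))
    )
    truth <- structure(
      list(positivity = data.frame(protein = ids, p = p),
           latent = z, pair_prob = prob_pos, spec = spec),
      class = "ground_truth"
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Generate synthetic per-protein embeddings
#'
#' Produces fixed-length embedding vectors standing in for protein
#' language-model features.
#'
#' * `mode = "identity"`: each protein's vector is a deterministic
#'   pseudorandom function of (identifier, seed) — a unique fingerprint that
#'   carries no information about labels beyond protein identity.  This is
#'   the regime in which a learner can only memorise per-protein positivity.
#' * `mode = "signal"`: the first `latent_dim` coordinates are the protein's
#'   latent interaction vector `z_i` plus Gaussian noise of scale
#'   `noise_sd`; remaining coordinates are identity-style pseudorandom.
#'   Labels are then (partially) predictable from features for unseen
#'   proteins.
#'
#' Vectors depend only on the individual identifier and the seed, never on
#' the order or composition of `proteins`.
#'
#' @param proteins character vector of protein identifiers.
#' @param mode `"identity"` or `"signal"`.
#' @param dim embedding length (e.g. 1280 to mimic a large protein language
#'   model; smaller for desk-scale studies).
#' @param noise_sd Gaussian noise scale on the signal coordinates.
#' @param truth a `ground_truth` (required in signal mode).
#' @param seed integer seed.
#' @return A numeric matrix with one row per protein (rownames are the
#'   identifiers) — the embedding store consumed by [build_design()].
#' @export
generate_embeddings <- function(proteins, mode = c("identity", "signal"),
                                dim = 64, noise_sd = 0.1, truth = NULL,
                                seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.character(proteins), length(proteins) >= 1, dim >= 1)
  if (anyDuplicated(proteins)) stop("duplicate protein identifiers")
  if (mode == "signal") {
    if (is.null(truth)) stop("signal mode requires the generator ground truth")
    latent_dim <- ncol(truth$latent)
    if (dim < latent_dim) {
      stop("dim (", dim, ") must be >= latent_dim (", latent_dim, ")")
    }
    missing <- setdiff(proteins, rownames(truth$latent))
    if (length(missing)) {
      stop("no latent vector for protein(s): ", paste(head(missing, 5), collapse = ", "))
    }
  }
  emb <- matrix(0, nrow = length(proteins), ncol = dim,
                dimnames = list(proteins, NULL))
  for (i in seq_along(proteins)) {
    id <- proteins[i]
    vec <- with_seed(string_seed(id, seed), rnorm(dim))
    if (mode == "signal") {
      ld <- ncol(truth$latent)
      noise <- if (noise_sd > 0) {
        with_seed(string_seed(id, derive_seed(seed, 1)), rnorm(ld, sd = noise_sd))
      } else {
        0
      }
      vec[seq_len(ld)] <- truth$latent[id, ] + noise
    }
    emb[i, ] <- vec
  }
  emb
}

#' Write / read an embedding table
#'
#' Plain-text exchange format: one row per protein, the identifier followed
#' by the vector values, tab-separated, no header.
#'
#' @param embeddings numeric matrix with protein identifiers as rownames.
#' @param path file path.
#' @return `write_embeddings()`: `path` invisibly; `read_embeddings()`: the
#'   embedding matrix.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  df <- data.frame(id = rownames(embeddings), embeddings)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate protein identifier in ", path)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, NULL)
  m
}
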