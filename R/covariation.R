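# Weighted, average-product-corrected mutual information between alignment
# columns, standardized against a within-column shuffle null, with a
# randomized-dataset family-wise significance cutoff.

#' The twenty standard amino acids
#'
#' One-letter codes in alphabetical order; the residue alphabet used by the
#' covariation machinery and by residue couplings in the simulators.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# amino-acid character matrix (taxa x sites) from a codon alignment or an
# already-translated matrix; unknown residues/gaps -> NA
as_aa_matrix <- function(x) {
  if (inherits(x, "codon_alignment")) {
    m <- matrix(translate_codons(as.vector(x$codons)), nrow = length(x$taxa),
                dimnames = list(x$taxa, NULL))
    attr(m, "ref_map") <- x$ref_map
    m
  } else if (is.matrix(x) && is.character(x)) {
    m <- toupper(x)
    m[!m %in% AA20] <- NA_character_
    m
  } else stop("expected a codon_alignment or a character matrix of residues")
}

#' Cluster-based sequence weights
#'
#' Single-linkage clusters sequences at the given pairwise identity
#' threshold (identity computed over positions where neither sequence is
#' gapped) and weights each sequence by 1 / (its cluster size), so that
#' groups of near-duplicate sequences contribute one effective observation.
#'
#' @param aln A [codon_alignment] or amino-acid character matrix.
#' @param identity_threshold Fractional identity at or above which two
#'   sequences are linked (default 0.62).
#' @return Named numeric vector of weights, all > 0.
#' @export
sequence_weights <- function(aln, identity_threshold = 0.62) {
  m <- as_aa_matrix(aln)
  n <- nrow(m)
  if (n == 0) stop("empty alignment")
  if (n == 1) return(stats::setNames(1, rownames(m)))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      id <- if (any(ok)) mean(m[i, ok] == m[j, ok]) else 0
      adj[i, j] <- adj[j, i] <- id >= identity_threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  w <- 1 / as.numeric(sizes[as.character(comp)])
  stats::setNames(w, rownames(m))
}

#' Weighted mutual information between two columns
#'
#' MI (in nats) of the joint residue distribution of two columns under
#' sequence weights, with pairwise deletion of gapped taxa and a
#' pseudocount that shrinks the joint frequencies toward independence:
#' f~(a,b) = (1 - lambda) f(a,b) + lambda f(a) f(b), which leaves the
#' marginals unchanged.
#'
#' @param col_i,col_j Character vectors of residues (NA = gap).
#' @param weights Positive per-taxon weights (default 1).
#' @param pseudocount Shrinkage weight lambda in [0, 1) (default 0.05).
#' @return Nonnegative MI in nats.
#' @export
weighted_mi <- function(col_i, col_j, weights = NULL, pseudocount = 0.05) {
  if (length(col_i) != length(col_j)) stop("columns differ in length")
  if (is.null(weights)) weights <- rep(1, length(col_i))
  if (any(weights <= 0)) stop("weights must be positive")
  ok <- !is.na(col_i) & !is.na(col_j)
  if (!any(ok)) stop("all-gap column pair")
  ci <- factor(col_i[ok]); cj <- factor(col_j[ok]); w <- weights[ok]
  J <- tapply(w, list(ci, cj), sum, default = 0)
  J <- J / sum(J)
  .mi_from_joint(J, pseudocount)
}

.mi_from_joint <- function(J, lambda) {
  fa <- rowSums(J); fb <- colSums(J)
  E <- outer(fa, fb)
  Jt <- (1 - lambda) * J + lambda * E
  nz <- Jt > 0 & E > 0
  sum(Jt[nz] * log(Jt[nz] / E[nz]))
}

# full pairwise MI matrix via one weighted indicator cross-product.
# Gapped entries get zero weight, which implements pairwise deletion.
mi_matrix <- function(aa, weights = NULL, pseudocount = 0.05) {
  n <- nrow(aa); L <- ncol(aa)
  if (is.null(weights)) weights <- rep(1, n)
  lev <- AA20
  K <- length(lev)
  ind <- matrix(0, n, K * L)
  for (j in seq_len(L)) {
    idx <- match(aa[, j], lev)
    ok <- which(!is.na(idx))
    ind[cbind(ok, (j - 1) * K + idx[ok])] <- weights[ok]
  }
  indu <- ind > 0
  storage.mode(indu) <- "numeric"
  # joint weighted counts between all column pairs at once
  CC <- crossprod(ind, indu) # rows weighted, cols indicate membership
  M <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    bi <- (i - 1) * K + seq_len(K)
    for (j in (i + 1):L) {
      bj <- (j - 1) * K + seq_len(K)
      J <- CC[bi, bj]
      tot <- sum(J)
      if (tot <= 0) next
      M[i, j] <- M[j, i] <- .mi_from_joint(J / tot, pseudocount)
    }
  }
  M
}

# average-product correction: subtract (row mean_i * row mean_j) / grand mean
# (off-diagonal means)
apc_correct <- function(M) {
  L <- nrow(M)
  if (L < 3) stop("APC needs at least 3 columns")
  rm_ <- (rowSums(M)) / (L - 1)
  gm <- sum(M) / (L * (L - 1))
  if (gm == 0) return(M)
  C <- M - outer(rm_, rm_) / gm
  diag(C) <- 0
  C
}

# one within-column shuffle of an aa matrix (destroys covariation, preserves
# per-column composition)
shuffle_columns <- function(aa) {
  apply(aa, 2, sample)
}

#' APC-corrected MI z-scores for all column pairs
#'
#' Computes the full weighted MI matrix, applies the average-product
#' correction (APC), and standardizes each pair against a null distribution
#' of corrected MI values obtained by recomputing the matrix on
#' `n_column_shuffles` independent within-column shuffles of the alignment.
#'
#' @param aln A [codon_alignment] or amino-acid character matrix.
#' @param weights Optional sequence weights (default: [sequence_weights()]).
#' @param n_column_shuffles Number of shuffled replicates for the null
#'   (default 100, >= 2).
#' @param pseudocount Joint-frequency shrinkage (default 0.05).
#' @param seed Optional seed.
#' @return List with matrices `mi_raw`, `mi_corrected`, `z`, plus
#'   `null_mean`, `null_sd`, and `sites` (reference numbering if available).
#' @export
apc_z_scores <- function(aln, weights = NULL, n_column_shuffles = 100,
                         pseudocount = 0.05, seed = NULL) {
  if (n_column_shuffles < 2) stop("need at least 2 shuffles")
  if (!is.null(seed)) set.seed(seed)
  aa <- as_aa_matrix(aln)
  if (is.null(weights)) weights <- sequence_weights(aa)
  M <- mi_matrix(aa, weights, pseudocount)
  C <- apc_correct(M)
  L <- ncol(aa)
  null_sum <- matrix(0, L, L); null_sq <- matrix(0, L, L)
  for (r in seq_len(n_column_shuffles)) {
    Cs <- apc_correct(mi_matrix(shuffle_columns(aa), weights, pseudocount))
    null_sum <- null_sum + Cs
    null_sq <- null_sq + Cs^2
  }
  mu <- null_sum / n_column_shuffles
  sdv <- sqrt(pmax(null_sq / n_column_shuffles - mu^2, 0) *
                n_column_shuffles / (n_column_shuffles - 1))
  sdv[sdv < 1e-12] <- 1e-12
  z <- (C - mu) / sdv
  diag(z) <- 0
  list(mi_raw = M, mi_corrected = C, z = z, null_mean = mu, null_sd = sdv,
       sites = attr(aa, "ref_map"))
}

#' Randomized-dataset significance cutoff for MI z-scores
#'
#' Generates `n_random` fully randomized datasets (independent within-column
#' shuffles of the whole alignment), scores every pair of every randomized
#' dataset with the same APC-corrected z statistic, and returns the maximum
#' absolute z observed — the family-wise cutoff z*: an observed pair is
#' called significant only if its z exceeds every z produced by chance alone.
#' Because a within-column shuffle of a shuffled alignment is itself a
#' within-column shuffle, all replicates share one shuffle null
#' (mean/sd pool) of size `n_column_shuffles`.
#'
#' @param aln A [codon_alignment] or amino-acid character matrix.
#' @param n_random Number of randomized datasets (default 150).
#' @param n_column_shuffles Size of the shared shuffle null (default 100).
#' @param weights Optional sequence weights.
#' @param pseudocount Joint-frequency shrinkage.
#' @param seed Optional seed.
#' @return List with `z_star` (the cutoff), `n_random`, and `rep_max`
#'   (each replicate's maximum |z|).
#' @export
randomization_cutoff <- function(aln, n_random = 150, n_column_shuffles = 100,
                                 weights = NULL, pseudocount = 0.05,
                                 seed = NULL) {
  if (n_random < 1) stop("n_random must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  aa <- as_aa_matrix(aln)
  if (is.null(weights)) weights <- sequence_weights(aa)
  L <- ncol(aa)
  null_sum <- matrix(0, L, L); null_sq <- matrix(0, L, L)
  for (r in seq_len(n_column_shuffles)) {
    Cs <- apc_correct(mi_matrix(shuffle_columns(aa), weights, pseudocount))
    null_sum <- null_sum + Cs
    null_sq <- null_sq + Cs^2
  }
  mu <- null_sum / n_column_shuffles
  sdv <- sqrt(pmax(null_sq / n_column_shuffles - mu^2, 0) *
                n_column_shuffles / (n_column_shuffles - 1))
  sdv[sdv < 1e-12] <- 1e-12
  rep_max <- vapply(seq_len(n_random), function(r) {
    Cr <- apc_correct(mi_matrix(shuffle_columns(aa), weights, pseudocount))
    zr <- (Cr - mu) / sdv
    diag(zr) <- 0
    max(abs(zr))
  }, 1.0)
  list(z_star = max(rep_max), n_random = n_random, rep_max = rep_max)
}

#' Mutual-information coevolution scan against a focal site
#'
#' Runs the full APC-corrected, weighted MI analysis, derives the
#' randomized-dataset cutoff z*, and reports all pairs containing the focal
#' site (computed from the full pairwise matrix, which the APC term
#' requires).
#'
#' @param aln A [codon_alignment] (translated internally) or amino-acid
#'   matrix with a `ref_map` attribute.
#' @param focal_site Reference residue number of the focal column.
#' @param n_random,n_column_shuffles,pseudocount,identity_threshold,seed
#'   Tuning parameters (defaults 150, 100, 0.05, 0.62).
#' @return An object of class `mi_scan`: data.frame of focal pairs (`site`,
#'   `mi_raw`, `mi_corrected`, `z`, `z_star`, `significant`) with the full
#'   result in attributes.
#' @export
mi_scan <- function(aln, focal_site, n_random = 150, n_column_shuffles = 100,
                    pseudocount = 0.05, identity_threshold = 0.62, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- as_aa_matrix(aln)
  sites <- attr(aa, "ref_map")
  if (is.null(sites)) sites <- seq_len(ncol(aa))
  fc <- match(focal_site, sites)
  if (is.na(fc)) stop("focal site ", focal_site, " not in alignment")
  w <- sequence_weights(aa, identity_threshold)
  zs <- apc_z_scores(aa, weights = w, n_column_shuffles = n_column_shuffles,
                     pseudocount = pseudocount)
  rc <- randomization_cutoff(aa, n_random = n_random,
                             n_column_shuffles = n_column_shuffles,
                             weights = w, pseudocount = pseudocount)
  other <- setdiff(seq_len(ncol(aa)), fc)
  df <- data.frame(site = sites[other],
                   mi_raw = zs$mi_raw[fc, other],
                   mi_corrected = zs$mi_corrected[fc, other],
                   z = zs$z[fc, other],
                   z_star = rc$z_star,
                   significant = zs$z[fc, other] > rc$z_star)
  attr(df, "full") <- zs
  attr(df, "cutoff") <- rc
  attr(df, "focal_site") <- focal_site
  class(df) <- c("mi_scan", "data.frame")
  df
}
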