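# Muse-Gavrilets/Goldman-Yang style codon rate matrices and their
# eigendecompositions.

#' Codon substitution rate specification
#'
#' Bundles the parameters of a GY94-style codon model: the
#' transition/transversion rate ratio kappa, the stationary codon frequencies
#' pi over the 61 sense codons, and the nonsynonymous/synonymous rate ratio
#' omega (dN/dS).
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param pi Stationary codon frequencies (length 61, nonnegative, sum 1).
#' @param omega dN/dS ratio, >= 0.
#' @return An object of class `codon_rate_spec`.
#' @export
codon_rate_spec <- function(kappa, pi, omega) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a single positive number")
  if (length(pi) != 61L || any(pi < 0) || abs(sum(pi) - 1) > 1e-10)
    stop("pi must be 61 nonnegative frequencies summing to 1")
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0)
    stop("omega must be a single nonnegative number")
  structure(list(kappa = kappa, pi = as.numeric(pi), omega = omega),
            class = "codon_rate_spec")
}

#' Build a codon instantaneous rate matrix
#'
#' Constructs the 61 x 61 GY94-style generator: the rate from codon i to
#' codon j is zero unless the codons differ at exactly one nucleotide
#' position, and otherwise proportional to `pi[j]`, multiplied by `kappa` for
#' transitions and by `omega` for nonsynonymous changes. Rows sum to zero.
#'
#' @param spec A [codon_rate_spec()].
#' @param scale If `TRUE` (default), the matrix is scaled so the mean
#'   substitution rate at stationarity is 1 (branch lengths are then expected
#'   substitutions per codon under this single matrix).
#' @return A 61 x 61 rate matrix with codon row/column names.
#' @export
build_codon_Q <- function(spec, scale = TRUE) {
  stopifnot(inherits(spec, "codon_rate_spec"))
  tab <- codon_tables()
  Q <- matrix(0, 61, 61, dimnames = list(tab$codons, tab$codons))
  one <- tab$diffpos > 0L
  rate <- matrix(rep(spec$pi, each = 61), 61, 61)
  rate[tab$is_ts] <- rate[tab$is_ts] * spec$kappa
  rate[tab$is_ns] <- rate[tab$is_ns] * spec$omega
  Q[one] <- rate[one]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(spec$pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# Eigendecomposition of a reversible Q via symmetrization:
# S = D^{1/2} Q D^{-1/2} is symmetric for pi-reversible Q, so
# P(t) = A exp(L t) B with A = D^{-1/2} U, B = U' D^{1/2}.
codon_q_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  S <- (sq * Q) %*% diag(1 / sq)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(A = diag(1 / sq) %*% es$vectors,
       B = t(es$vectors) %*% diag(sq),
       lam = es$values)
}

# Transition probability matrix from an eigen structure.
codon_P <- function(eg, t) {
  P <- eg$A %*% (exp(eg$lam * t) * eg$B)
  P[P < 0] <- 0
  P
}

#' Position-specific (F3x4) codon frequencies from an alignment
#'
#' Estimates stationary codon frequencies as the product of the empirical
#' nucleotide frequencies at the three codon positions, renormalized over the
#' 61 sense codons. A small pseudocount keeps all frequencies positive.
#'
#' @param aln A [codon_alignment].
#' @param pseudocount Added to each nucleotide count per position (default 1).
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
f3x4_frequencies <- function(aln, pseudocount = 1) {
  stopifnot(inherits(aln, "codon_alignment"))
  tab <- codon_tables()
  nt <- c("A", "C", "G", "T")
  cod <- as.vector(aln$codons)
  cod <- cod[!is.na(codons_to_states(cod))]
  if (length(cod) == 0) return(rep(1 / 61, 61))
  m <- do.call(rbind, strsplit(cod, ""))
  fpos <- sapply(1:3, function(k) {
    cnt <- table(factor(m[, k], levels = nt)) + pseudocount
    as.numeric(cnt / sum(cnt))
  })
  pi <- fpos[match(tab$cmat[, 1], nt), 1] *
    fpos[match(tab$cmat[, 2], nt), 2] *
    fpos[match(tab$cmat[, 3], nt), 3]
  pi / sum(pi)
}

#' Empirical (F61) codon frequencies from an alignment
#'
#' @param aln A [codon_alignment].
#' @param pseudocount Added to each sense-codon count (default 0.5).
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
f61_frequencies <- function(aln, pseudocount = 0.5) {
  stopifnot(inherits(aln, "codon_alignment"))
  st <- codons_to_states(as.vector(aln$codons))
  cnt <- tabulate(st[!is.na(st)], nbins = 61) + pseudocount
  cnt / sum(cnt)
}
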