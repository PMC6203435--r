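# Phylogenetic likelihood evaluation for codon site-class mixtures.

# integer masks of the single-nucleotide-change structure, cached
.codon_masks <- function(tab) {
  if (!is.null(.codon_env$masks)) return(.codon_env$masks)
  d <- (tab$diffpos > 0L) + 0L
  ts <- tab$is_ts + 0L
  ns <- tab$is_ns + 0L
  storage.mode(d) <- storage.mode(ts) <- storage.mode(ns) <- "integer"
  .codon_env$masks <- list(diff = d, ts = ts, ns = ns)
  .codon_env$masks
}

# postorder edge representation used by the C++ kernels
postorder_tree <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  list(edge = phy$edge, tlen = phy$edge.length, phy = phy,
       n_tips = length(phy$tip.label))
}

# tip states (1..61, NA -> 0) in the row order of phy$tip.label
tipstate_matrix <- function(aln, phy) {
  if (!setequal(aln$taxa, phy$tip.label) ||
      length(aln$taxa) != length(phy$tip.label))
    stop("taxon mismatch between alignment and tree")
  m <- aln$codons[phy$tip.label, , drop = FALSE]
  st <- matrix(codons_to_states(as.vector(m)), nrow = nrow(m))
  st[is.na(st)] <- 0L
  storage.mode(st) <- "integer"
  st
}

# Per-class per-site log-likelihood matrix for a mixture whose classes are
# defined by per-edge omega assignments. `class_q` is a list (one per class)
# of either a single Q spec or an integer vector (per postorder edge) of
# indices into `q_specs`. Internally every distinct (kappa, omega) generator
# is eigendecomposed once.
mixture_site_logliks <- function(aln, ct, kappa, pi, class_edge_omega, scale = 1,
                                 weights = NULL, bg_omegas = NULL,
                                 normalize = FALSE) {
  po <- postorder_tree(ct$phy)
  ts <- tipstate_matrix(aln, po$phy)
  n_edges <- nrow(po$edge)
  n_classes <- length(class_edge_omega)

  # collect distinct omegas across classes/edges
  omat <- matrix(NA_real_, n_edges, n_classes)
  for (cl in seq_len(n_classes)) {
    om <- class_edge_omega[[cl]]
    omat[, cl] <- if (length(om) == 1L) rep(om, n_edges) else om
  }
  uom <- sort(unique(as.vector(omat)))
  tab <- codon_tables()
  masks <- .codon_masks(tab)
  eg <- codon_eigen_set_cpp(kappa, uom, pi, masks$diff, masks$ts, masks$ns)
  A <- eg$A; B <- eg$B; lam <- eg$lam
  qmap <- matrix(match(as.vector(omat), uom), n_edges, n_classes)
  storage.mode(qmap) <- "integer"
  storage.mode(po$edge) <- "integer"
  eff_scale <- scale
  if (normalize) {
    mu <- sum(weights * eg$rates[match(bg_omegas, uom)])
    eff_scale <- scale / mu
  }
  mixture_pruning_loglik_cpp(ts, po$edge, po$tlen * eff_scale, A, B, lam, qmap, pi)
}

# total lnL from per-class per-site log-likelihoods and weights (log-sum-exp)
mixture_total_lnL <- function(site_logliks, weights) {
  lw <- log(weights)
  m <- apply(site_logliks, 2, max)
  sum(m + log(colSums(exp(sweep(site_logliks + lw, 2, m, "-")))))
}

# per-site class posteriors (naive empirical Bayes at the supplied parameters)
neb_posteriors <- function(site_logliks, weights) {
  lw <- log(weights)
  x <- site_logliks + lw
  m <- apply(x, 2, max)
  ex <- exp(sweep(x, 2, m, "-"))
  t(sweep(ex, 2, colSums(ex), "/"))
}

#' Mixture pruning log-likelihood of a codon alignment
#'
#' Evaluates the phylogenetic log-likelihood of a codon alignment under a
#' finite mixture of site classes, each with its own dN/dS ratio (possibly
#' differing between foreground and background branches). The likelihood is
#' computed by Felsenstein pruning with transition probabilities from the
#' matrix exponential of the class generator; gapped/missing codons
#' contribute partial likelihood 1 over all states. Branch lengths are taken
#' from the tree; under `normalize = TRUE` the class generators share a
#' single mixture-average rate normalization so branch lengths are expected
#' substitutions per codon across the mixture (with branch-heterogeneous
#' classes, the normalization uses the background generator).
#'
#' @param aln A [codon_alignment].
#' @param tree A [clade_tree] over the same taxa.
#' @param mixture List with elements `weights` (class weights summing to 1)
#'   and `omegas` — either a numeric vector of per-class dN/dS values, or a
#'   list whose elements are single omegas or named lists
#'   `list(background =, <partition> = ...)` for branch-heterogeneous classes.
#' @param kappa Transition/transversion ratio.
#' @param pi Stationary codon frequencies (61).
#' @param scale Multiplier applied to all branch lengths (default 1).
#' @param normalize Apply mixture-average rate normalization (default TRUE).
#' @return The total log-likelihood (numeric scalar), with attribute
#'   `site_logliks` (classes x sites matrix of per-class log-likelihoods).
#' @export
pruning_lnL <- function(aln, tree, mixture, kappa = 2, pi = rep(1 / 61, 61),
                        scale = 1, normalize = TRUE) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "clade_tree"))
  w <- mixture$weights
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  ceo <- resolve_class_edge_omegas(tree, mixture$omegas)
  sl <- mixture_site_logliks(aln, tree, kappa, pi, ceo$class_edge_omega,
                             scale = scale, weights = w,
                             bg_omegas = ceo$background_omegas,
                             normalize = normalize)
  out <- mixture_total_lnL(sl, w)
  attr(out, "site_logliks") <- sl
  out
}

# expand per-class omega specs into per-edge omega vectors
resolve_class_edge_omegas <- function(ct, omegas) {
  po <- postorder_tree(ct$phy)
  n_edges <- nrow(po$edge)
  # map original edge indices to postorder edge order
  key <- paste(ct$phy$edge[, 1], ct$phy$edge[, 2])
  pokey <- paste(po$edge[, 1], po$edge[, 2])
  part_edges <- lapply(resolve_partition_edges(ct), function(e) match(key[e], pokey))
  if (!is.list(omegas)) omegas <- as.list(omegas)
  bg <- numeric(length(omegas))
  ceo <- vector("list", length(omegas))
  for (cl in seq_along(omegas)) {
    om <- omegas[[cl]]
    if (length(om) == 1L && is.numeric(om)) {
      ceo[[cl]] <- om
      bg[cl] <- om
    } else {
      if (is.null(om$background)) stop("branch-heterogeneous class needs a background omega")
      v <- rep(om$background, n_edges)
      for (pn in setdiff(names(om), "background")) {
        if (!pn %in% names(part_edges)) stop("unknown partition: ", pn)
        v[part_edges[[pn]]] <- om[[pn]]
      }
      ceo[[cl]] <- v
      bg[cl] <- om$background
    }
  }
  list(class_edge_omega = ceo, background_omegas = bg)
}

# mixture-average substitution rate at stationarity (background omegas)
mixture_mean_rate <- function(kappa, pi, weights, omegas) {
  rates <- vapply(omegas, function(w) {
    Q <- build_codon_Q(codon_rate_spec(kappa, pi, w), scale = FALSE)
    -sum(pi * diag(Q))
  }, 1.0)
  sum(weights * rates)
}
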