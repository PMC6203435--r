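# Codon-based marginal ancestral reconstruction at internal nodes under a
# fitted site-class model.

# per-class per-edge transition matrices at a fit's MLEs (postorder order),
# using the same mixture-rate normalization as the likelihood
.fit_edge_P <- function(fit, tree) {
  ceo <- resolve_class_edge_omegas(tree, fit$class_omegas)
  mu <- mixture_mean_rate(fit$kappa, fit$pi, fit$weights, ceo$background_omegas)
  po <- postorder_tree(tree$phy)
  n_edges <- nrow(po$edge)
  omat <- sapply(ceo$class_edge_omega, function(om)
    if (length(om) == 1L) rep(om, n_edges) else om)
  uom <- sort(unique(as.vector(omat)))
  egs <- lapply(uom, function(w) {
    Q <- build_codon_Q(codon_rate_spec(fit$kappa, fit$pi, w), scale = FALSE)
    codon_q_eigen(Q, fit$pi)
  })
  Ps <- lapply(seq_len(ncol(omat)), function(cl) {
    lapply(seq_len(n_edges), function(e)
      codon_P(egs[[match(omat[e, cl], uom)]], po$tlen[e] * fit$scale / mu))
  })
  list(po = po, Ps = Ps)
}

#' Marginal ancestral codon reconstruction
#'
#' Computes, for each requested internal node and site, the marginal
#' posterior distribution over the 61 sense codons under the fitted
#' site-class model: below-node partial likelihoods are combined with the
#' likelihood of the rest of the tree (root prior = stationary frequencies),
#' per class, and the per-class reconstructions are mixed with weights equal
#' to the site's empirical-Bayes class posteriors. The reported codon is the
#' posterior mode (MAP); ties are broken by codon lexicographic order and
#' flagged.
#'
#' @param aln A [codon_alignment].
#' @param tree The [clade_tree] the model was fitted on.
#' @param fit A `site_class_fit` for this alignment and tree.
#' @param sites Reference residue numbers to reconstruct.
#' @param nodes Internal node numbers (ape numbering, > number of tips);
#'   default all internal nodes.
#' @return List with `table` (data.frame: node, site, map_codon, map_aa,
#'   posterior, tied) and `posterior` (array node x site x codon of full
#'   marginal posteriors).
#' @export
marginal_reconstruct <- function(aln, tree, fit, sites, nodes = NULL) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "clade_tree"),
            inherits(fit, "site_class_fit"))
  cols <- site_to_col(aln, sites)
  ep <- .fit_edge_P(fit, tree)
  po <- ep$po
  n_tips <- po$n_tips
  n_nodes <- max(po$edge)
  internal <- setdiff(seq_len(n_nodes), seq_len(n_tips))
  if (is.null(nodes)) nodes <- internal
  if (any(nodes <= n_tips | nodes > n_nodes))
    stop("nodes must be internal node numbers")
  ts <- tipstate_matrix(aln, po$phy)[, cols, drop = FALSE]
  S <- length(cols)
  n_classes <- length(fit$weights)
  n_edges <- nrow(po$edge)
  root <- po$edge[n_edges, 1]

  # class posteriors restricted to the requested sites
  cpost <- fit$site_posteriors[cols, , drop = FALSE]

  post_arr <- array(0, c(length(nodes), S, 61),
                    dimnames = list(as.character(nodes), as.character(sites),
                                    codon_tables()$codons))
  children <- split(seq_len(n_edges), po$edge[, 1])

  for (cl in seq_len(n_classes)) {
    P <- ep$Ps[[cl]]
    # down pass: partial likelihood of subtree below each node
    down <- vector("list", n_nodes)
    for (tp in seq_len(n_tips)) {
      m <- matrix(0, 61, S)
      for (s in seq_len(S)) {
        if (ts[tp, s] > 0) m[ts[tp, s], s] <- 1 else m[, s] <- 1
      }
      down[[tp]] <- m
    }
    for (e in seq_len(n_edges)) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      if (is.null(down[[p]])) down[[p]] <- matrix(1, 61, S)
      down[[p]] <- down[[p]] * (P[[e]] %*% down[[ch]])
    }
    # up pass: likelihood of the rest of the tree given the node state
    up <- vector("list", n_nodes)
    up[[root]] <- matrix(fit$pi, 61, S)
    for (e in rev(seq_len(n_edges))) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      sib <- setdiff(children[[as.character(p)]], e)
      acc <- up[[p]]
      for (e2 in sib) acc <- acc * (P[[e2]] %*% down[[po$edge[e2, 2]]])
      up[[ch]] <- crossprod(P[[e]], acc)
    }
    for (ni in seq_along(nodes)) {
      g <- up[[nodes[ni]]] * down[[nodes[ni]]]
      g <- sweep(g, 2, colSums(g), "/")
      post_arr[ni, , ] <- post_arr[ni, , ] +
        t(g) * matrix(cpost[, cl], S, 61)
    }
  }

  cods <- codon_tables()$codons
  rows <- do.call(rbind, lapply(seq_along(nodes), function(ni) {
    do.call(rbind, lapply(seq_len(S), function(s) {
      pv <- post_arr[ni, s, ]
      mx <- max(pv)
      topi <- which(pv >= mx - 1e-12)
      map <- min(topi) # lexicographic tie-break (codons sorted)
      data.frame(node = nodes[ni], site = sites[s], map_codon = cods[map],
                 map_aa = translate_codons(cods[map]),
                 posterior = pv[map], tied = length(topi) > 1L)
    }))
  }))
  list(table = rows, posterior = post_arr)
}

#' Ancestral motif report over a set of sites
#'
#' Concatenates the MAP amino acids at the requested sites (in the given
#' order) into a motif per node, with the minimum codon posterior across the
#' sites as an uncertainty summary.
#'
#' @param recon Output of [marginal_reconstruct()] covering all `sites`.
#' @param sites Reference residue numbers (default the rhodopsin 119, 122,
#'   123, 124 coevolving quartet).
#' @return data.frame with `node`, `motif`, `min_posterior`, `any_tied`.
#' @export
motif_report <- function(recon, sites = c(119L, 122L, 123L, 124L)) {
  tb <- recon$table
  miss <- setdiff(sites, unique(tb$site))
  if (length(miss) > 0)
    stop("reconstruction missing site(s): ", paste(miss, collapse = ", "))
  do.call(rbind, lapply(split(tb, tb$node), function(d) {
    d <- d[match(sites, d$site), ]
    data.frame(node = d$node[1], motif = paste(d$map_aa, collapse = ""),
               min_posterior = min(d$posterior), any_tied = any(d$tied))
  }))
}
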