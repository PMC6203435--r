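# Shared fixture builders. Everything is generated in code at test time.

# small codon alignment from explicit codon rows
make_aln <- function(rows, ref_start = 1L) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  codon_alignment(m, ref_start = ref_start)
}

# quartet tree with branch lengths
quartet_tree <- function(bl = c(a = 0.1, b = 0.2, c = 0.15, d = 0.25,
                                ab = 0.05, cd = 0.08)) {
  txt <- sprintf("((a:%g,b:%g):%g,(c:%g,d:%g):%g);",
                 bl["a"], bl["b"], bl["ab"], bl["c"], bl["d"], bl["cd"])
  clade_tree(ape::read.tree(text = txt))
}

# independent enumeration oracle for the codon mixture likelihood on the
# quartet ((a,b),(c,d)): explicit sum over all internal-node states using
# Matrix::expm (independent of the package's eigen-based exponentials).
# mixture omegas must be plain per-class scalars.
quartet_enum_lnL <- function(aln, tree, weights, omegas, kappa, pi,
                             normalize = TRUE) {
  phy <- tree$phy
  stopifnot(length(phy$tip.label) == 4L)
  mu <- if (normalize) {
    rates <- vapply(omegas, function(w) {
      Q <- build_codon_Q(codon_rate_spec(kappa, pi, w), scale = FALSE)
      -sum(pi * diag(Q))
    }, 1)
    sum(weights * rates)
  } else 1
  st <- matrix(coevoscan:::codons_to_states(as.vector(aln$codons)),
               nrow = 4, dimnames = list(aln$taxa, NULL))
  # node ids: tips 1..4 in phy$tip.label order, root 5, internals 6 (a,b), 7 (c,d)
  total <- 0
  n_sites <- aln$n_sites
  idx <- expand.grid(r = 1:61, u = 1:61, v = 1:61)
  for (s in seq_len(n_sites)) {
    site_lik <- 0
    for (cl in seq_along(weights)) {
      Q <- build_codon_Q(codon_rate_spec(kappa, pi, omegas[[cl]]),
                         scale = FALSE) / mu
      P <- lapply(phy$edge.length, function(t)
        as.matrix(Matrix::expm(Q * t)))
      names(P) <- paste(phy$edge[, 1], phy$edge[, 2])
      tipP <- function(node, from_states) {
        lab <- phy$tip.label[node]
        stv <- st[lab, s]
        if (is.na(stv)) rep(1, length(from_states))
        else P[[paste(which_parent(phy, node), node)]][cbind(from_states, stv)]
      }
      which_parent <- function(phy, node) phy$edge[phy$edge[, 2] == node, 1]
      u_par <- which_parent(phy, 1) # internal above tips a,b
      v_par <- which_parent(phy, 3)
      lik <- pi[idx$r] *
        P[[paste(5, u_par)]][cbind(idx$r, idx$u)] *
        P[[paste(5, v_par)]][cbind(idx$r, idx$v)]
      for (tp in 1:2) lik <- lik * {
        stv <- st[phy$tip.label[tp], s]
        if (is.na(stv)) 1 else P[[paste(u_par, tp)]][cbind(idx$u, stv)]
      }
      for (tp in 3:4) lik <- lik * {
        stv <- st[phy$tip.label[tp], s]
        if (is.na(stv)) 1 else P[[paste(v_par, tp)]][cbind(idx$v, stv)]
      }
      site_lik <- site_lik + weights[cl] * sum(lik)
    }
    total <- total + log(site_lik)
  }
  total
}

# enumeration oracle for the 4-state trait likelihood on a 3-leaf tree
# ((a,b),c) with the given branch lengths
pagel_enum_lnL <- function(bl, tx, ty, rates, model, root = "stationary") {
  Q <- pagel_Q(rates, model)
  pivec <- if (root == "stationary") coevoscan:::chain_stationary(Q) else rep(0.25, 4)
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  sidx <- function(x, y) 1 + 2 * x + y
  lik <- 0
  for (r in 1:4) for (u in 1:4) {
    lik <- lik + pivec[r] * P(bl["int"])[r, u] *
      P(bl["c"])[r, sidx(tx["c"], ty["c"])] *
      P(bl["a"])[u, sidx(tx["a"], ty["a"])] *
      P(bl["b"])[u, sidx(tx["b"], ty["b"])]
  }
  log(lik)
}

skip_slow <- function() invisible(TRUE) # all tests run everywhere
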