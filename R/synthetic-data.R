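# Simulators for every input the pipeline consumes: codon alignments under
# site-class mixtures (with optional clade-specific omega shifts and planted
# covarying column pairs), correlated binary traits, retinal-release traces
# and absorbance spectra. All are pure functions of their arguments and seed.

#' Balanced benchmark tree with two named clades
#'
#' Builds a (maximally) balanced rooted topology over `n_taxa` tips split
#' into two equal-as-possible clades named `cladeA` and `cladeB`, assigns
#' Grafen branch lengths rescaled to the requested root-to-tip height, and
#' registers each clade as a partition. This mimics, at desk scale, a
#' two-lineage dataset (e.g. a teleost vs tetrapod split) for clade-model
#' benchmarks.
#'
#' @param n_taxa Total tip count (default 30).
#' @param height Root-to-tip height in expected substitutions per codon
#'   (default 1).
#' @param clade_names Names of the two partitions.
#' @param equal_branches If `TRUE`, every edge gets the same length
#'   (height / tree depth) instead of Grafen lengths; with a power-of-two
#'   tip count this is still ultrametric and makes every branch share one
#'   transition matrix, which speeds up replicated benchmark fits.
#' @return A [clade_tree].
#' @export
sim_balanced_clade_tree <- function(n_taxa = 30L, height = 1,
                                    clade_names = c("cladeA", "cladeB"),
                                    equal_branches = FALSE) {
  stopifnot(n_taxa >= 4L)
  split_newick <- function(labels) {
    n <- length(labels)
    if (n == 1L) return(labels)
    h <- ceiling(n / 2)
    paste0("(", split_newick(labels[1:h]), ",",
           split_newick(labels[(h + 1):n]), ")")
  }
  nA <- ceiling(n_taxa / 2)
  labA <- paste0("A", seq_len(nA))
  labB <- paste0("B", seq_len(n_taxa - nA))
  nwk <- paste0("(", split_newick(labA), ",", split_newick(labB), ");")
  phy <- ape::read.tree(text = nwk)
  if (equal_branches) {
    phy$edge.length <- rep(1, nrow(phy$edge))
  } else {
    phy <- ape::compute.brlen(phy, method = "Grafen")
  }
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth * height
  clade_tree(phy, stats::setNames(
    list(list(type = "clade", taxa = labA),
         list(type = "clade", taxa = labB)),
    clade_names))
}

#' Simulate a codon alignment under a site-class mixture
#'
#' Draws a site class for every column, samples root codons from the
#' stationary frequencies, and evolves them along the tree using the
#' class-specific generator (branch-specific omegas for clade-shifted
#' classes). Generators share the same mixture-average rate normalization as
#' [pruning_lnL()], so simulation and inference use identical branch-length
#' units. The state at the end of each branch is drawn from the exact
#' transition kernel exp(Qt).
#'
#' @param tree A [clade_tree].
#' @param mixture List with `weights` and `omegas` as in [pruning_lnL()]
#'   (clade-shifted classes as `list(background =, <partition> = )`).
#' @param n_sites Number of codon columns.
#' @param kappa Transition/transversion ratio (default 2).
#' @param pi Stationary codon frequencies (default uniform over 61).
#' @param ref_start Reference residue number of the first column.
#' @param seed Optional integer seed.
#' @return List with `aln` (a [codon_alignment]) and `true_class` (integer
#'   vector of the class drawn for each site).
#' @export
simulate_codon_alignment <- function(tree, mixture, n_sites, kappa = 2,
                                     pi = rep(1 / 61, 61), ref_start = 1L,
                                     seed = NULL) {
  stopifnot(inherits(tree, "clade_tree"))
  if (!is.null(seed)) set.seed(seed)
  w <- mixture$weights
  stopifnot(abs(sum(w) - 1) < 1e-8)
  ceo <- resolve_class_edge_omegas(tree, mixture$omegas)
  mu <- mixture_mean_rate(kappa, pi, w, ceo$background_omegas)
  po <- postorder_tree(tree$phy)
  n_edges <- nrow(po$edge)
  n_tips <- po$n_tips
  n_classes <- length(w)

  true_class <- sample.int(n_classes, n_sites, replace = TRUE, prob = w)
  # eigen per distinct omega; P per edge per class on demand
  omat <- matrix(NA_real_, n_edges, n_classes)
  for (cl in seq_len(n_classes)) {
    om <- ceo$class_edge_omega[[cl]]
    omat[, cl] <- if (length(om) == 1L) rep(om, n_edges) else om
  }
  uom <- sort(unique(as.vector(omat)))
  egs <- lapply(uom, function(wm) {
    Q <- build_codon_Q(codon_rate_spec(kappa, pi, wm), scale = FALSE)
    codon_q_eigen(Q, pi)
  })

  n_nodes <- max(po$edge)
  states <- matrix(NA_integer_, n_nodes, n_sites)
  root <- po$edge[n_edges, 1]
  states[root, ] <- sample.int(61, n_sites, replace = TRUE, prob = pi)
  # preorder = reverse postorder
  for (e in rev(seq_len(n_edges))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    t_e <- po$tlen[e] / mu
    states[ch, ] <- states[p, ]
    for (cl in seq_len(n_classes)) {
      idx <- which(true_class == cl)
      if (length(idx) == 0) next
      P <- codon_P(egs[[match(omat[e, cl], uom)]], t_e)
      ps <- states[p, idx]
      for (u in unique(ps)) {
        ii <- idx[ps == u]
        states[ch, ii] <- sample.int(61, length(ii), replace = TRUE, prob = P[u, ])
      }
    }
  }
  cods <- codon_tables()$codons
  m <- matrix(cods[states[seq_len(n_tips), , drop = FALSE]], n_tips, n_sites)
  rownames(m) <- po$phy$tip.label
  list(aln = codon_alignment(m, ref_start = ref_start), true_class = true_class)
}

#' Plant a covarying column pair in a codon alignment
#'
#' Rewrites column `pair[2]` as a residue-level function of column
#' `pair[1]`: each taxon's target residue is `coupling[source residue]`, and
#' the written codon is the lexicographically first codon of that residue.
#' When `noise = 0` and `coupling` is a bijection over the residues present,
#' the amino-acid entropy of the target column equals that of the source
#' column and their mutual information equals that entropy. With
#' `noise > 0`, each taxon independently keeps its original codon with that
#' probability.
#'
#' @param aln A [codon_alignment].
#' @param pair Two reference residue numbers (source, target).
#' @param coupling Named character vector mapping source residues to target
#'   residues. Must be a bijection when `noise = 0`.
#' @param noise Per-taxon probability of keeping the original target codon.
#' @param seed Optional seed (only used when `noise > 0`).
#' @return The modified [codon_alignment].
#' @export
plant_covarying_pair <- function(aln, pair, coupling, noise = 0, seed = NULL) {
  stopifnot(inherits(aln, "codon_alignment"), length(pair) == 2L)
  if (!is.null(seed)) set.seed(seed)
  cols <- site_to_col(aln, pair)
  src_aa <- translate_codons(aln$codons[, cols[1]])
  present <- unique(src_aa[!is.na(src_aa)])
  missing_map <- setdiff(present, names(coupling))
  if (length(missing_map) > 0)
    stop("coupling lacks residues: ", paste(missing_map, collapse = ", "))
  if (noise == 0 && anyDuplicated(coupling[present]))
    stop("coupling must be a residue bijection in exact mode")
  tab <- codon_tables()
  first_codon <- vapply(split(tab$codons, tab$aa), `[`, "", 1)
  keep <- if (noise > 0) stats::runif(length(src_aa)) < noise else rep(FALSE, length(src_aa))
  cur_aa <- translate_codons(aln$codons[, cols[2]])
  for (i in seq_along(src_aa)) {
    if (is.na(src_aa[i]) || keep[i]) next
    target <- coupling[[src_aa[i]]]
    if (identical(cur_aa[i], target)) next # already the target residue
    aln$codons[i, cols[2]] <- first_codon[[target]]
  }
  aln
}

#' Simulate two binary traits on a tree
#'
#' Evolves the joint 4-state chain (states 00, 01, 10, 11 over traits X, Y)
#' along the tree from a root state drawn from the chain's stationary
#' distribution (or uniform). Under the independent model each trait's
#' gain/loss rates are shared across the other trait's states; the dependent
#' model has 8 free rates. Branch-end states are drawn from the exact
#' transition kernel, equivalent in law to event-by-event simulation.
#'
#' @param tree A [clade_tree] or `ape::phylo`.
#' @param rates Numeric rate vector: length 4 for the independent model
#'   (x_gain, x_loss, y_gain, y_loss) or length 8 for the dependent model
#'   (see [pagel_Q()]).
#' @param model `"independent"` or `"dependent"`.
#' @param root `"stationary"` (default) or `"uniform"`.
#' @param seed Optional seed.
#' @return List with named 0/1 integer vectors `x` and `y` over the tips.
#' @export
simulate_binary_traits <- function(tree, rates, model = c("independent", "dependent"),
                                   root = c("stationary", "uniform"), seed = NULL) {
  model <- match.arg(model); root <- match.arg(root)
  if (!is.null(seed)) set.seed(seed)
  phy <- if (inherits(tree, "clade_tree")) tree$phy else tree
  Q <- pagel_Q(rates, model)
  pivec <- if (root == "stationary") chain_stationary(Q) else rep(0.25, 4)
  po <- postorder_tree(phy)
  n_edges <- nrow(po$edge)
  n_nodes <- max(po$edge)
  states <- integer(n_nodes)
  rootn <- po$edge[n_edges, 1]
  states[rootn] <- sample.int(4, 1, prob = pivec)
  for (e in rev(seq_len(n_edges))) {
    P <- as.matrix(Matrix_expm_fallback(Q * po$tlen[e]))
    states[po$edge[e, 2]] <- sample.int(4, 1, prob = P[states[po$edge[e, 1]], ])
  }
  tip <- states[seq_len(po$n_tips)]
  x <- as.integer(tip %in% c(3L, 4L)) # states 10, 11
  y <- as.integer(tip %in% c(2L, 4L)) # states 01, 11
  names(x) <- names(y) <- po$phy$tip.label
  list(x = x, y = y)
}

# small dense matrix exponential (series with scaling and squaring)
Matrix_expm_fallback <- function(M) {
  n <- nrow(M)
  s <- max(0, ceiling(log2(max(1e-16, norm(M, "1")))))
  A <- M / 2^s
  E <- diag(n); term <- diag(n)
  for (k in 1:20) {
    term <- term %*% A / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E[E < 0] <- 0
  E
}

#' Simulate a retinal-release fluorescence trace
#'
#' The first-order exponential rise y = y0 + a (1 - exp(-b t)) sampled on a
#' regular grid (default every 0.5 min, matching 30 s recording intervals)
#' with i.i.d. Gaussian noise.
#'
#' @param y0 Baseline fluorescence.
#' @param a Amplitude.
#' @param b Rate constant (per min), > 0.
#' @param noise_sd Gaussian noise standard deviation.
#' @param t_end Last time point (min; default 60).
#' @param dt Sampling interval (min; default 0.5).
#' @param seed Optional seed.
#' @return data.frame with columns `time_min` and `fluorescence`.
#' @export
simulate_release_trace <- function(y0, a, b, noise_sd = 0, t_end = 60, dt = 0.5,
                                   seed = NULL) {
  stopifnot(b > 0)
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, t_end, by = dt)
  y <- y0 + a * (1 - exp(-b * tt)) + stats::rnorm(length(tt), 0, noise_sd)
  data.frame(time_min = tt, fluorescence = y)
}

#' Simulate an absorbance spectrum from the A1 pigment template
#'
#' @param lambda_max Peak wavelength (nm).
#' @param scale Peak absorbance scale.
#' @param noise_sd Gaussian noise standard deviation (absorbance units).
#' @param grid Wavelength grid in nm (default 350-650 at 1 nm).
#' @param seed Optional seed.
#' @return data.frame with columns `wavelength_nm` and `absorbance`.
#' @export
simulate_spectrum <- function(lambda_max, scale = 1, noise_sd = 0,
                              grid = seq(350, 650, by = 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ab <- scale * a1_template(grid, lambda_max) + stats::rnorm(length(grid), 0, noise_sd)
  data.frame(wavelength_nm = grid, absorbance = ab)
}
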