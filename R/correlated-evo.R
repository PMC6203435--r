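# Pagel-type tests for correlated evolution of two binary traits on a tree,
# with Monte-Carlo (parametric bootstrap) p-values and Bonferroni correction.

#' Joint rate matrix for two binary traits
#'
#' State order is 00, 01, 10, 11 (trait X first, trait Y second); double
#' transitions have rate zero. Under the independent model the 4 rates are
#' (x_gain, x_loss, y_gain, y_loss), shared across the other trait's state.
#' The dependent model has 8 rates, in the order
#' (x_gain|y0, x_gain|y1, x_loss|y0, x_loss|y1,
#'  y_gain|x0, y_gain|x1, y_loss|x0, y_loss|x1).
#'
#' @param rates Positive rate vector of length 4 or 8.
#' @param model `"independent"` or `"dependent"`.
#' @return 4 x 4 rate matrix with rows summing to zero.
#' @export
pagel_Q <- function(rates, model = c("independent", "dependent")) {
  model <- match.arg(model)
  if (any(rates <= 0)) stop("rates must be positive")
  if (model == "independent") {
    if (length(rates) != 4) stop("independent model needs 4 rates")
    r <- rates[c(1, 1, 2, 2, 3, 3, 4, 4)]
  } else {
    if (length(rates) != 8) stop("dependent model needs 8 rates")
    r <- rates
  }
  # r = (xg|y0, xg|y1, xl|y0, xl|y1, yg|x0, yg|x1, yl|x0, yl|x1)
  Q <- matrix(0, 4, 4, dimnames = rep(list(c("00", "01", "10", "11")), 2))
  Q["00", "10"] <- r[1]; Q["01", "11"] <- r[2]
  Q["10", "00"] <- r[3]; Q["11", "01"] <- r[4]
  Q["00", "01"] <- r[5]; Q["10", "11"] <- r[6]
  Q["01", "00"] <- r[7]; Q["11", "10"] <- r[8]
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution of a 4-state chain
chain_stationary <- function(Q) {
  A <- rbind(t(Q), rep(1, 4))
  b <- c(rep(0, 4), 1)
  p <- qr.solve(A, b)
  p <- pmax(p, 0)
  p / sum(p)
}

# tip partial-likelihood columns (4 x n_tips) from two 0/1/NA trait vectors,
# in the tree's tip order; missing states are marginalized
.pagel_tip_partials <- function(phy, trait_x, trait_y) {
  lab <- phy$tip.label
  if (!all(lab %in% names(trait_x)) || !all(lab %in% names(trait_y)))
    stop("trait/tree label mismatch")
  x <- trait_x[lab]; y <- trait_y[lab]
  tp <- matrix(0, 4, length(lab))
  for (i in seq_along(lab)) {
    okx <- if (is.na(x[i])) c(0L, 1L) else x[i]
    oky <- if (is.na(y[i])) c(0L, 1L) else y[i]
    for (xv in okx) for (yv in oky) tp[1L + 2L * xv + yv, i] <- 1
  }
  tp
}

#' Log-likelihood of two binary traits under a Pagel model
#'
#' Joint 4-state continuous-time Markov chain over the trait pair, evaluated
#' by Felsenstein pruning. The root state distribution is the stationary
#' distribution of the chain (default) or uniform.
#'
#' @param tree A [clade_tree] or `ape::phylo`.
#' @param trait_x,trait_y Named 0/1 vectors over the tips (NA = missing,
#'   marginalized).
#' @param rates Rate vector (4 or 8; see [pagel_Q()]).
#' @param model `"independent"` or `"dependent"`.
#' @param root `"stationary"` or `"uniform"`.
#' @return Log-likelihood (numeric scalar).
#' @export
pagel_lnL <- function(tree, trait_x, trait_y, rates,
                      model = c("independent", "dependent"),
                      root = c("stationary", "uniform")) {
  model <- match.arg(model); root <- match.arg(root)
  phy <- if (inherits(tree, "clade_tree")) tree$phy else tree
  Q <- pagel_Q(rates, model)
  pivec <- if (root == "stationary") chain_stationary(Q) else rep(0.25, 4)
  po <- postorder_tree(phy)
  tp <- .pagel_tip_partials(po$phy, trait_x, trait_y)
  edge <- po$edge; storage.mode(edge) <- "integer"
  four_state_pruning_loglik_cpp(tp, edge, po$tlen, Q, pivec)
}

# ML fit of one Pagel model; optimization on log rates, bounded, multistart.
# Tree is rescaled to unit height so rate bounds are scale-free.
fit_pagel_model <- function(phy, trait_x, trait_y, model, n_starts = 3,
                            root = "stationary", rate_bounds = c(1e-6, 100),
                            start_rates = NULL) {
  h <- max(ape::node.depth.edgelength(phy))
  phy2 <- phy
  phy2$edge.length <- phy$edge.length / h
  nr <- if (model == "independent") 4L else 8L
  po <- postorder_tree(phy2)
  tp <- .pagel_tip_partials(po$phy, trait_x, trait_y)
  edge <- po$edge; storage.mode(edge) <- "integer"
  nll <- function(lv) {
    Q <- pagel_Q(exp(lv), model)
    pivec <- if (root == "stationary") chain_stationary(Q) else rep(0.25, 4)
    ll <- four_state_pruning_loglik_cpp(tp, edge, po$tlen, Q, pivec)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  base <- if (is.null(start_rates)) rep(log(1), nr) else log(pmin(pmax(start_rates, rate_bounds[1]), rate_bounds[2]))
  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    v0 <- if (s == 1) base else pmin(pmax(base + stats::rnorm(nr, 0, 1.5), lb), ub)
    f <- tryCatch(stats::nlminb(v0, nll, lower = lb, upper = ub,
                                control = list(rel.tol = 1e-10, iter.max = 400)),
                  error = function(e) NULL)
    if (!is.null(f) && is.finite(f$objective) &&
        (is.null(best) || f$objective < best$objective)) best <- f
  }
  if (is.null(best)) stop("Pagel optimization failed")
  list(lnL = -best$objective, rates = exp(best$par) / h, model = model,
       rates_unit_height = exp(best$par))
}

#' Monte-Carlo test of correlated evolution (Pagel)
#'
#' Fits the independent (4-rate) and dependent (8-rate) models by maximum
#' likelihood, then calibrates the likelihood-ratio statistic by parametric
#' bootstrap: `n_sim` trait pairs are simulated on the same tree under the
#' independent model at its MLEs, both models are refitted to each
#' replicate, and p_mc = (1 + #\{simulated LRT >= observed\}) / (n_sim + 1).
#' The asymptotic chi-square p (df 4) is reported alongside for reference.
#'
#' @param tree A [clade_tree] or `ape::phylo`.
#' @param trait_x,trait_y Named 0/1 trait vectors over the tips.
#' @param n_sim Number of bootstrap replicates (default 1000).
#' @param n_starts Restarts for the observed-data fits (default 5; replicate
#'   fits start from the generating rates plus one random restart).
#' @param root Root-state rule (`"stationary"` default).
#' @param seed Optional seed.
#' @return An object of class `pagel_fit`: list with `lnL_indep`, `lnL_dep`,
#'   `rates_indep`, `rates_dep`, `lrt_stat`, `p_mc`, `p_asymptotic`,
#'   `n_sim`, `untestable`.
#' @export
pagel_mc_test <- function(tree, trait_x, trait_y, n_sim = 1000, n_starts = 5,
                          root = "stationary", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- if (inherits(tree, "clade_tree")) tree$phy else tree
  mono <- function(v) length(unique(v[!is.na(v)])) < 2L
  if (mono(trait_x) || mono(trait_y)) {
    return(structure(list(untestable = TRUE,
                          reason = "monomorphic trait: test undefined",
                          lnL_indep = NA, lnL_dep = NA, lrt_stat = NA,
                          p_mc = NA, p_asymptotic = NA, n_sim = 0L),
                     class = "pagel_fit"))
  }
  h <- max(ape::node.depth.edgelength(phy))
  phy2 <- phy
  phy2$edge.length <- phy$edge.length / h
  po <- postorder_tree(phy2)
  tp <- .pagel_tip_partials(po$phy, trait_x, trait_y)
  edge <- po$edge; storage.mode(edge) <- "integer"
  lb <- log(1e-6); ub <- log(100)
  stationary <- root == "stationary"
  # identical optimizer budget for the observed fits and the bootstrap
  # replicate fits, so the observed statistic is exchangeable with the
  # simulated ones
  maxit <- 80; ftol <- 1e-7
  starts4 <- cbind(rep(0, 4),
                   matrix(stats::rnorm(4 * max(0, n_starts - 1), 0, 1.5), 4))
  starts4 <- pmin(pmax(starts4, lb), ub)
  fi <- pagel_fit_nm_cpp(tp, edge, po$tlen, TRUE, starts4, stationary, lb, ub,
                         maxit = maxit, ftol = ftol)
  exp_idx <- c(1, 1, 2, 2, 3, 3, 4, 4)
  starts8 <- cbind(fi$lograates[exp_idx],
                   matrix(fi$lograates[exp_idx] +
                            stats::rnorm(8 * max(0, n_starts - 1), 0, 1.5), 8))
  starts8 <- pmin(pmax(starts8, lb), ub)
  fd <- pagel_fit_nm_cpp(tp, edge, po$tlen, FALSE, starts8, stationary, lb, ub,
                         maxit = maxit, ftol = ftol)
  if (fd$lnL < fi$lnL) { # dependent nests independent; enforce
    fd$lnL <- fi$lnL
    fd$lograates <- fi$lograates[exp_idx]
  }
  obs <- max(0, 2 * (fd$lnL - fi$lnL))
  sim_stats <- pagel_bootstrap_cpp(edge, po$tlen, length(phy$tip.label),
                                   as.numeric(fi$lograates), stationary,
                                   as.integer(n_sim), lb, ub,
                                   maxit = maxit, ftol = ftol)
  ge <- sum(sim_stats >= obs - 1e-9)
  structure(list(untestable = FALSE,
                 lnL_indep = fi$lnL, lnL_dep = fd$lnL,
                 rates_indep = exp(as.numeric(fi$lograates)) / h,
                 rates_dep = exp(as.numeric(fd$lograates)) / h,
                 lrt_stat = obs, p_mc = (1 + ge) / (n_sim + 1),
                 p_asymptotic = stats::pchisq(obs, 4, lower.tail = FALSE),
                 n_sim = as.integer(n_sim)),
            class = "pagel_fit")
}

#' @export
print.pagel_fit <- function(x, ...) {
  if (isTRUE(x$untestable)) {
    cat("pagel_fit: untestable (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("pagel_fit: LRT =", signif(x$lrt_stat, 4),
      " p_mc =", signif(x$p_mc, 3),
      " (n_sim =", x$n_sim, "; asymptotic p =", signif(x$p_asymptotic, 3), ")\n")
  invisible(x)
}

#' Bonferroni correction for a family of tests
#'
#' @param p_values Numeric p-values in [0, 1].
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `threshold` (= alpha / m), `m`, `significant` (logical,
#'   p < threshold; NA p-values stay NA).
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m < 1) stop("need at least one p-value")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  thr <- alpha / m
  list(threshold = thr, m = m, significant = p_values < thr)
}
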