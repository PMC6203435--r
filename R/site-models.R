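# Maximum-likelihood fitting of codon site-class models (M-series) and
# Clade Model C, with LRT/AIC comparison and empirical-Bayes site
# classification.

.SITE_MODELS <- c("M0", "M1a", "M2a", "M3", "M7", "M8", "M8a", "M2a_rel", "CmC")

# ---- parameterization ------------------------------------------------------
# Each model is described by natural-scale parameters; fitting happens on an
# unconstrained transform: proportions via softmax against the last class,
# (0,1) omegas via logit, positive parameters via log, and omega_p >= 1 in
# M8 via 1 + exp(u).

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(u) 1 / (1 + exp(-u))
# beta shape parameters bounded in [0.005, 100] on the log scale
.BETA_LO <- log(0.005); .BETA_HI <- log(100)
.to_beta <- function(x) .logit((log(pmin(pmax(x, 0.00501), 99.9)) - .BETA_LO) /
                                 (.BETA_HI - .BETA_LO))
.from_beta <- function(u) exp(.BETA_LO + (.BETA_HI - .BETA_LO) * .inv_logit(u))

# default natural-scale starting parameters
model_start <- function(model_id, n_fg = 0L) {
  switch(model_id,
    M0      = list(omega = 0.2),
    M1a     = list(p0 = 0.8, w0 = 0.1),
    M2a     = list(p0 = 0.75, p1 = 0.2, w0 = 0.1, w2 = 2),
    M3      = list(p0 = 0.5, p1 = 0.3, w0 = 0.05, w1 = 0.3, w2 = 1.2),
    M7      = list(p = 0.5, q = 2),
    M8      = list(p0 = 0.9, p = 0.5, q = 2, wp = 1.5),
    M8a     = list(p0 = 0.9, p = 0.5, q = 2),
    M2a_rel = list(p0 = 0.6, p1 = 0.1, w0 = 0.05, w2 = 0.3),
    CmC     = c(list(p0 = 0.6, p1 = 0.1, w0 = 0.05, wd_bg = 0.3),
                stats::setNames(as.list(rep(0.15, n_fg)),
                                paste0("wd_fg", seq_len(n_fg)))),
    stop("unknown model: ", model_id))
}

# number of free mixture parameters (excluding kappa and branch lengths)
mixture_df <- function(model_id, n_fg = 0L) {
  switch(model_id,
    M0 = 1L, M1a = 2L, M2a = 4L, M3 = 5L, M7 = 2L, M8 = 4L, M8a = 3L,
    M2a_rel = 4L, CmC = 4L + as.integer(n_fg),
    stop("unknown model: ", model_id))
}

#' Free-parameter count of a site-class model fit
#'
#' Counts every free parameter identically across models: the mixture
#' parameters (class proportions, class omegas, beta shape parameters), the
#' transition/transversion ratio kappa, and one parameter per branch length.
#' Differences of these counts give the degrees of freedom of nested-model
#' comparisons (Clade Model C with one foreground vs M2a_rel: 1; two
#' foregrounds: 2; M8 vs M7: 2; M8 vs M8a: 1).
#'
#' @param model_id One of `r paste(.SITE_MODELS, collapse=", ")`.
#' @param n_edges Number of branches in the tree.
#' @param n_fg Number of foreground partitions (CmC only).
#' @return Integer parameter count.
#' @export
count_free_params <- function(model_id, n_edges, n_fg = 0L) {
  mixture_df(model_id, n_fg) + 1L + as.integer(n_edges)
}

# natural parameters -> unconstrained vector
par_to_vec <- function(model_id, par, kappa, scale) {
  v <- switch(model_id,
    M0      = log(par$omega),
    M1a     = c(.logit(par$p0), .logit(par$w0)),
    M2a     = c(log(par$p0 / (1 - par$p0 - par$p1)),
                log(par$p1 / (1 - par$p0 - par$p1)),
                .logit(par$w0), log(pmax(par$w2 - 1, 1e-6))),
    M3      = c(log(par$p0 / (1 - par$p0 - par$p1)),
                log(par$p1 / (1 - par$p0 - par$p1)),
                log(par$w0 + 1e-8), log(par$w1 + 1e-8), log(par$w2 + 1e-8)),
    M7      = c(.to_beta(par$p), .to_beta(par$q)),
    M8      = c(.logit(par$p0), .to_beta(par$p), .to_beta(par$q),
                log(pmax(par$wp - 1, 1e-6))),
    M8a     = c(.logit(par$p0), .to_beta(par$p), .to_beta(par$q)),
    M2a_rel = c(log(par$p0 / (1 - par$p0 - par$p1)),
                log(par$p1 / (1 - par$p0 - par$p1)),
                .logit(par$w0), log(par$w2 + 1e-8)),
    CmC     = {
      fg <- grep("^wd_fg", names(par), value = TRUE)
      c(log(par$p0 / (1 - par$p0 - par$p1)),
        log(par$p1 / (1 - par$p0 - par$p1)),
        .logit(par$w0), log(par$wd_bg + 1e-8),
        log(unlist(par[fg]) + 1e-8))
    })
  c(v, log(kappa), log(scale))
}

# unconstrained vector -> natural parameters
vec_to_par <- function(model_id, v, n_fg = 0L) {
  k <- length(v)
  kappa <- exp(v[k - 1]); scale <- exp(v[k])
  w <- v[seq_len(k - 2)]
  soft3 <- function(a, b) {
    m <- max(a, b, 0)
    e <- c(exp(a - m), exp(b - m), exp(-m))
    p <- e / sum(e)
    list(p0 = p[1], p1 = p[2])
  }
  par <- switch(model_id,
    M0      = list(omega = exp(w[1])),
    M1a     = list(p0 = .inv_logit(w[1]), w0 = .inv_logit(w[2])),
    M2a     = c(soft3(w[1], w[2]), list(w0 = .inv_logit(w[3]), w2 = 1 + exp(w[4]))),
    M3      = c(soft3(w[1], w[2]),
                list(w0 = exp(w[3]), w1 = exp(w[4]), w2 = exp(w[5]))),
    M7      = list(p = .from_beta(w[1]), q = .from_beta(w[2])),
    M8      = list(p0 = .inv_logit(w[1]), p = .from_beta(w[2]), q = .from_beta(w[3]),
                   wp = 1 + exp(w[4])),
    M8a     = list(p0 = .inv_logit(w[1]), p = .from_beta(w[2]), q = .from_beta(w[3])),
    M2a_rel = c(soft3(w[1], w[2]), list(w0 = .inv_logit(w[3]), w2 = exp(w[4]))),
    CmC     = {
      p <- c(soft3(w[1], w[2]), list(w0 = .inv_logit(w[3]), wd_bg = exp(w[4])))
      if (n_fg > 0) {
        fg <- as.list(exp(w[4 + seq_len(n_fg)]))
        names(fg) <- paste0("wd_fg", seq_len(n_fg))
        p <- c(p, fg)
      }
      p
    })
  list(par = par, kappa = kappa, scale = scale)
}

# beta discretization: K equal-probability categories, median per bin
beta_categories <- function(p, q, K) {
  stats::qbeta((2 * seq_len(K) - 1) / (2 * K), p, q)
}

# class weights and per-class omega specs for a model at given parameters.
# fg_names: partition labels (CmC); n_beta_cat: beta discretization count.
model_classes <- function(model_id, par, fg_names = character(0), n_beta_cat = 10L) {
  K <- n_beta_cat
  switch(model_id,
    M0 = list(weights = 1, omegas = list(par$omega)),
    M1a = list(weights = c(par$p0, 1 - par$p0), omegas = list(par$w0, 1)),
    M2a = list(weights = c(par$p0, par$p1, 1 - par$p0 - par$p1),
               omegas = list(par$w0, 1, par$w2)),
    M3 = list(weights = c(par$p0, par$p1, 1 - par$p0 - par$p1),
              omegas = list(par$w0, par$w1, par$w2)),
    M7 = list(weights = rep(1 / K, K),
              omegas = as.list(beta_categories(par$p, par$q, K))),
    M8 = list(weights = c(rep(par$p0 / K, K), 1 - par$p0),
              omegas = c(as.list(beta_categories(par$p, par$q, K)), list(par$wp))),
    M8a = list(weights = c(rep(par$p0 / K, K), 1 - par$p0),
               omegas = c(as.list(beta_categories(par$p, par$q, K)), list(1))),
    M2a_rel = list(weights = c(par$p0, par$p1, 1 - par$p0 - par$p1),
                   omegas = list(par$w0, 1, par$w2)),
    CmC = {
      div <- c(list(background = par$wd_bg),
               stats::setNames(lapply(seq_along(fg_names),
                                      function(i) par[[paste0("wd_fg", i)]]),
                               fg_names))
      list(weights = c(par$p0, par$p1, 1 - par$p0 - par$p1),
           omegas = list(par$w0, 1, div))
    })
}

# ---- fitting ---------------------------------------------------------------

# Precomputed evaluation context: postorder tree, tip states, partition edge
# indices (postorder order) and codon structure masks. Everything the
# objective needs that does not change across evaluations.
.make_fit_context <- function(aln, ct, pi, fg_names) {
  po <- postorder_tree(ct$phy)
  ts <- tipstate_matrix(aln, po$phy)
  storage.mode(po$edge) <- "integer"
  key <- paste(ct$phy$edge[, 1], ct$phy$edge[, 2])
  pokey <- paste(po$edge[, 1], po$edge[, 2])
  part_edges <- lapply(resolve_partition_edges(ct),
                       function(e) match(key[e], pokey))
  part_edges <- part_edges[fg_names]
  masks <- .codon_masks(codon_tables())
  # site-pattern compression: identical columns evaluated once
  pat_key <- apply(ts, 2, paste, collapse = ",")
  upat <- !duplicated(pat_key)
  pattern_index <- match(pat_key, pat_key[upat])
  ts_u <- ts[, upat, drop = FALSE]
  pattern_weights <- tabulate(pattern_index, nbins = ncol(ts_u))
  list(po = po, ts = ts_u, pattern_index = pattern_index,
       pattern_weights = pattern_weights, part_edges = part_edges, pi = pi,
       masks = masks, n_edges = nrow(po$edge))
}

# class/site log-likelihoods and total lnL at given natural parameters
.ctx_logliks <- function(ctx, cls, kappa, scale, fg_names) {
  n_edges <- ctx$n_edges
  n_classes <- length(cls$weights)
  omat <- matrix(NA_real_, n_edges, n_classes)
  bg <- numeric(n_classes)
  for (cl in seq_len(n_classes)) {
    om <- cls$omegas[[cl]]
    if (is.list(om)) {
      v <- rep(om$background, n_edges)
      for (pn in setdiff(names(om), "background"))
        v[ctx$part_edges[[pn]]] <- om[[pn]]
      omat[, cl] <- v
      bg[cl] <- om$background
    } else {
      omat[, cl] <- om
      bg[cl] <- om
    }
  }
  uom <- sort(unique(as.vector(omat)))
  eg <- codon_eigen_set_cpp(kappa, uom, ctx$pi, ctx$masks$diff,
                            ctx$masks$ts, ctx$masks$ns)
  mu <- sum(cls$weights * eg$rates[match(bg, uom)])
  qmap <- matrix(match(as.vector(omat), uom), n_edges, n_classes)
  storage.mode(qmap) <- "integer"
  sl <- mixture_pruning_loglik_cpp(ctx$ts, ctx$po$edge,
                                   ctx$po$tlen * scale / mu,
                                   eg$A, eg$B, eg$lam, qmap, ctx$pi)
  lw <- log(cls$weights)
  m <- apply(sl, 2, max)
  per_pattern <- m + log(colSums(exp(sweep(sl + lw, 2, m, "-"))))
  list(site_logliks = sl[, ctx$pattern_index, drop = FALSE],
       lnL = sum(ctx$pattern_weights * per_pattern))
}

# negative log-likelihood at an unconstrained parameter vector
.site_model_nll <- function(v, model_id, ctx, fg_names, n_beta_cat) {
  np <- vec_to_par(model_id, v, n_fg = length(fg_names))
  cls <- model_classes(model_id, np$par, fg_names, n_beta_cat)
  ll <- tryCatch(.ctx_logliks(ctx, cls, np$kappa, np$scale, fg_names)$lnL,
                 error = function(e) NA_real_)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a random-sites codon model by maximum likelihood
#'
#' Fits one of the site-class models M0, M1a, M2a, M3, M7, M8, M8a or
#' M2a_rel to a codon alignment on a fixed tree topology. Free parameters
#' are the class proportions and omegas (or beta shape parameters), kappa,
#' and a single branch-length scale factor; they are maximized with a
#' bounded quasi-Newton optimizer on transformed parameters, from
#' `n_starts` starting points (the default heuristic start plus random
#' perturbations). Per-site class posteriors are computed by naive
#' empirical Bayes at the MLEs.
#'
#' @param aln A [codon_alignment].
#' @param tree A [clade_tree].
#' @param model_id Model name.
#' @param options List of options: `n_starts` (default 3), `n_beta_cat`
#'   (beta discretization, default 10), `freq` ("F3x4" default, or "F61"),
#'   `kappa_start`, `scale_start`, `start` (natural-parameter list
#'   overriding the heuristic first start), `rel_tol`.
#' @return An object of class `site_class_fit` with elements `model_id`,
#'   `lnL`, `params`, `kappa`, `scale`, `pi`, `n_free_params`, `aic`,
#'   `site_posteriors`, `site_mean_omega`, `class_omegas`, `weights`,
#'   `converged`, `flags`.
#' @export
fit_site_model <- function(aln, tree, model_id, options = list()) {
  stopifnot(model_id %in% setdiff(.SITE_MODELS, "CmC"))
  .fit_codon_mixture(aln, tree, model_id, character(0), options)
}

#' Fit Clade Model C
#'
#' Three site classes: class 0 (0 < omega0 < 1) and class 1 (omega = 1)
#' shared across the tree, and a divergent class whose omega takes a
#' separate value in each named foreground partition and in the background.
#' Constraining all divergent omegas equal recovers M2a_rel, so the
#' CmC-vs-M2a_rel LRT has one degree of freedom per foreground partition.
#' The per-site posterior of membership in the divergent class is reported
#' (empirical Bayes at the MLEs).
#'
#' @param aln A [codon_alignment].
#' @param tree A [clade_tree] with at least one named partition.
#' @param partitions Partition labels to use as foregrounds (default: all
#'   partitions of `tree`).
#' @param options See [fit_site_model()].
#' @return A `site_class_fit` (with `divergent_posterior` in the report).
#' @export
fit_clade_model_C <- function(aln, tree, partitions = NULL, options = list()) {
  if (is.null(partitions)) partitions <- names(tree$partitions)
  if (length(partitions) < 1L) stop("CmC needs at least one named partition")
  unknown <- setdiff(partitions, names(tree$partitions))
  if (length(unknown) > 0)
    stop("unknown partition(s): ", paste(unknown, collapse = ", "))
  .fit_codon_mixture(aln, tree, "CmC", partitions, options)
}

.fit_codon_mixture <- function(aln, tree, model_id, fg_names, options) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "clade_tree"))
  opts <- utils::modifyList(
    list(n_starts = 3L, n_beta_cat = 10L, freq = "F3x4",
         kappa_start = 2, scale_start = 1, start = NULL, rel_tol = 1e-10,
         fix_kappa = NULL),
    options)
  if (!is.null(opts$fix_kappa)) opts$kappa_start <- opts$fix_kappa
  pi <- switch(opts$freq, F3x4 = f3x4_frequencies(aln),
               F61 = f61_frequencies(aln),
               stop("freq must be 'F3x4' or 'F61'"))
  n_fg <- length(fg_names)
  st <- codons_to_states(as.vector(aln$codons))
  stm <- matrix(st, nrow = length(aln$taxa))
  invariant <- all(apply(stm, 2, function(col) {
    u <- unique(col[!is.na(col)]); length(u) <= 1L
  }))

  start0 <- model_start(model_id, n_fg)
  if (!is.null(opts$start)) start0 <- utils::modifyList(start0, opts$start)
  v0 <- par_to_vec(model_id, start0, opts$kappa_start, opts$scale_start)
  # deterministic alternate starts at informative boundaries: M8 from the
  # near-M8a corner (wp ~ 1), CmC from the no-divergence corner
  alt <- switch(model_id,
    M8 = list(utils::modifyList(start0, list(wp = 1 + 1e-4, p0 = 0.98))),
    CmC = list(utils::modifyList(start0, stats::setNames(
      as.list(rep(start0$wd_bg, n_fg)), paste0("wd_fg", seq_len(n_fg))))),
    list())
  valt <- lapply(alt, par_to_vec, model_id = model_id,
                 kappa = opts$kappa_start, scale = opts$scale_start)

  ctx <- .make_fit_context(aln, tree, pi, fg_names)
  # optionally hold kappa fixed (e.g. at an M0 estimate): drop its
  # coordinate from the optimization vector
  kap_idx <- length(v0) - 1L
  free_idx <- if (is.null(opts$fix_kappa)) seq_along(v0) else setdiff(seq_along(v0), kap_idx)
  expand_v <- function(vf) {
    v <- v0
    v[free_idx] <- vf
    v
  }
  nll_free <- function(vf, ...) .site_model_nll(expand_v(vf), ...)
  best <- NULL
  lnls <- numeric(0)
  for (s in seq_len(max(1L, opts$n_starts))) {
    v <- if (s == 1L) v0
    else if (s - 1L <= length(valt)) valt[[s - 1L]]
    else v0 + stats::rnorm(length(v0), 0, 0.7)
    if (!is.null(opts$fix_kappa)) v[kap_idx] <- log(opts$fix_kappa)
    fit <- tryCatch(
      stats::nlminb(v[free_idx], nll_free, model_id = model_id, ctx = ctx,
                    fg_names = fg_names, n_beta_cat = opts$n_beta_cat,
                    control = list(rel.tol = opts$rel_tol, iter.max = 500,
                                   eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    lnls <- c(lnls, -fit$objective)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("optimization failed for model ", model_id,
                          " after ", opts$n_starts, " starts")
  converged <- best$convergence == 0 ||
    (length(lnls) >= 2 && diff(range(tail(sort(lnls), 2))) < 1e-4)

  np <- vec_to_par(model_id, expand_v(best$par), n_fg)
  cls <- model_classes(model_id, np$par, fg_names, opts$n_beta_cat)
  lk <- .ctx_logliks(ctx, cls, np$kappa, np$scale, fg_names)
  ll <- lk$lnL
  post <- neb_posteriors(lk$site_logliks, cls$weights)
  class_om_num <- vapply(cls$omegas, function(o) {
    if (is.list(o)) o$background else o
  }, 1.0)
  mean_om <- as.numeric(post %*% class_om_num)
  n_edges <- nrow(tree$phy$edge)
  k <- count_free_params(model_id, n_edges, n_fg)
  flags <- character(0)
  if (invariant) flags <- c(flags, "identifiability: alignment invariant, omega not estimable")
  if (!converged) flags <- c(flags, "convergence not confirmed across restarts")
  if (model_id %in% c("CmC")) flags <- c(flags, "site classification: naive empirical Bayes at the MLEs")

  structure(list(
    model_id = model_id, fg_names = fg_names,
    lnL = as.numeric(ll), params = np$par, kappa = np$kappa,
    scale = np$scale, pi = pi, weights = cls$weights,
    class_omegas = cls$omegas, n_beta_cat = opts$n_beta_cat,
    n_free_params = k, aic = 2 * k - 2 * as.numeric(ll),
    site_posteriors = post, site_mean_omega = mean_om,
    ref_map = aln$ref_map, n_edges = n_edges,
    converged = converged, n_starts_used = length(lnls), flags = flags),
    class = "site_class_fit")
}

#' @export
print.site_class_fit <- function(x, ...) {
  cat("site_class_fit:", x$model_id,
      if (length(x$fg_names)) paste0("(foreground: ", paste(x$fg_names, collapse = ", "), ")"),
      "\n  lnL =", format(x$lnL, nsmall = 2),
      " k =", x$n_free_params, " AIC =", format(x$aic, nsmall = 2), "\n")
  pstr <- paste(names(x$params), signif(unlist(x$params), 3), sep = "=", collapse = ", ")
  cat("  params:", pstr, "| kappa =", signif(x$kappa, 3),
      "| scale =", signif(x$scale, 3), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Likelihood-ratio test of nested site-class fits
#'
#' @param fit_alt,fit_null Fitted models (`site_class_fit`), null nested in
#'   alternative.
#' @param df Degrees of freedom; default is the difference in free-parameter
#'   counts.
#' @param tol Tolerance for detecting `lnL_alt < lnL_null` (an optimization
#'   failure; default 1e-4).
#' @return List with `statistic` (2 dlnL, clipped at 0), `df`, `p` (chi-square
#'   upper tail).
#' @export
lrt <- function(fit_alt, fit_null, df = NULL, tol = 1e-4) {
  la <- if (is.list(fit_alt)) fit_alt$lnL else fit_alt
  ln <- if (is.list(fit_null)) fit_null$lnL else fit_null
  if (is.null(df)) {
    df <- fit_alt$n_free_params - fit_null$n_free_params
  }
  if (df < 1) stop("df must be >= 1")
  if (la < ln - tol)
    stop("alternative lnL below null lnL (", la, " < ", ln,
         "): optimization failure")
  stat <- max(0, 2 * (la - ln))
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' AIC differences relative to the best model
#'
#' AIC = 2k - 2 lnL; every fit's AIC difference from the minimum-AIC fit.
#'
#' @param fits List of `site_class_fit` objects (or lists with `lnL` and
#'   `n_free_params`), length >= 2, optionally named.
#' @return Named numeric vector of dAIC values (best model 0).
#' @export
delta_aic <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits")
  aic <- vapply(fits, function(f) 2 * f$n_free_params - 2 * f$lnL, 1.0)
  out <- aic - min(aic)
  if (!is.null(names(fits))) names(out) <- names(fits)
  out
}

#' Per-site empirical-Bayes classification report
#'
#' Tabulates, for every codon site, the posterior probability of each site
#' class and the posterior-mean omega (for Clade Model C, the background
#' divergent-class omega enters the mean, and the divergent-class posterior
#' is reported separately).
#'
#' @param fit A `site_class_fit` from [fit_site_model()] or
#'   [fit_clade_model_C()].
#' @return data.frame with columns `site` (reference numbering), one
#'   `post_class*` column per class, `mean_omega`, and for CmC
#'   `divergent_posterior`.
#' @export
site_posterior_report <- function(fit) {
  stopifnot(inherits(fit, "site_class_fit"))
  post <- fit$site_posteriors
  df <- data.frame(site = fit$ref_map)
  for (k in seq_len(ncol(post))) df[[paste0("post_class", k - 1)]] <- post[, k]
  df$mean_omega <- fit$site_mean_omega
  if (fit$model_id == "CmC") df$divergent_posterior <- post[, ncol(post)]
  if (fit$model_id == "M8") df$positive_posterior <- post[, ncol(post)]
  df
}
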