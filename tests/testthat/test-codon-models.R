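# Rate-matrix structure, likelihood oracles, and model-comparison
# bookkeeping for the codon site-class machinery.

pi_unif <- rep(1 / 61, 61)

test_that("codon rate matrix has GY94 structure", {
  set.seed(1)
  pi <- f3x4_frequencies(simulate_codon_alignment(
    sim_balanced_clade_tree(4), list(weights = 1, omegas = 0.5),
    n_sites = 50, seed = 2)$aln)
  Q <- build_codon_Q(codon_rate_spec(kappa = 3, pi = pi, omega = 0.4))
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # mean rate 1 at stationarity
  expect_lt(abs(-sum(pi * diag(Q)) - 1), 1e-12)
  # detailed balance pi_i q_ij = pi_j q_ji over all pairs
  F <- pi * Q
  expect_lt(max(abs(F - t(F))), 1e-14)
  # multi-nucleotide changes have rate zero
  tab <- coevoscan:::codon_tables()
  expect_true(all(Q[tab$diffpos == 0L & !diag(61)] == 0))
  # omega = 0 kills all nonsynonymous rates
  Q0 <- build_codon_Q(codon_rate_spec(2, pi, 0), scale = FALSE)
  expect_true(all(Q0[tab$is_ns & tab$diffpos > 0L] == 0))
  expect_error(codon_rate_spec(2, rep(1, 61), 0.5), "sum")
})

test_that("degenerate likelihoods reduce to stationary log-frequencies", {
  aln <- make_aln(list(a = "GAA", b = "GAA"))
  i <- which(sense_codons() == "GAA")
  # two identical taxa joined by total branch length 0
  ct0 <- clade_tree(ape::read.tree(text = "(a:0,b:0);"))
  ll <- pruning_lnL(aln, ct0, list(weights = 1, omegas = 0.5),
                    kappa = 2, pi = pi_unif)
  expect_equal(as.numeric(ll), log(pi_unif[i]), tolerance = 1e-10)
})

test_that("pruning likelihood matches full state enumeration on a quartet", {
  set.seed(7)
  ct <- quartet_tree()
  sim <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.5),
                                  n_sites = 3, kappa = 2, seed = 8)
  aln <- sim$aln
  aln$codons["b", 2] <- "---" # exercise missing data
  for (mix in list(list(weights = 1, omegas = list(0.5)),
                   list(weights = c(0.6, 0.4), omegas = list(0.1, 1.7)))) {
    ll <- pruning_lnL(aln, ct, mix, kappa = 2, pi = pi_unif)
    oracle <- quartet_enum_lnL(aln, ct, mix$weights, mix$omegas,
                               kappa = 2, pi = pi_unif)
    expect_equal(as.numeric(ll), oracle, tolerance = 1e-8)
  }
})

test_that("likelihood evaluation rejects taxon mismatches", {
  aln <- make_aln(list(a = "GAA", b = "GAA", z = "GAA"))
  ct <- clade_tree(ape::read.tree(text = "((a:1,b:1):1,c:1);"))
  expect_error(pruning_lnL(aln, ct, list(weights = 1, omegas = 1),
                           pi = pi_unif),
               "taxon mismatch")
})

test_that("nested models never lose likelihood and flags fire", {
  set.seed(11)
  ct <- sim_balanced_clade_tree(8, height = 1)
  sim <- simulate_codon_alignment(ct, list(weights = c(0.7, 0.3),
                                           omegas = list(0.05, 0.8)),
                                  n_sites = 120, seed = 12)
  opts <- list(n_starts = 3, n_beta_cat = 4)
  f7 <- fit_site_model(sim$aln, ct, "M7", opts)
  f8a <- fit_site_model(sim$aln, ct, "M8a", opts)
  f8 <- fit_site_model(sim$aln, ct, "M8", opts)
  expect_gte(f8$lnL, f7$lnL - 1e-6)
  expect_gte(f8$lnL, f8a$lnL - 1e-6)
  # posteriors sum to one per site
  expect_lt(max(abs(rowSums(f8$site_posteriors) - 1)), 1e-8)
  # invariant alignment flags unidentifiable omega
  alni <- make_aln(list(a = c("GAA", "ATG"), b = c("GAA", "ATG"),
                        c = c("GAA", "ATG"), d = c("GAA", "ATG")))
  ct4 <- quartet_tree()
  fi <- fit_site_model(alni, ct4, "M0", list(n_starts = 1))
  expect_true(any(grepl("identifiability", fi$flags)))
})

test_that("CmC constrained to equal divergent omegas reproduces M2a_rel", {
  set.seed(13)
  ct <- sim_balanced_clade_tree(8, height = 1)
  sim <- simulate_codon_alignment(ct, list(weights = c(0.6, 0.1, 0.3),
                                           omegas = list(0.03, 1, 0.4)),
                                  n_sites = 150, seed = 14)
  frel <- fit_site_model(sim$aln, ct, "M2a_rel", list(n_starts = 2))
  # evaluate the CmC likelihood at the M2a_rel solution with wd_fg == wd_bg
  mix <- list(weights = c(frel$params$p0, frel$params$p1,
                          1 - frel$params$p0 - frel$params$p1),
              omegas = list(frel$params$w0, 1,
                            list(background = frel$params$w2,
                                 cladeA = frel$params$w2)))
  ll <- pruning_lnL(sim$aln, ct, mix, kappa = frel$kappa, pi = frel$pi,
                    scale = frel$scale)
  expect_equal(as.numeric(ll), frel$lnL, tolerance = 1e-4)
})

test_that("free-parameter bookkeeping gives the expected test df", {
  n_edges <- 57
  expect_equal(count_free_params("CmC", n_edges, n_fg = 1) -
                 count_free_params("M2a_rel", n_edges), 1L)
  expect_equal(count_free_params("CmC", n_edges, n_fg = 2) -
                 count_free_params("M2a_rel", n_edges), 2L)
  expect_equal(count_free_params("M8", n_edges) -
                 count_free_params("M7", n_edges), 2L)
  expect_equal(count_free_params("M8", n_edges) -
                 count_free_params("M8a", n_edges), 1L)
  expect_equal(count_free_params("M2a", n_edges) -
                 count_free_params("M1a", n_edges), 2L)
})

test_that("likelihood-ratio test matches the chi-square oracle", {
  f_alt <- list(lnL = -100, n_free_params = 5)
  f_null <- list(lnL = -100, n_free_params = 4)
  r <- lrt(f_alt, f_null, df = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r2 <- lrt(list(lnL = -100 + 3.841 / 2, n_free_params = 5), f_null, df = 1)
  expect_equal(r2$p, stats::pchisq(3.841, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(r2$p, 3), 0.05)
  expect_error(lrt(list(lnL = -101, n_free_params = 5), f_null, df = 1),
               "optimization failure")
})

test_that("AIC differences rank models against the minimum", {
  a <- list(lnL = -47069.60, n_free_params = 10)
  b <- list(lnL = -47073.06, n_free_params = 9)
  expect_equal(unname(delta_aic(list(a, b))[2]), 4.92, tolerance = 1e-9)
  expect_equal(delta_aic(list(x = a, y = a)), c(x = 0, y = 0))
  expect_error(delta_aic(list(a)), "two fits")
})

test_that("single-class fits put every site in the only class", {
  set.seed(15)
  ct <- quartet_tree()
  sim <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.4),
                                  n_sites = 30, seed = 16)
  f0 <- fit_site_model(sim$aln, ct, "M0", list(n_starts = 1))
  rep0 <- site_posterior_report(f0)
  expect_true(all(rep0$post_class0 == 1))
  expect_equal(rep0$mean_omega, rep(f0$params$omega, 30))
})
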