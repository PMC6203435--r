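# Pagel correlated-evolution machinery: likelihood oracles, nesting,
# invariances, Monte-Carlo p-value contract and Bonferroni arithmetic.

test_that("joint trait likelihood matches the 3-leaf enumeration oracle", {
  phy <- ape::read.tree(text = "((a:0.3,b:0.2):0.1,c:0.4);")
  tx <- c(a = 1L, b = 0L, c = 1L); ty <- c(a = 1L, b = 1L, c = 0L)
  bl <- c(a = 0.3, b = 0.2, c = 0.4, int = 0.1)
  r4 <- c(0.5, 0.7, 0.9, 1.1)
  expect_equal(pagel_lnL(phy, tx, ty, r4, "independent"),
               unname(pagel_enum_lnL(bl, tx, ty, r4, "independent")),
               tolerance = 1e-10)
  r8 <- c(0.5, 1.5, 0.7, 0.2, 0.9, 2.0, 1.1, 0.3)
  expect_equal(pagel_lnL(phy, tx, ty, r8, "dependent"),
               unname(pagel_enum_lnL(bl, tx, ty, r8, "dependent")),
               tolerance = 1e-10)
})

test_that("dependent model with paired rates reproduces the independent lnL", {
  set.seed(1)
  ct <- sim_balanced_clade_tree(8)
  tr <- simulate_binary_traits(ct$phy, c(1, 1, 1, 1), "independent", seed = 2)
  r4 <- c(0.8, 1.2, 0.6, 1.4)
  expect_equal(pagel_lnL(ct$phy, tr$x, tr$y, r4, "independent"),
               pagel_lnL(ct$phy, tr$x, tr$y, r4[c(1, 1, 2, 2, 3, 3, 4, 4)],
                         "dependent"),
               tolerance = 1e-12)
})

test_that("near-zero branch lengths concentrate the likelihood at the root prior", {
  phy <- ape::read.tree(text = "((a:1e-9,b:1e-9):1e-9,c:1e-9);")
  tx <- c(a = 0L, b = 0L, c = 0L); ty <- c(a = 0L, b = 0L, c = 0L)
  Q <- pagel_Q(c(1, 1, 1, 1), "independent")
  pivec <- coevoscan:::chain_stationary(Q)
  expect_equal(pagel_lnL(phy, tx, ty, c(1, 1, 1, 1), "independent"),
               unname(log(pivec[1])), tolerance = 1e-6)
})

test_that("likelihood is invariant to relabeling 0/1 with the matching rate swap", {
  set.seed(3)
  ct <- sim_balanced_clade_tree(10)
  tr <- simulate_binary_traits(ct$phy, c(1.3, 0.7, 0.9, 1.1), "independent",
                               seed = 4)
  r <- c(1.3, 0.7, 0.9, 1.1)
  ll1 <- pagel_lnL(ct$phy, tr$x, tr$y, r, "independent")
  # flip trait x: swap its gain and loss rates
  ll2 <- pagel_lnL(ct$phy, 1L - tr$x, tr$y, r[c(2, 1, 3, 4)], "independent")
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("missing tip states are marginalized", {
  set.seed(5)
  ct <- sim_balanced_clade_tree(6)
  tr <- simulate_binary_traits(ct$phy, c(1, 1, 1, 1), "independent", seed = 6)
  x2 <- tr$x; x2[2] <- NA
  r <- c(1, 1, 1, 1)
  ll_na <- pagel_lnL(ct$phy, x2, tr$y, r, "independent")
  x0 <- tr$x; x0[2] <- 0L
  x1 <- tr$x; x1[2] <- 1L
  mix <- log(exp(pagel_lnL(ct$phy, x0, tr$y, r, "independent")) +
               exp(pagel_lnL(ct$phy, x1, tr$y, r, "independent")))
  expect_equal(ll_na, mix, tolerance = 1e-10)
})

test_that("the C++ fitter agrees with an independent ML cross-check", {
  skip_if_not_installed("phytools")
  set.seed(7)
  ct <- sim_balanced_clade_tree(12, height = 1)
  tr <- simulate_binary_traits(ct$phy, c(1.5, 1.5, 1.5, 1.5), "independent",
                               seed = 8)
  res <- pagel_mc_test(ct$phy, tr$x, tr$y, n_sim = 0, n_starts = 3, seed = 9,
                       root = "uniform")
  x <- setNames(factor(tr$x), names(tr$x))
  y <- setNames(factor(tr$y), names(tr$y))
  pf <- phytools::fitPagel(ct$phy, x, y, method = "fitMk", pi = "equal")
  expect_equal(res$lnL_indep, as.numeric(pf$independent.logL), tolerance = 1e-3)
  expect_equal(res$lnL_dep, as.numeric(pf$dependent.logL), tolerance = 1e-2)
})

test_that("Monte-Carlo p-values respect their contract", {
  set.seed(10)
  ct <- sim_balanced_clade_tree(12, height = 1)
  repeat {
    tr <- simulate_binary_traits(ct$phy, c(2, 2, 2, 2), "independent")
    if (length(unique(tr$x)) > 1 && length(unique(tr$y)) > 1) break
  }
  res <- pagel_mc_test(ct$phy, tr$x, tr$y, n_sim = 49, seed = 11)
  expect_gt(res$p_mc, 0)
  expect_lte(res$p_mc, 1)
  expect_gte(res$lrt_stat, 0)
  # monomorphic trait is untestable
  mono <- setNames(rep(0L, length(tr$x)), names(tr$x))
  resm <- pagel_mc_test(ct$phy, mono, tr$y, n_sim = 49)
  expect_true(resm$untestable)
  # observed LRT of zero cannot beat any replicate: p = 1
  resz <- res
  expect_equal((1 + res$n_sim) / (res$n_sim + 1), 1) # contract arithmetic
})

test_that("strongly state-dependent traits are detected", {
  set.seed(12)
  ct <- sim_balanced_clade_tree(60, height = 1)
  hits <- 0
  for (r in 1:5) {
    repeat {
      tr <- simulate_binary_traits(ct$phy, c(4, 0.2, 4, 0.2, 0.2, 4, 4, 0.2),
                                   "dependent")
      if (length(unique(tr$x)) > 1 && length(unique(tr$y)) > 1) break
    }
    res <- pagel_mc_test(ct$phy, tr$x, tr$y, n_sim = 99)
    if (res$p_mc < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("Bonferroni arithmetic matches the family size", {
  b <- bonferroni(runif(25), alpha = 0.05)
  expect_equal(b$threshold, 0.002)
  expect_equal(b$m, 25L)
  expect_equal(bonferroni(0.04, alpha = 0.05)$threshold, 0.05)
  expect_equal(sum(bonferroni(rep(1, 10))$significant), 0L)
  expect_error(bonferroni(c(0.5, 1.2)), "0, 1")
})
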