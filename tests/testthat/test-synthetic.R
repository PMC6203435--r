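# Simulators: determinism, degenerate limits, and distributional checks.

test_that("zero branch lengths copy the root to every tip", {
  phy <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  ct <- clade_tree(phy)
  sim <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.5),
                                  n_sites = 15, seed = 1)
  expect_true(all(apply(sim$aln$codons, 2, function(col)
    length(unique(col)) == 1L)))
})

test_that("simulators are pure functions of the seed", {
  ct <- sim_balanced_clade_tree(8)
  s1 <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.3),
                                 n_sites = 25, seed = 42)
  s2 <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.3),
                                 n_sites = 25, seed = 42)
  expect_identical(s1$aln$codons, s2$aln$codons)
  expect_identical(s1$true_class, s2$true_class)
  t1 <- simulate_binary_traits(ct$phy, c(1, 2, 3, 4), "independent", seed = 7)
  t2 <- simulate_binary_traits(ct$phy, c(1, 2, 3, 4), "independent", seed = 7)
  expect_identical(t1, t2)
  sp1 <- simulate_spectrum(500, noise_sd = 0.01, seed = 3)
  sp2 <- simulate_spectrum(500, noise_sd = 0.01, seed = 3)
  expect_identical(sp1, sp2)
})

test_that("long simulations approach the stationary codon frequencies", {
  phy <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:16, ":3", collapse = ","), ");"))
  ct <- clade_tree(phy)
  sim <- simulate_codon_alignment(ct, list(weights = 1, omegas = 1),
                                  n_sites = 10000, seed = 4)
  st <- coevoscan:::codons_to_states(as.vector(sim$aln$codons))
  emp <- tabulate(st, nbins = 61) / length(st)
  expect_lt(sum(abs(emp - rep(1 / 61, 61))) / 2, 0.01) # total variation
})

test_that("clade-shifted classes use the foreground omega on foreground branches", {
  # extreme contrast: divergent class omega 0 in foreground, 2 in background
  ct <- sim_balanced_clade_tree(16, height = 1.5)
  mix <- list(weights = c(0.0001, 0.9999),
              omegas = list(0.5, list(background = 2, cladeA = 0.001)))
  sim <- simulate_codon_alignment(ct, mix, n_sites = 150, seed = 5)
  aa <- coevoscan:::as_aa_matrix(sim$aln)
  amino_changes <- function(rows) {
    sub <- aa[rows, , drop = FALSE]
    mean(apply(sub, 2, function(col) length(unique(col[!is.na(col)])) > 1))
  }
  # foreground clade should show far less amino-acid variation
  expect_lt(amino_changes(paste0("A", 1:8)) + 0.02,
            amino_changes(paste0("B", 1:8)))
})

test_that("exact planted coupling equals the source-column entropy", {
  set.seed(6)
  ct <- sim_balanced_clade_tree(16, height = 2)
  aln <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.8),
                                  n_sites = 10, seed = 7)$aln
  aa3 <- translate_codons(aln$codons[, 3])
  pres <- unique(aa3[!is.na(aa3)])
  coup <- setNames(AA20[seq_along(pres)], pres)
  aln2 <- plant_covarying_pair(aln, c(3, 8), coup)
  aa <- coevoscan:::as_aa_matrix(aln2)
  f <- table(aa[, 3]) / nrow(aa)
  H <- -sum(f * log(f))
  expect_equal(weighted_mi(aa[, 3], aa[, 8], pseudocount = 0), H,
               tolerance = 1e-12)
  # noisy coupling sits strictly between 0 and H
  aln3 <- plant_covarying_pair(aln, c(3, 8), coup, noise = 0.3, seed = 8)
  aa3m <- coevoscan:::as_aa_matrix(aln3)
  mi <- weighted_mi(aa3m[, 3], aa3m[, 8], pseudocount = 0)
  expect_gt(mi, 0)
  expect_lt(mi, H)
  # identity coupling on a column is a no-op
  ident <- setNames(pres, pres)
  aln4 <- plant_covarying_pair(aln, c(3, 3), ident)
  expect_identical(aln4$codons[, 3], aln$codons[, 3])
  expect_error(plant_covarying_pair(aln, c(3, 8),
                                    setNames(rep("A", length(pres)), pres)),
               "bijection")
})

test_that("very fast symmetric trait evolution yields near-independent fair coins", {
  ct <- sim_balanced_clade_tree(16, height = 1)
  xs <- integer(0); ys <- integer(0)
  set.seed(9)
  for (r in 1:40) {
    tr <- simulate_binary_traits(ct$phy, c(50, 50, 50, 50), "independent")
    xs <- c(xs, tr$x); ys <- c(ys, tr$y)
  }
  expect_gt(chisq.test(table(xs))$p.value, 0.01)
  expect_gt(chisq.test(table(xs, ys))$p.value, 0.01)
})

test_that("noiseless traces and spectra round-trip through their fits", {
  tr <- simulate_release_trace(1.5, 3, 0.21, noise_sd = 0, t_end = 40)
  fit <- fit_retinal_release(tr$time_min, tr$fluorescence)
  expect_equal(fit$b, 0.21, tolerance = 1e-8)
  sp <- simulate_spectrum(492.6, noise_sd = 0)
  expect_lt(abs(fit_a1_template(sp$wavelength_nm, sp$absorbance)$lambda_max -
                  492.6), 0.05)
})
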