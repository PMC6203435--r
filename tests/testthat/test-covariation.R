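# Weighted MI, APC correction, shuffle-null z-scores and the randomized
# dataset cutoff.

test_that("sequence weights reflect single-linkage identity clusters", {
  m <- rbind(s1 = c("A", "C", "D", "E"), s2 = c("A", "C", "D", "E"),
             s3 = c("W", "Y", "F", "H"), s4 = c("W", "Y", "F", "H"))
  w <- sequence_weights(m, identity_threshold = 0.62)
  expect_equal(unname(w), rep(0.5, 4))
  # all identical -> one cluster of N
  m2 <- matrix("A", 3, 5, dimnames = list(paste0("t", 1:3), NULL))
  expect_equal(unname(sequence_weights(m2)), rep(1 / 3, 3))
  # fully dissimilar pair -> singleton clusters
  m3 <- rbind(a = c("A", "C"), b = c("W", "Y"))
  expect_equal(unname(sequence_weights(m3, 0.62)), c(1, 1))
})

test_that("weighted MI has its closed forms and bounds", {
  # two identical binary columns, equal split, unit weights, no pseudocount
  ci <- rep(c("A", "W"), each = 6)
  expect_equal(weighted_mi(ci, ci, pseudocount = 0), log(2), tolerance = 1e-12)
  # constant column against anything -> 0
  expect_equal(weighted_mi(rep("A", 12), ci, pseudocount = 0), 0)
  expect_gte(weighted_mi(ci, rev(ci), pseudocount = 0.05), 0)
  # symmetry
  set.seed(1)
  cj <- sample(c("A", "W", "Y"), 12, replace = TRUE)
  expect_identical(weighted_mi(ci, cj), weighted_mi(cj, ci))
  # data-processing: a residue bijection leaves MI unchanged
  map <- c(A = "K", W = "R", Y = "G")
  expect_equal(weighted_mi(ci, cj), weighted_mi(map[ci], map[cj]),
               tolerance = 1e-12)
  expect_error(weighted_mi(rep(NA_character_, 4), rep("A", 4)), "all-gap")
})

test_that("independently shuffled columns fall below their permutation tail", {
  set.seed(2)
  ci <- sample(c("A", "W", "Y", "K"), 40, replace = TRUE)
  cj <- sample(c("A", "W", "Y", "K"), 40, replace = TRUE)
  obs <- weighted_mi(ci, cj, pseudocount = 0)
  null <- replicate(300, weighted_mi(ci, sample(cj), pseudocount = 0))
  expect_lt(obs, quantile(null, 0.995))
})

test_that("APC removes a uniform background exactly", {
  M <- matrix(0.7, 10, 10); diag(M) <- 0
  C <- coevoscan:::apc_correct(M)
  expect_lt(max(abs(C)), 1e-12)
})

test_that("planted covarying pair attains the top z and weighting absorbs duplication", {
  set.seed(3)
  ct <- sim_balanced_clade_tree(24, height = 2)
  sim <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.5),
                                  n_sites = 20, seed = 4)
  aln <- sim$aln
  aa5 <- translate_codons(aln$codons[, 5])
  pres <- unique(aa5[!is.na(aa5)])
  coup <- setNames(AA20[seq_along(pres)], pres)
  aln2 <- plant_covarying_pair(aln, c(5, 15), coup)
  aa <- coevoscan:::as_aa_matrix(aln2)
  zs <- apc_z_scores(aa, n_column_shuffles = 40, seed = 5)
  z <- zs$z; diag(z) <- -Inf
  top <- arrayInd(which.max(z), dim(z))
  expect_setequal(as.vector(top), c(5L, 15L))
  # duplicating every sequence exactly once leaves weighted z unchanged
  aa_dup <- rbind(aa, aa)
  rownames(aa_dup) <- make.unique(rep(rownames(aa), 2))
  w1 <- sequence_weights(aa)
  w2 <- sequence_weights(aa_dup)
  m1 <- coevoscan:::mi_matrix(aa, w1)
  m2 <- coevoscan:::mi_matrix(aa_dup, w2)
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("randomization cutoff dominates its replicates and is deterministic", {
  set.seed(6)
  ct <- sim_balanced_clade_tree(12, height = 2)
  aln <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.8),
                                  n_sites = 12, seed = 7)$aln
  rc1 <- randomization_cutoff(aln, n_random = 10, n_column_shuffles = 20,
                              seed = 11)
  expect_equal(rc1$z_star, max(rc1$rep_max))
  expect_true(all(rc1$z_star >= rc1$rep_max))
  rc2 <- randomization_cutoff(aln, n_random = 10, n_column_shuffles = 20,
                              seed = 11)
  expect_identical(rc1$z_star, rc2$z_star)
})

test_that("a focal scan on independent columns reports no significant pairs", {
  set.seed(8)
  ct <- sim_balanced_clade_tree(16, height = 2)
  aln <- simulate_codon_alignment(ct, list(weights = 1, omegas = 0.6),
                                  n_sites = 15, seed = 9)$aln
  sc <- mi_scan(aln, focal_site = 8, n_random = 15, n_column_shuffles = 25,
                seed = 10)
  expect_equal(sum(sc$significant), 0L)
  expect_equal(nrow(sc), 14L)
})
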