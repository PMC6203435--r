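# Standard genetic code bookkeeping over the 61 sense codons.

.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' Returns the 61 sense codons (standard code, stop codons excluded) in a
#' fixed lexicographic order over the alphabet A, C, G, T. All codon state
#' indices used throughout the package refer to positions in this vector.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  codon_tables()$codons
}

# Internal cache of codon tables and the pairwise single-change structure
# used to build rate matrices.
codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  nt <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  all64 <- sort(all64)
  aa <- as.character(Biostrings::GENETIC_CODE[all64])
  keep <- aa != "*"
  codons <- all64[keep]
  aa <- aa[keep]
  n <- length(codons)
  stopifnot(n == 61L)
  cmat <- do.call(rbind, strsplit(codons, ""))

  # single-nucleotide-change structure: for each ordered pair, the differing
  # position (0 if not exactly one), transition flag and nonsynonymous flag
  diffpos <- matrix(0L, n, n)
  is_ts <- matrix(FALSE, n, n)
  is_ns <- matrix(FALSE, n, n)
  purines <- c("A", "G")
  for (k in 1:3) {
    same_other <- matrix(TRUE, n, n)
    for (m in setdiff(1:3, k)) {
      same_other <- same_other & outer(cmat[, m], cmat[, m], "==")
    }
    diff_k <- outer(cmat[, k], cmat[, k], "!=")
    one <- same_other & diff_k
    diffpos[one] <- k
    tsk <- outer(cmat[, k] %in% purines, cmat[, k] %in% purines, "==")
    is_ts[one] <- tsk[one]
  }
  is_ns <- outer(aa, aa, "!=")
  tab <- list(codons = codons, aa = aa, cmat = cmat,
              index = stats::setNames(seq_len(n), codons),
              diffpos = diffpos, is_ts = is_ts, is_ns = is_ns)
  .codon_env$tab <- tab
  tab
}

#' Translate codons to one-letter amino acids
#'
#' @param codons Character vector of codon triplets. Gaps (`"---"`) and codons
#'   containing non-ACGT characters translate to `NA`.
#' @return Character vector of one-letter amino-acid codes (`NA` for
#'   missing/ambiguous codons, `"*"` for stops).
#' @export
translate_codons <- function(codons) {
  tab <- codon_tables()
  codons <- toupper(codons)
  out <- rep(NA_character_, length(codons))
  known <- codons %in% names(Biostrings::GENETIC_CODE)
  out[known] <- as.character(Biostrings::GENETIC_CODE[codons[known]])
  out
}

# integer states 1..61 (NA for gap/missing/stop)
codons_to_states <- function(codons) {
  tab <- codon_tables()
  unname(tab$index[toupper(codons)])
}
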