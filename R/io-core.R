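# Alignment and tree I/O, reference-residue numbering, clade partitions,
# dataset pruning, and per-site variant summaries.

#' Codon alignment with reference residue numbering
#'
#' Constructs a codon alignment from a character matrix of codon triplets.
#' Columns are codon sites; `ref_map` maps each column to a residue number in
#' a reference protein numbering (for rhodopsin analyses, bovine RH1
#' numbering). Codons containing gaps or ambiguity codes are treated as
#' missing data.
#'
#' @param codons Character matrix (taxa x sites) of codon triplets, rownames
#'   are taxon labels. `"---"` marks a gapped codon.
#' @param ref_start Residue number of the first column (default 1).
#' @param ref_map Optional explicit integer vector of residue numbers, one
#'   per column, strictly increasing; overrides `ref_start`.
#' @return An object of class `codon_alignment` with elements `taxa`,
#'   `codons`, `n_sites`, `ref_map`.
#' @export
codon_alignment <- function(codons, ref_start = 1L, ref_map = NULL) {
  if (!is.matrix(codons) || !is.character(codons))
    stop("codons must be a character matrix of codon triplets")
  if (is.null(rownames(codons))) stop("codons must have taxon rownames")
  if (anyDuplicated(rownames(codons))) stop("duplicate taxon labels")
  if (any(nchar(codons) != 3L)) stop("all entries must be codon triplets")
  codons <- toupper(codons)
  tab <- codon_tables()
  aa <- translate_codons(as.vector(codons))
  if (any(aa == "*", na.rm = TRUE))
    stop("alignment contains stop codons")
  n_sites <- ncol(codons)
  if (is.null(ref_map)) {
    ref_map <- seq.int(ref_start, length.out = n_sites)
  }
  ref_map <- as.integer(ref_map)
  if (length(ref_map) != n_sites || any(diff(ref_map) <= 0))
    stop("ref_map must be strictly increasing and cover every column")
  structure(list(taxa = rownames(codons), codons = codons,
                 n_sites = n_sites, ref_map = ref_map),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa,", x$n_sites,
      "codon sites (residues", x$ref_map[1], "-",
      x$ref_map[x$n_sites], ")\n")
  invisible(x)
}

#' Read an in-frame codon alignment from FASTA
#'
#' Reads aligned coding sequences, splits them into codon triplets, and
#' attaches reference residue numbering starting at `ref_start`. Sequences
#' whose length is not a multiple of 3, duplicate labels, and internal stop
#' codons are rejected. A stop codon in the final column (a translated
#' terminator) is converted to missing data with a warning.
#'
#' @param path FASTA file of aligned in-frame coding sequences.
#' @param ref_start Residue number of the first codon column.
#' @return A [codon_alignment].
#' @export
read_codon_alignment <- function(path, ref_start = 1L) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("empty FASTA file: ", path)
  chars <- lapply(as.character(dna), function(s) toupper(paste(s, collapse = "")))
  lens <- vapply(chars, nchar, 1L)
  if (length(unique(lens)) != 1L)
    stop("sequences differ in length; input must be aligned")
  if (lens[1] %% 3L != 0L)
    stop("alignment length ", lens[1], " is not divisible by 3")
  if (anyDuplicated(names(dna))) stop("duplicate taxon labels in FASTA")
  n_sites <- lens[1] %/% 3L
  split_codons <- function(s) substring(s, 3L * seq_len(n_sites) - 2L, 3L * seq_len(n_sites))
  m <- do.call(rbind, lapply(chars, split_codons))
  rownames(m) <- names(dna)
  aa <- matrix(translate_codons(as.vector(m)), nrow = nrow(m))
  stops <- which(aa == "*", arr.ind = TRUE)
  if (nrow(stops) > 0) {
    if (any(stops[, 2] < n_sites))
      stop("stop codon at a non-terminal position in taxon ",
           rownames(m)[stops[stops[, 2] < n_sites, 1][1]])
    warning("terminal stop codon(s) converted to missing data")
    m[stops] <- "---"
  }
  codon_alignment(m, ref_start = ref_start)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  dna <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  names(dna) <- aln$taxa
  ape::write.FASTA(dna, file = path)
  invisible(path)
}

# column index for a reference residue number
site_to_col <- function(aln, sites) {
  idx <- match(sites, aln$ref_map)
  if (anyNA(idx)) stop("unknown site(s): ", paste(sites[is.na(idx)], collapse = ", "))
  idx
}

#' Phylogeny with named foreground partitions
#'
#' Couples an `ape::phylo` tree (branch lengths required; expected
#' substitutions per codon) with named foreground partitions. A partition is
#' either a *clade* (all branches descending from the most recent common
#' ancestor of the listed taxa) or a *branch* (the single stem edge leading
#' to that MRCA). Branches in no partition form the background. Partitions
#' are stored as taxon-set definitions and resolved to edge indices on
#' demand, so they survive pruning.
#'
#' @param phy An `ape::phylo` object with branch lengths.
#' @param partitions Named list; each element is `list(type = "clade"|"branch",
#'   taxa = <character vector>)`.
#' @return An object of class `clade_tree`.
#' @export
clade_tree <- function(phy, partitions = list()) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape::phylo tree")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  if (length(partitions) > 0) {
    if (is.null(names(partitions)) || any(names(partitions) == ""))
      stop("partitions must be named")
    for (p in partitions) {
      if (!is.list(p) || is.null(p$taxa) || !(p$type %in% c("clade", "branch")))
        stop("each partition needs fields type ('clade' or 'branch') and taxa")
      unknown <- setdiff(p$taxa, phy$tip.label)
      if (length(unknown) > 0)
        stop("partition references unknown taxa: ", paste(unknown, collapse = ", "))
    }
  }
  ct <- structure(list(phy = phy, partitions = partitions), class = "clade_tree")
  pe <- resolve_partition_edges(ct)
  if (length(pe) > 1) {
    all_e <- unlist(pe)
    if (anyDuplicated(all_e)) stop("partitions must be disjoint")
  }
  ct
}

#' @export
print.clade_tree <- function(x, ...) {
  cat("clade_tree:", length(x$phy$tip.label), "tips;",
      length(x$partitions), "foreground partition(s)",
      if (length(x$partitions)) paste0("(", paste(names(x$partitions), collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Resolve partition definitions to edge indices
#'
#' @param ct A [clade_tree].
#' @return Named list of integer edge indices (rows of `ct$phy$edge`).
#' @export
resolve_partition_edges <- function(ct) {
  stopifnot(inherits(ct, "clade_tree"))
  phy <- ct$phy
  lapply(ct$partitions, function(p) {
    taxa <- intersect(p$taxa, phy$tip.label)
    if (length(taxa) == 0) return(integer(0))
    if (length(taxa) == 1L) {
      node <- match(taxa, phy$tip.label)
    } else {
      node <- ape::getMRCA(phy, taxa)
    }
    stem <- which(phy$edge[, 2] == node)
    if (p$type == "branch") return(stem)
    # clade: all edges within the subtree rooted at `node`
    desc <- node
    repeat {
      more <- phy$edge[phy$edge[, 1] %in% desc, 2]
      new <- setdiff(more, desc)
      if (length(new) == 0) break
      desc <- c(desc, new)
    }
    which(phy$edge[, 1] %in% desc)
  })
}

#' Read partition definitions from a YAML sidecar
#'
#' Expects a top-level mapping `partitions:` of
#' `name: {type: clade|branch, taxa: [...]}` entries.
#'
#' @param path YAML file.
#' @return Named list of partition definitions for [clade_tree()].
#' @export
read_partitions <- function(path) {
  y <- yaml::read_yaml(path)
  parts <- if (!is.null(y$partitions)) y$partitions else y
  lapply(parts, function(p) list(type = p$type, taxa = as.character(p$taxa)))
}

#' Read a clade tree from Newick plus an optional partition YAML
#'
#' @param tree_path Newick file with branch lengths.
#' @param partition_path Optional YAML partition file (see [read_partitions()]).
#' @return A [clade_tree].
#' @export
read_clade_tree <- function(tree_path, partition_path = NULL) {
  phy <- ape::read.tree(tree_path)
  parts <- if (is.null(partition_path)) list() else read_partitions(partition_path)
  clade_tree(phy, parts)
}

#' Prune an alignment and tree to a taxon subset
#'
#' Restricts alignment rows and tree leaves to `keep`. Degree-2 nodes created
#' by pruning are suppressed with their branch lengths summed (so patristic
#' distances among retained leaves are unchanged). Columns that become all-gap
#' are retained and flagged in the `all_gap` attribute of the returned
#' alignment.
#'
#' @param aln A [codon_alignment].
#' @param tree A [clade_tree] over the same taxa.
#' @param keep Character vector of taxa to retain (>= 2).
#' @return List with elements `aln` and `tree`.
#' @export
prune_to_taxa <- function(aln, tree, keep) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "clade_tree"))
  unknown <- setdiff(keep, aln$taxa)
  if (length(unknown) > 0)
    stop("unknown taxa in keep: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L)
    stop("need at least two taxa to retain a tree")
  phy2 <- ape::keep.tip(tree$phy, keep)
  parts2 <- lapply(tree$partitions, function(p) {
    list(type = p$type, taxa = intersect(p$taxa, keep))
  })
  parts2 <- parts2[vapply(parts2, function(p) length(p$taxa) > 0, TRUE)]
  aln2 <- aln
  aln2$codons <- aln$codons[keep, , drop = FALSE]
  aln2$taxa <- keep
  st <- matrix(codons_to_states(as.vector(aln2$codons)), nrow = length(keep))
  attr(aln2, "all_gap") <- which(colSums(!is.na(st)) == 0L)
  list(aln = aln2, tree = clade_tree(phy2, parts2))
}

#' Per-site amino-acid frequency profiles
#'
#' Tabulates amino-acid frequencies at the requested reference sites, with
#' gaps excluded from the denominator. The consensus residue is the most
#' frequent amino acid; ties are broken by alphabetical order of the
#' one-letter code.
#'
#' @param aln A [codon_alignment].
#' @param sites Reference residue numbers.
#' @return Named list (one element per site) of `list(freq = <named numeric>,
#'   consensus = <character>, n = <count of non-gap taxa>)`.
#' @export
site_variant_profile <- function(aln, sites) {
  stopifnot(inherits(aln, "codon_alignment"))
  cols <- site_to_col(aln, sites)
  out <- lapply(cols, function(j) {
    aa <- translate_codons(aln$codons[, j])
    aa <- aa[!is.na(aa)]
    if (length(aa) == 0)
      return(list(freq = numeric(0), consensus = NA_character_, n = 0L))
    f <- table(aa)
    f <- f / sum(f)
    f <- f[order(-as.numeric(f), names(f))]
    list(freq = stats::setNames(as.numeric(f), names(f)),
         consensus = names(f)[1], n = length(aa))
  })
  names(out) <- as.character(sites)
  out
}

#' Binary consensus/variant encoding of a site
#'
#' Encodes each taxon at the given site as 0 (consensus residue, per the
#' [site_variant_profile()] tie rule) or 1 (any other residue); gapped codons
#' are `NA` (missing).
#'
#' @param aln A [codon_alignment].
#' @param site A reference residue number.
#' @return An object of class `binary_trait`: list with `values` (named
#'   integer vector in 0/1/NA), `site` and `consensus`.
#' @export
encode_binary_trait <- function(aln, site) {
  stopifnot(inherits(aln, "codon_alignment"), length(site) == 1L)
  prof <- site_variant_profile(aln, site)[[1]]
  if (prof$n == 0L) stop("site ", site, " is entirely gapped")
  aa <- translate_codons(aln$codons[, site_to_col(aln, site)])
  vals <- ifelse(is.na(aa), NA_integer_, ifelse(aa == prof$consensus, 0L, 1L))
  names(vals) <- aln$taxa
  structure(list(values = vals, site = site, consensus = prof$consensus),
            class = "binary_trait")
}

#' @export
print.binary_trait <- function(x, ...) {
  cat("binary_trait: site", x$site, "consensus", x$consensus, "-",
      sum(x$values == 1L, na.rm = TRUE), "variant taxa of",
      sum(!is.na(x$values)), "\n")
  invisible(x)
}
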