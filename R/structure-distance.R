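# Inter-residue distances from a protein structure and the focal-site
# neighborhood used to filter candidate coevolving sites.

#' Read a structure chain for distance analysis
#'
#' Parses a PDB file (via bio3d), restricts it to one chain, drops hydrogens
#' and keeps the first alternate location of each atom.
#'
#' @param path PDB file.
#' @param chain Chain identifier (default "A").
#' @return List with `xyz` (atom coordinate matrix), `resno` (residue number
#'   per atom), `structure_id` and `chain`.
#' @export
read_structure_chain <- function(path, chain = "A") {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$chain == chain & at$type == "ATOM", ]
  if (nrow(at) == 0) stop("no atoms in chain ", chain)
  elt <- at$elesy
  if (is.null(elt) || all(is.na(elt)) || all(elt == "")) {
    elt <- substr(gsub("^[0-9 ]+", "", at$elety), 1, 1)
  }
  at <- at[toupper(trimws(elt)) != "H", ]
  alt <- at$alt
  if (!is.null(alt)) at <- at[is.na(alt) | alt %in% c("", "A"), ]
  list(xyz = as.matrix(at[, c("x", "y", "z")]),
       resno = at$resno,
       structure_id = sub("\\.pdb$", "", basename(path)),
       chain = chain)
}

#' Minimum heavy-atom distance between two residues
#'
#' The minimum Euclidean distance over all heavy-atom pairs of the two
#' residues, reported to 0.1 Angstrom.
#'
#' @param structure Output of [read_structure_chain()] (or a PDB path, read
#'   with defaults).
#' @param res_i,res_j Residue numbers.
#' @param chain Chain (used only when `structure` is a path).
#' @param digits Rounding (default 1 decimal).
#' @return Distance in Angstrom.
#' @export
min_residue_distance <- function(structure, res_i, res_j, chain = "A",
                                 digits = 1) {
  if (is.character(structure)) structure <- read_structure_chain(structure, chain)
  xi <- structure$xyz[structure$resno == res_i, , drop = FALSE]
  xj <- structure$xyz[structure$resno == res_j, , drop = FALSE]
  if (nrow(xi) == 0) stop("residue ", res_i, " missing from chain")
  if (nrow(xj) == 0) stop("residue ", res_j, " missing from chain")
  if (res_i == res_j) return(0)
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
  round(sqrt(max(0, min(d2))), digits)
}

#' Residue neighborhood of a focal site
#'
#' All residues of the chain whose minimum heavy-atom distance to the focal
#' residue is at most `radius`, excluding the focal residue itself. Sequence
#' neighbors of the focal site (within `seq_neighbors` positions) are always
#' included in the returned scan set with a flag, since immediately adjacent
#' residues interact through the backbone regardless of the measured
#' side-chain distance.
#'
#' @param structure Output of [read_structure_chain()] or a PDB path.
#' @param focal Focal residue number (default 122).
#' @param radius Distance cutoff in Angstrom (default 6).
#' @param chain Chain (when `structure` is a path).
#' @param seq_neighbors Sequence-adjacency window always kept (default 2).
#' @return data.frame with `residue`, `distance`, `within_radius`,
#'   `seq_neighbor`.
#' @export
neighborhood <- function(structure, focal = 122, radius = 6, chain = "A",
                         seq_neighbors = 2) {
  if (is.character(structure)) structure <- read_structure_chain(structure, chain)
  res <- sort(unique(structure$resno))
  if (!focal %in% res) stop("focal residue ", focal, " missing from chain")
  d <- vapply(res, function(r) min_residue_distance(structure, focal, r), 1.0)
  df <- data.frame(residue = res, distance = d)
  df$within_radius <- df$distance <= radius & df$residue != focal
  df$seq_neighbor <- abs(df$residue - focal) <= seq_neighbors & df$residue != focal
  df[df$residue != focal & (df$within_radius | df$seq_neighbor), , drop = FALSE]
}

#' Full distance map to a focal residue
#'
#' @param structure Output of [read_structure_chain()] or a PDB path.
#' @param focal Focal residue number.
#' @param chain Chain (when `structure` is a path).
#' @return data.frame with `residue` and `distance` (to 0.1 Angstrom) for
#'   every residue in the chain.
#' @export
residue_distance_map <- function(structure, focal = 122, chain = "A") {
  if (is.character(structure)) structure <- read_structure_chain(structure, chain)
  res <- sort(unique(structure$resno))
  data.frame(residue = res,
             distance = vapply(res, function(r)
               min_residue_distance(structure, focal, r), 1.0))
}

#' Write a synthetic helix-bundle structure file
#'
#' Generates a small, clearly synthetic PDB file: `n_helices` ideal
#' alpha-helical CA/CB traces arranged on a circle, with residue numbering
#' starting at `res_start`. Used to exercise the distance machinery when no
#' experimental structure is available; it is not a model of any real
#' protein.
#'
#' @param path Output PDB path.
#' @param n_helices Number of helices (default 3).
#' @param helix_len Residues per helix (default 30).
#' @param res_start First residue number (default 101).
#' @param bundle_radius Circle radius in Angstrom (default 6).
#' @return Invisibly, `path`.
#' @export
write_synthetic_structure <- function(path, n_helices = 3, helix_len = 30,
                                      res_start = 101, bundle_radius = 6) {
  lines <- character(0)
  serial <- 0L
  resno <- res_start - 1L
  for (h in seq_len(n_helices)) {
    ang <- 2 * pi * (h - 1) / n_helices
    cx <- bundle_radius * cos(ang); cy <- bundle_radius * sin(ang)
    dir <- if (h %% 2 == 0) -1 else 1
    for (i in seq_len(helix_len)) {
      resno <- resno + 1L
      phi <- 100 * pi / 180 * i
      x <- cx + 2.3 * cos(phi); y <- cy + 2.3 * sin(phi)
      z <- dir * 1.5 * i
      for (atom in c("CA", "CB")) {
        serial <- serial + 1L
        off <- if (atom == "CB") 1.5 else 0
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, atom, resno,
          x + off * cos(phi), y + off * sin(phi), z))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
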