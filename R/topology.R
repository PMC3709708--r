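AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA3 <- setNames(names(AA1), AA1)

#' Build a backbone peptide topology
#'
#' Defines the atom and residue bookkeeping for a linear peptide carrying the
#' five backbone atoms per residue (N, H, CA, C, O). The amide hydrogen of
#' residue 1 is omitted (the N-terminal ammonium carries no single amide H),
#' and proline contributes no amide H either. Residue numbering is 1-based
#' throughout, matching the Turn_j-i / HB_d-a labelling convention used for
#' alpha-syn12.
#'
#' @param sequence One-letter amino-acid sequence, e.g. `"MDVFMKGLSKAK"`.
#' @param protonation Protonation-state label: `"physiological"` (lysines
#'   protonated, aspartate deprotonated), `"acidic"` (aspartate also
#'   protonated), `"alkaline"`, or `"custom"`. The label selects default turn
#'   and hydrogen-bond registries downstream; it does not alter atom records.
#' @return An object of class `peptide_topology`: a list with `sequence`,
#'   `residues` (tibble of `resno`, `resid`), `atoms` (tibble of `atom`,
#'   `resno`, `resid`, `name`, `element`) and `protonation`.
#' @examples
#' topo <- peptide_topology("MDVFMKGLSKAK")
#' n_residues(topo)
#' @export
peptide_topology <- function(sequence,
                             protonation = c("physiological", "acidic",
                                             "alkaline", "custom")) {
  protonation <- match.arg(protonation)
  stopifnot(is.character(sequence), length(sequence) == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 4) {
    abort("peptide must have at least 4 residues for any turn analysis")
  }
  bad <- setdiff(aa, names(AA1))
  if (length(bad)) abort(paste0("unknown residue code(s): ", paste(bad, collapse = ", ")))
  resid3 <- unname(AA1[aa])
  rows <- list()
  k <- 0L
  for (r in seq_along(aa)) {
    names_r <- c("N", if (r > 1 && aa[r] != "P") "H", "CA", "C", "O")
    for (nm in names_r) {
      k <- k + 1L
      rows[[k]] <- tibble(atom = k, resno = r, resid = resid3[r], name = nm,
                          element = substr(nm, 1, 1))
    }
  }
  structure(
    list(sequence = paste(aa, collapse = ""),
         residues = tibble(resno = seq_along(aa), resid = resid3),
         atoms = bind_rows(rows),
         protonation = protonation),
    class = "peptide_topology")
}

#' Topology of the alpha-syn12 peptide
#'
#' Convenience constructor for residues 1-12 of human alpha-synuclein
#' (MDVFMKGLSKAK), the peptide whose helix-to-hairpin transition this package
#' analyzes.
#'
#' @inheritParams peptide_topology
#' @return A [peptide_topology()] object with 12 residues.
#' @export
syn12_topology <- function(protonation = c("physiological", "acidic",
                                           "alkaline", "custom")) {
  peptide_topology("MDVFMKGLSKAK", protonation = match.arg(protonation))
}

#' @export
print.peptide_topology <- function(x, ...) {
  cat("<peptide_topology> ", x$sequence, " (", n_residues(x), " residues, ",
      nrow(x$atoms), " backbone atoms, ", x$protonation, " pH)\n", sep = "")
  invisible(x)
}

#' Number of residues in a topology
#' @param topology A [peptide_topology()] object.
#' @return Integer residue count.
#' @export
n_residues <- function(topology) nrow(topology$residues)

# index of a named backbone atom; NA if absent (e.g. H of residue 1)
atom_index <- function(topology, resno, name) {
  i <- which(topology$atoms$resno == resno & topology$atoms$name == name)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Indices of the Calpha atoms
#'
#' The default atom selection for superposition and RMSD: the conventional
#' RMSDCa metric uses Calpha atoms only.
#'
#' @param topology A [peptide_topology()] object.
#' @return Integer vector of atom indices.
#' @export
ca_indices <- function(topology) which(topology$atoms$name == "CA")
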