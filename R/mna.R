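# atom label used inside MNA strings: element symbol with the formal charge
# sign appended when nonzero ("O-", "N+", "Ca+2"); a charged atom is a
# different vocabulary item from its neutral counterpart.
atom_labels <- function(mol) {
  chg <- mol$atoms$charge
  suffix <- ifelse(chg == 0L, "",
                   paste0(ifelse(chg > 0L, "+", "-"),
                          ifelse(abs(chg) > 1L, abs(chg), "")))
  paste0(mol$atoms$element, suffix)
}

# labels of all atoms at one level; lower holds the level-(L-1) labels
mna_level_up <- function(lower, adj, base) {
  vapply(seq_along(base), function(i) {
    nb <- lower[adj[[i]]]
    paste0(base[i], "(", paste(sort(nb), collapse = ""), ")")
  }, character(1))
}

#' MNA descriptor of one atom
#'
#' The Multilevel Neighborhoods of Atoms descriptor is a canonical linear
#' notation for an atom-centered fragment: at level 0 it is the atom label
#' alone; at level L it is the atom label followed, in parentheses, by the
#' lexicographically sorted level-(L-1) descriptors of its neighbors. Bond
#' orders play no role, hydrogens are explicit atoms, and sorting makes the
#' string independent of atom input order.
#'
#' @param mol a [molecule_graph].
#' @param atom_index 1-based atom index.
#' @param level non-negative neighborhood depth.
#' @return The descriptor string.
#' @examples
#' m <- parse_structure("C", "smiles")   # methane
#' mna_atom(m, 1, 1)                     # "C(HHHH)"
#' @export
mna_atom <- function(mol, atom_index, level) {
  stopifnot(inherits(mol, "molecule_graph"))
  if (length(atom_index) != 1L || is.na(atom_index) ||
      atom_index < 1L || atom_index > n_atoms(mol))
    stop("invalid atom index", call. = FALSE)
  if (level < 0L) stop("level must be >= 0", call. = FALSE)
  base <- atom_labels(mol)
  lab <- base
  if (level > 0L) {
    adj <- adjacency_list(mol)
    for (l in seq_len(level)) lab <- mna_level_up(lab, adj, base)
  }
  lab[atom_index]
}

#' MNA descriptor set of a molecule
#'
#' The set of unique MNA descriptor strings over all atoms and, by default,
#' all levels `0..max_level` (cumulative construction: the set at depth k is
#' always a superset of the set at depth k-1). Set semantics: each label
#' counts once per compound regardless of how many atoms generate it.
#'
#' @param mol a [molecule_graph].
#' @param max_level maximum neighborhood depth; default 2, the standard
#'   choice for MNA descriptors.
#' @param cumulative include levels `0..max_level` (default) rather than
#'   only level `max_level`.
#' @return Sorted character vector of descriptor labels with attribute
#'   `source_id`.
#' @examples
#' mna_descriptors(parse_structure("O", "smiles"), max_level = 1)
#' # "H" "H(O)" "O" "O(HH)"
#' @export
mna_descriptors <- function(mol, max_level = 2L, cumulative = TRUE) {
  stopifnot(inherits(mol, "molecule_graph"))
  if (max_level < 0L) stop("max_level must be >= 0", call. = FALSE)
  if (n_atoms(mol) == 0L) stop("empty molecule", call. = FALSE)
  base <- atom_labels(mol)
  adj <- adjacency_list(mol)
  levels <- vector("list", max_level + 1L)
  levels[[1L]] <- base
  lab <- base
  if (max_level > 0L) {
    for (l in seq_len(max_level)) {
      lab <- mna_level_up(lab, adj, base)
      levels[[l + 1L]] <- lab
    }
  }
  out <- if (cumulative) unlist(levels) else lab
  out <- sort(unique(out))
  attr(out, "source_id") <- mol$source_id
  out
}

#' Descriptor sets for a list of molecules
#'
#' @param mols named list of [molecule_graph] objects, as returned by
#'   [read_structures()].
#' @inheritParams mna_descriptors
#' @return Named list of descriptor sets (character vectors), one per
#'   compound; this is the `features` map consumed by [sar_train()].
#' @export
featurize_structures <- function(mols, max_level = 2L, cumulative = TRUE) {
  out <- lapply(mols, mna_descriptors, max_level = max_level,
                cumulative = cumulative)
  names(out) <- vapply(mols, function(m) m$source_id, character(1))
  out
}

#' Collapse compounds with identical descriptor sets
#'
#' Training corpora can hold the same parent structure under several ids
#' (salts, registry duplicates). Compounds whose canonical descriptor sets
#' are identical are merged onto one representative id (the first seen).
#'
#' @param features named list of descriptor sets.
#' @return List with `features` (deduplicated map) and `representative`
#'   (named character vector mapping every original id to its
#'   representative).
#' @export
dedupe_by_descriptors <- function(features) {
  keys <- vapply(features, function(d) paste(d, collapse = "\x01"),
                 character(1))
  rep_idx <- match(keys, keys)
  representative <- names(features)[rep_idx]
  names(representative) <- names(features)
  list(features = features[!duplicated(keys)],
       representative = representative)
}
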