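#' Hydrogen-materialized, bond-type-agnostic molecular graph
#'
#' A `molecule_graph` is the substrate of MNA descriptor generation: every
#' implicit hydrogen implied by standard valence and formal charge is present
#' as an explicit atom node, bond orders and aromaticity are deliberately
#' discarded, and stereochemical annotations are never stored, so two
#' stereoisomers yield identical graphs.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param charges integer vector of formal charges, one per atom.
#' @param edges two-column integer matrix of atom-index pairs (unordered,
#'   no self-loops, no duplicates).
#' @param source_id compound identifier string.
#' @return An object of class `molecule_graph`: a list with components
#'   `atoms` (data.frame with `element` and `charge`), `edges` (two-column
#'   integer matrix with `i < j` per row) and `source_id`.
#' @examples
#' # bare methane graph written by hand
#' m <- molecule_graph(c("C", "H", "H", "H", "H"), integer(5),
#'                     cbind(1L, 2:5), "methane")
#' n_atoms(m)
#' @export
molecule_graph <- function(elements, charges, edges, source_id = "") {
  elements <- as.character(elements)
  charges <- as.integer(charges)
  if (length(elements) == 0L)
    stop("empty molecule: no atoms", call. = FALSE)
  if (length(charges) != length(elements))
    stop("'charges' must have one entry per atom", call. = FALSE)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > length(elements)))
      stop("edge references an atom index out of range", call. = FALSE)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed", call. = FALSE)
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(list(
    atoms = data.frame(element = elements, charge = charges,
                       stringsAsFactors = FALSE),
    edges = edges,
    source_id = as.character(source_id)
  ), class = "molecule_graph")
}

#' @rdname molecule_graph
#' @param x a `molecule_graph`.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("molecule_graph '%s': %d atoms, %d edges\n",
              x$source_id, n_atoms(x), nrow(x$edges)))
  comp <- table(x$atoms$element)
  cat("  composition:",
      paste(sprintf("%s%d", names(comp), comp), collapse = " "), "\n")
  invisible(x)
}

# adjacency list: integer vector of neighbors per atom
adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (i in seq_along(adj)) adj[[i]] <- integer(0)
  e <- mol$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1L]; j <- e[r, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# connected components by BFS; returns integer component id per atom
graph_components <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

# restrict a graph to a subset of atoms (salt stripping)
subset_graph <- function(mol, keep) {
  keep <- sort(keep)
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  e <- mol$edges
  if (nrow(e)) {
    sel <- e[, 1L] %in% keep & e[, 2L] %in% keep
    e <- cbind(remap[e[sel, 1L]], remap[e[sel, 2L]])
  }
  molecule_graph(mol$atoms$element[keep], mol$atoms$charge[keep], e,
                 mol$source_id)
}

parse_error <- function(msg, record = NA_integer_, context = "") {
  structure(class = c("mnasar_parse_error", "error", "condition"),
            list(message = sprintf("structure parse failure (record %s): %s%s",
                                   record, msg,
                                   if (nzchar(context))
                                     paste0(" [", context, "]") else ""),
                 call = NULL, record = record))
}

# OpenBabel conversion of one record to a hydrogen-materialized V2000 block.
# `from` is an OpenBabel input format id ("SMI" or "SDF").
ob_to_sdf <- function(text, from) {
  out <- suppressWarnings(
    ChemmineOB::convertFormat(from, "SDF", source = text,
                              options = data.frame(names = "h", args = "",
                                                   stringsAsFactors = FALSE)))
  if (!nzchar(trimws(out))) return(NULL)
  out
}

# parse "M  CHG  n  idx chg  idx chg ..." property lines of a V2000 block
chg_from_block <- function(lines, n_atom) {
  charge <- integer(n_atom)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]])
    n <- f[1L]
    for (k in seq_len(n)) {
      idx <- f[2L * k]; chg <- f[2L * k + 1L]
      if (!is.na(idx) && idx >= 1L && idx <= n_atom) charge[idx] <- chg
    }
  }
  charge
}

# one normalized (hydrogen-explicit) SDF record -> molecule_graph
sdf_block_to_graph <- function(block, source_id, keep_largest, record = NA) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1L]]
  counts <- lines[4L]
  n_atom <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bond <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atom) || n_atom < 1L)
    stop(parse_error("no atoms in record", record))
  atom_lines <- lines[4L + seq_len(n_atom)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  bond_lines <- if (n_bond > 0L) lines[4L + n_atom + seq_len(n_bond)]
                else character(0)
  edges <- if (length(bond_lines)) {
    cbind(as.integer(substr(bond_lines, 1L, 3L)),
          as.integer(substr(bond_lines, 4L, 6L)))
  } else matrix(integer(0), ncol = 2L)
  charge <- chg_from_block(lines, n_atom)
  mol <- molecule_graph(elements, charge, edges, source_id)
  if (keep_largest) {
    comp <- graph_components(mol)
    if (max(comp) > 1L) {
      sizes <- tabulate(comp)
      mol <- subset_graph(mol, which(comp == which.max(sizes)))
    }
  }
  mol
}

#' Parse a molecular structure into a hydrogen-materialized graph
#'
#' Reads a single SMILES string or an MDL Molfile/SDF record, standardizes it
#' through OpenBabel (which adds every hydrogen implied by standard valence
#' and formal charge as an explicit atom), and returns the bond-type-agnostic
#' [molecule_graph]. Stereochemistry is discarded: stereoisomers written as
#' different SMILES parse to graphs with identical descriptor sets. When the
#' input holds several covalent fragments (a salt), only the largest fragment
#' is retained by default.
#'
#' @param text the structure: one SMILES string (an optional
#'   whitespace-separated identifier after it is used as `source_id`), or the
#'   full text of one V2000 Molfile/SDF record.
#' @param format `"smiles"` or `"sdf"`.
#' @param keep_largest keep only the largest covalent fragment (salt
#'   stripping). Set `FALSE` to keep all fragments in one graph.
#' @param source_id compound identifier; defaults to the identifier embedded
#'   in the record (SMILES trailing token or Molfile title line).
#' @return A [molecule_graph].
#' @examples
#' m <- parse_structure("O", "smiles")       # water: O + 2 explicit H
#' n_atoms(m)                                 # 3
#' parse_structure("CC(=O)[O-].[Na+]", "smiles")  # sodium salt stripped
#' @seealso [read_structures()] for files with many records.
#' @export
parse_structure <- function(text, format = c("smiles", "sdf"),
                            keep_largest = TRUE, source_id = NULL) {
  format <- match.arg(format)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop(parse_error("empty input", 1L))
  if (format == "smiles") {
    toks <- strsplit(trimws(text), "\\s+")[[1L]]
    smi <- toks[1L]
    if (is.null(source_id))
      source_id <- if (length(toks) > 1L) toks[2L] else smi
    out <- ob_to_sdf(paste0(smi, "\n"), "SMI")
    if (is.null(out)) stop(parse_error("invalid SMILES", 1L, smi))
  } else {
    title <- trimws(strsplit(text, "\n", fixed = TRUE)[[1L]][1L])
    if (is.null(source_id))
      source_id <- if (nzchar(title)) title else "mol1"
    if (!grepl("\\$\\$\\$\\$", text)) text <- paste0(text, "\n$$$$\n")
    out <- ob_to_sdf(text, "SDF")
    if (is.null(out)) stop(parse_error("invalid Molfile/SDF record", 1L))
  }
  sdf_block_to_graph(out, source_id, keep_largest, record = 1L)
}

# split raw SDF text into records on "$$$$" delimiter lines
split_sdf_records <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(list(paste(lines, collapse = "\n")))
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- mapply(function(s, e) paste(lines[s:e], collapse = "\n"),
                 starts, ends, SIMPLIFY = FALSE)
  recs[vapply(recs, function(r) nzchar(trimws(gsub("\\$\\$\\$\\$", "", r))),
              logical(1))]
}

#' Read many structures from a SMILES or SDF file
#'
#' SMILES files hold one record per line (`SMILES [identifier]`); SDF files
#' follow the V2000 specification with records separated by `$$$$`. Records
#' that fail to parse are skipped with a message to the condition log
#' (stderr), never to stdout; the indices of failed records are returned in
#' the `failed` attribute.
#'
#' @param path file path, or a character vector of lines via `text =`.
#' @param format `"smiles"` or `"sdf"`; guessed from the file extension
#'   (`.smi`/`.smiles` vs `.sdf`/`.mol`) when `NULL`.
#' @param keep_largest see [parse_structure()].
#' @param text optional character vector of raw lines instead of a file.
#' @return Named list of [molecule_graph] objects (names are compound
#'   identifiers; duplicates disambiguated), with attribute `failed` holding
#'   the 1-based indices of unparseable records.
#' @export
read_structures <- function(path = NULL, format = NULL, keep_largest = TRUE,
                            text = NULL) {
  if (is.null(text)) {
    if (is.null(format)) {
      ext <- tolower(tools::file_ext(path))
      format <- if (ext %in% c("sdf", "mol", "mdl")) "sdf" else "smiles"
    }
    text <- readLines(path, warn = FALSE)
  } else if (is.null(format)) {
    format <- "smiles"
  }
  format <- match.arg(format, c("smiles", "sdf"))
  records <- if (format == "smiles") {
    as.list(text[nzchar(trimws(text))])
  } else {
    split_sdf_records(paste(text, collapse = "\n"))
  }
  if (!length(records))
    stop(parse_error("empty input: no records found", NA_integer_))
  mols <- list()
  failed <- integer(0)
  for (i in seq_along(records)) {
    m <- tryCatch(parse_structure(records[[i]], format, keep_largest),
                  mnasar_parse_error = function(e) {
                    message(sprintf("record %d skipped: %s", i,
                                    conditionMessage(e)))
                    NULL
                  })
    if (is.null(m)) { failed <- c(failed, i); next }
    if (m$source_id %in% names(mols))
      m$source_id <- sprintf("%s.%d", m$source_id, i)
    mols[[m$source_id]] <- m
  }
  if (!length(mols))
    stop(parse_error("no parseable structures in input", NA_integer_))
  attr(mols, "failed") <- failed
  mols
}

#' Canonical SMILES of a structure
#'
#' OpenBabel canonical SMILES for a SMILES input; used to check that the
#' descriptor set is invariant under rewriting of the structure.
#'
#' @param smiles a single SMILES string.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", source = paste0(smiles, "\n")))
  out <- trimws(strsplit(out, "\\s+")[[1L]][1L])
  if (!nzchar(out)) stop(parse_error("invalid SMILES", 1L, smiles))
  out
}
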