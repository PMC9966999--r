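# Low-level molecule handling through Open Babel (ChemmineOB) and ChemmineR.
# All structure I/O in the package funnels through these helpers so that one
# toolkit defines SMILES validity, canonicalization and implicit hydrogens.

#' Test whether SMILES strings are parseable
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, `TRUE` where the string parses to a non-empty
#'   molecule.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    nzchar(sub("[\t\n].*$", "", out))
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES
#'
#' Returns the toolkit's canonical SMILES. Unparseable input is an error; use
#' [is_valid_smiles()] to screen first.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- sub("[\t\n].*$", "", out)
    if (!nzchar(out)) stop("unparseable SMILES: ", s, call. = FALSE)
    out
  }, character(1), USE.NAMES = FALSE)
}

# Heavy-atom count of a single-component SMILES.
heavy_atom_count <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  el <- sub("_.*$", "", rownames(ab))
  sum(el != "H")
}

#' Strip salts and canonicalize a SMILES string
#'
#' Keeps the largest organic fragment of a multi-component SMILES (counter
#' ions and solvents are dropped) and returns its canonical SMILES. Fragments
#' containing carbon are preferred over purely inorganic ones; ties are broken
#' by heavy-atom count, then lexicographically. The operation is idempotent.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical, salt-stripped SMILES.
#' @export
strip_salts_and_canonicalize <- function(smiles) {
  vapply(smiles, function(s) {
    can <- canonical_smiles(s)
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(can)
    has_c <- grepl("[cC]", gsub("Cl|Ca|Cd|Cu|Co|Cr|Cs|Sc", "", frags))
    pool <- if (any(has_c)) frags[has_c] else frags
    n_heavy <- vapply(pool, heavy_atom_count, numeric(1))
    best <- pool[order(-n_heavy, pool)][1L]
    canonical_smiles(best)
  }, character(1), USE.NAMES = FALSE)
}

# Molecular graph (heavy atoms) of a SMILES string: element labels plus a
# bond table with kekulized bond orders, as read from a V2000 block.
mol_graph <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  if (nrow(bb) > 0) {
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  }
  list(elements = elements, bonds = bonds)
}

# Serialize an (elements, bonds) graph as a V2000 molfile and return the
# toolkit's canonical SMILES. Coordinates are irrelevant and set to zero.
graph_to_smiles <- function(elements, bonds) {
  n <- length(elements)
  if (n == 0L) return("")
  lines <- c(
    "", "  chemsar", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, elements),
    if (nrow(bonds) > 0)
      sprintf("%3d%3d%3d  0  0  0  0", bonds$a, bonds$b, bonds$order),
    "M  END", "$$$$", ""
  )
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste(lines, collapse = "\n"))
  sub("[\t\n].*$", "", out)
}

# Indices of atoms in the Murcko framework: the 2-core of the heavy-atom
# graph (iterative pruning of terminal atoms leaves rings and linkers), plus
# atoms attached to the core by a bond of order >= 2 (e.g. carbonyl oxygens
# on rings or linkers, the dominant toolkit convention).
framework_atoms <- function(graph) {
  n <- length(graph$elements)
  bonds <- graph$bonds
  alive <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    keep <- alive[bonds$a] & alive[bonds$b]
    tab <- table(factor(c(bonds$a[keep], bonds$b[keep]), levels = seq_len(n)))
    deg <- as.integer(tab)
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  core <- which(alive)
  if (length(core) == 0L) return(integer(0))
  multi <- bonds[bonds$order >= 2L, , drop = FALSE]
  exo <- c(multi$a[multi$b %in% core & !(multi$a %in% core)],
           multi$b[multi$a %in% core & !(multi$b %in% core)])
  sort(unique(c(core, exo)))
}

# Subgraph restricted to the given atom indices, with bonds renumbered.
subgraph <- function(graph, idx) {
  remap <- integer(length(graph$elements))
  remap[idx] <- seq_along(idx)
  keep <- graph$bonds$a %in% idx & graph$bonds$b %in% idx
  bonds <- graph$bonds[keep, , drop = FALSE]
  bonds$a <- remap[bonds$a]
  bonds$b <- remap[bonds$b]
  list(elements = graph$elements[idx], bonds = bonds)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Removes side chains (terminal atoms, iteratively) and keeps the union of
#' ring systems and linkers. Atoms double-bonded to the framework (such as
#' carbonyl oxygens) are retained. Acyclic molecules have no scaffold and
#' yield the empty-string sentinel.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical scaffold SMILES; `""` for acyclic
#'   molecules.
#' @export
murcko_scaffold <- function(smiles) {
  vapply(smiles, function(s) {
    if (!is_valid_smiles(s)) stop("unparseable SMILES: ", s, call. = FALSE)
    g <- mol_graph(s)
    idx <- framework_atoms(g)
    if (length(idx) == 0L) return("")
    graph_to_smiles_checked(subgraph(g, idx))
  }, character(1), USE.NAMES = FALSE)
}

#' Cyclic skeleton of a molecule
#'
#' The Murcko framework with every atom genericized to carbon and every bond
#' to a single bond, so that molecules differing only in heteroatoms or bond
#' orders share one skeleton. Acyclic molecules yield `""`.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical skeleton SMILES.
#' @export
cyclic_skeleton <- function(smiles) {
  vapply(smiles, function(s) {
    if (!is_valid_smiles(s)) stop("unparseable SMILES: ", s, call. = FALSE)
    g <- mol_graph(s)
    idx <- framework_atoms(g)
    if (length(idx) == 0L) return("")
    sg <- subgraph(g, idx)
    sg$elements[] <- "C"
    sg$bonds$order <- 1L
    graph_to_smiles_checked(sg)
  }, character(1), USE.NAMES = FALSE)
}

graph_to_smiles_checked <- function(sg) {
  out <- graph_to_smiles(sg$elements, sg$bonds)
  if (!nzchar(out)) stop("scaffold serialization failed", call. = FALSE)
  out
}
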