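# Drug-likeness descriptors and molecular fingerprints, computed through
# Open Babel. Substructure-key schemes (PubChem, Klekota-Roth) are supported
# through a pluggable SMARTS key table or an external fingerprint table.

ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

ob_mol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

#' Compute the six drug-likeness descriptors
#'
#' Molecular weight (MW, g/mol), octanol-water partition coefficient (LogP,
#' atom-contribution estimate), hydrogen-bond acceptor and donor counts (nHA,
#' nHD), rotatable-bond count (nRot, single non-ring bonds between
#' non-terminal, non-triple-bonded atoms) and topological polar surface area
#' (TPSA, squared angstroms).
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame with columns `MW`, `LogP`, `nHA`, `nHD`, `nRot`,
#'   `TPSA`, one row per molecule.
#' @export
compute_druglikeness <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    if (!is_valid_smiles(s)) stop("unparseable SMILES: ", s, call. = FALSE)
    m <- ob_mol(s)
    p <- ChemmineOB::prop_OB(m)
    nrot <- ChemmineOB::smartsSearch_OB(m, ROTATABLE_SMARTS,
                                        uniqueMatches = TRUE)
    data.frame(MW = p$MW, LogP = p$logP, nHA = as.integer(p$HBA2),
               nHD = as.integer(p$HBD), nRot = as.integer(nrot),
               TPSA = p$TPSA)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Declared widths of the natively supported fingerprint schemes. MACCS is
# reported with the toolkit's 167 positions (bit 1 corresponds to MACCS key
# 1; position 167 is never set but kept so indices match key numbers).
fp_widths <- c(maccs = 167L, ecfp4 = 2048L, fp2 = 1024L)

#' Compute a molecular fingerprint
#'
#' Native schemes: `"maccs"` (167 positions, key-indexed), `"ecfp4"`
#' (circular, radius 2, folded to `width` bits; default 2048) and `"fp2"`
#' (Open Babel linear-fragment fingerprint). The substructure-key schemes
#' `"pubchem"` and `"klekota_roth"` require a SMARTS key table supplied via
#' `key_table` (see [smarts_key_fingerprint()]); without one a capability
#' error points at the remedy.
#'
#' @param smiles character vector of valid SMILES.
#' @param scheme fingerprint scheme identifier.
#' @param width fold width for `ecfp4`.
#' @param key_table character vector of SMARTS patterns for substructure-key
#'   schemes.
#' @param counts for key-table schemes, return occurrence counts instead of
#'   binary bits.
#' @return integer matrix, one row per molecule, with attribute `scheme`.
#' @export
compute_fingerprint <- function(smiles,
                                scheme = c("maccs", "ecfp4", "fp2",
                                           "pubchem", "klekota_roth"),
                                width = 2048L, key_table = NULL,
                                counts = FALSE) {
  scheme <- match.arg(scheme)
  if (scheme %in% c("pubchem", "klekota_roth")) {
    if (is.null(key_table))
      stop("scheme '", scheme, "' needs a SMARTS key table: pass key_table ",
           "(one SMARTS per key) or load a precomputed table with ",
           "load_fingerprint_table()", call. = FALSE)
    return(smarts_key_fingerprint(smiles, key_table, counts = counts,
                                  scheme = scheme))
  }
  ob_name <- c(maccs = "MACCS", ecfp4 = "ECFP4", fp2 = "FP2")[[scheme]]
  out <- t(vapply(smiles, function(s) {
    if (!is_valid_smiles(s)) stop("unparseable SMILES: ", s, call. = FALSE)
    bits <- as.integer(ChemmineOB::fingerprint_OB(ob_mol(s), ob_name))
    if (scheme == "maccs") {
      bits[seq_len(167L)]
    } else if (scheme == "ecfp4") {
      fold_bits(bits, width)
    } else {
      bits
    }
  }, integer(if (scheme == "ecfp4") width else fp_widths[[scheme]])))
  rownames(out) <- names(smiles)
  structure(out, scheme = scheme)
}

# Fold a bit vector to the target width by OR-ing congruent positions.
fold_bits <- function(bits, width) {
  if (length(bits) %% width != 0)
    stop("fold width must divide the native fingerprint length",
         call. = FALSE)
  as.integer(rowSums(matrix(bits, nrow = width)) > 0)
}

#' Fingerprint molecules against a SMARTS key table
#'
#' The generic substructure-key engine behind PubChem- or Klekota-Roth-style
#' fingerprints: key j is set (or counted) when SMARTS pattern j matches.
#'
#' @param smiles character vector of valid SMILES.
#' @param smarts character vector of SMARTS patterns defining the keys.
#' @param counts return match counts instead of binary bits.
#' @param scheme label stored in the `scheme` attribute.
#' @return integer matrix, one column per key.
#' @export
smarts_key_fingerprint <- function(smiles, smarts, counts = FALSE,
                                   scheme = "smarts_keys") {
  out <- t(vapply(smiles, function(s) {
    if (!is_valid_smiles(s)) stop("unparseable SMILES: ", s, call. = FALSE)
    m <- ob_mol(s)
    hits <- vapply(smarts, function(q)
      as.integer(ChemmineOB::smartsSearch_OB(m, q, uniqueMatches = TRUE)),
      integer(1))
    if (counts) hits else as.integer(hits > 0)
  }, integer(length(smarts))))
  rownames(out) <- names(smiles)
  structure(out, scheme = scheme)
}

#' Load a precomputed fingerprint table
#'
#' Reads a CSV with one row per compound (id column first, or named via
#' `id_column`) and homogeneous numeric fingerprint columns, as produced by
#' external fingerprint tools.
#'
#' @param path CSV file.
#' @param id_column name of the compound id column; defaults to the first.
#' @param expected_ids optional compound ids to check coverage against;
#'   orphans on either side are reported as warnings.
#' @return integer matrix with compound ids as rownames and attribute
#'   `scheme = "external"`; empty input yields a 0-row matrix with a warning.
#' @export
load_fingerprint_table <- function(path, id_column = NULL,
                                   expected_ids = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty fingerprint table: ", path)
    return(structure(matrix(integer(0), 0, max(ncol(raw) - 1L, 0L)),
                     scheme = "external"))
  }
  if (is.null(id_column)) id_column <- names(raw)[1]
  ids <- as.character(raw[[id_column]])
  mat <- raw[, setdiff(names(raw), id_column), drop = FALSE]
  numeric_ok <- vapply(mat, is.numeric, logical(1))
  if (!all(numeric_ok))
    stop("non-numeric fingerprint column(s): ",
         paste(names(mat)[!numeric_ok], collapse = ", "), call. = FALSE)
  out <- as.matrix(mat)
  storage.mode(out) <- "integer"
  rownames(out) <- ids
  if (!is.null(expected_ids)) {
    missing_fp <- setdiff(expected_ids, ids)
    orphan_fp <- setdiff(ids, expected_ids)
    if (length(missing_fp) > 0)
      warning("no fingerprint for: ", paste(missing_fp, collapse = ", "))
    if (length(orphan_fp) > 0)
      warning("fingerprint rows without dataset match: ",
              paste(orphan_fp, collapse = ", "))
  }
  structure(out, scheme = "external")
}
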