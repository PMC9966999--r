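# Scaffold analysis: Murcko scaffold tables with enrichment factors,
# diversity metrics, representative-scaffold selection, cyclic-skeleton
# grouping and a simplified R-group decomposition.

#' Build the scaffold table of a curated dataset
#'
#' One row per distinct Murcko scaffold, ranked by frequency (ties broken
#' lexicographically by scaffold SMILES). The enrichment factor (EF) of a
#' scaffold is its active proportion (members with
#' `pic50 >= activity_threshold`) divided by the dataset's active
#' proportion. The `ef` column uses the dataset proportion rounded to two
#' decimals (the convention of printed enrichment tables, e.g. 1/0.51 =
#' 1.961); `ef_exact` uses the exact fraction. Acyclic molecules are grouped
#' under the empty-scaffold sentinel `""`.
#'
#' @param records curated data.frame with `compound_id`, `smiles`, `pic50`.
#' @param activity_threshold pIC50 cut for "active" in the EF sense.
#' @param scaffolds,skeletons optional precomputed scaffold/skeleton SMILES
#'   aligned with `records` (computed from `records$smiles` if omitted).
#' @return data.frame with columns `scaffold_smiles`, `skeleton_smiles`,
#'   `frequency`, `n_active`, `ef`, `ef_exact` and list-column
#'   `member_ids`; attributes `active_proportion` and `activity_threshold`.
#' @export
scaffold_table <- function(records, activity_threshold = 7.0,
                           scaffolds = NULL, skeletons = NULL) {
  if (nrow(records) < 1L) stop("empty dataset", call. = FALSE)
  if (is.null(scaffolds)) scaffolds <- murcko_scaffold(records$smiles)
  if (is.null(skeletons)) skeletons <- cyclic_skeleton(records$smiles)
  if (all(scaffolds == ""))
    warning("all compounds are acyclic; only the empty-scaffold group")
  active <- records$pic50 >= activity_threshold
  p_exact <- mean(active)
  p_round <- round(p_exact, 2)

  idx <- split(seq_len(nrow(records)), scaffolds)
  rows <- lapply(names(idx), function(sc) {
    i <- idx[[sc]]
    n_act <- sum(active[i])
    data.frame(scaffold_smiles = sc,
               skeleton_smiles = skeletons[i][1],
               frequency = length(i),
               n_active = n_act,
               ef = if (p_round > 0) (n_act / length(i)) / p_round else NA,
               ef_exact = if (p_exact > 0) (n_act / length(i)) / p_exact
                          else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$member_ids <- lapply(names(idx), function(sc)
    records$compound_id[idx[[sc]]])
  ord <- order(-out$frequency, out$scaffold_smiles)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, active_proportion = p_exact,
            active_proportion_rounded = p_round,
            activity_threshold = activity_threshold)
}

#' Diversity ratios from scaffold counts
#'
#' The arithmetic behind a scaffold diversity table: given the number of
#' compounds (N), Murcko scaffolds (Ns), singleton scaffolds (Nss) and
#' cyclic skeletons (Ncsk), returns the ratios Ns/N, Nss/N, Ncsk/N and
#' Ncsk/Ns, rounded to three decimals (exact values as attribute).
#'
#' @param N,Ns,Nss,Ncsk non-negative counts with `Nss <= Ns <= N` and
#'   `Ncsk <= Ns`.
#' @return named numeric vector of the four ratios (3 decimals), with
#'   attribute `exact`.
#' @export
diversity_ratios <- function(N, Ns, Nss, Ncsk) {
  stopifnot(N >= 1, Nss <= Ns, Ns <= N, Ncsk <= Ns)
  exact <- c(Ns_N = Ns / N, Nss_N = Nss / N, Ncsk_N = Ncsk / N,
             Ncsk_Ns = if (Ns > 0) Ncsk / Ns else NA_real_)
  structure(round(exact, 3), exact = exact)
}

#' Scaffold diversity report
#'
#' Counts compounds (N), distinct Murcko scaffolds (Ns), singleton scaffolds
#' (Nss, frequency 1) and distinct cyclic skeletons (Ncsk) and the four
#' diversity ratios. Acyclic molecules count toward N but contribute no
#' scaffold or skeleton.
#'
#' @param records curated data.frame.
#' @param subset optional logical vector selecting a subset of `records`.
#' @param scaffolds,skeletons optional precomputed SMILES aligned with
#'   `records` (before subsetting).
#' @return one-row data.frame with counts and rounded ratios.
#' @export
diversity_report <- function(records, subset = NULL, scaffolds = NULL,
                             skeletons = NULL) {
  if (is.null(scaffolds)) scaffolds <- murcko_scaffold(records$smiles)
  if (is.null(skeletons)) skeletons <- cyclic_skeleton(records$smiles)
  if (!is.null(subset)) {
    scaffolds <- scaffolds[subset]
    skeletons <- skeletons[subset]
  }
  if (length(scaffolds) == 0L) stop("empty subset", call. = FALSE)
  n <- length(scaffolds)
  sc <- scaffolds[scaffolds != ""]
  sk <- skeletons[skeletons != ""]
  ns <- length(unique(sc))
  nss <- sum(table(sc) == 1L)
  ncsk <- length(unique(sk))
  ratios <- diversity_ratios(n, ns, nss, ncsk)
  data.frame(N = n, Ns = ns, Nss = nss, Ncsk = ncsk,
             Ns_N = ratios[["Ns_N"]], Nss_N = ratios[["Nss_N"]],
             Ncsk_N = ratios[["Ncsk_N"]], Ncsk_Ns = ratios[["Ncsk_Ns"]])
}

#' Select representative scaffolds
#'
#' Keeps scaffolds with `frequency >= min_frequency` OR `ef >= min_ef`
#' (either criterion suffices), excluding the empty-scaffold group, ranked
#' by EF then frequency, both descending.
#'
#' @param scaffolds a [scaffold_table()].
#' @param min_frequency frequency criterion (default 10).
#' @param min_ef enrichment-factor criterion (default 1.0).
#' @return filtered, re-ranked scaffold table.
#' @export
select_representative <- function(scaffolds, min_frequency = 10,
                                  min_ef = 1.0) {
  keep <- scaffolds$scaffold_smiles != "" &
    (scaffolds$frequency >= min_frequency | scaffolds$ef >= min_ef)
  out <- scaffolds[keep, , drop = FALSE]
  out <- out[order(-out$ef, -out$frequency, out$scaffold_smiles), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group scaffolds by cyclic skeleton
#'
#' Default grouping puts scaffolds with identical cyclic skeletons in one
#' group. `manual_groups` (a list of integer vectors of scaffold-table row
#' indices) overrides: listed scaffolds are merged as given, the rest
#' grouped by skeleton.
#'
#' @param scaffolds a [scaffold_table()].
#' @param manual_groups optional list of scaffold row-index sets.
#' @return list of groups; each group is a list with `scaffold_idx`
#'   (rows of `scaffolds`), `skeletons` and `member_ids`.
#' @export
group_by_skeleton <- function(scaffolds, manual_groups = NULL) {
  n <- nrow(scaffolds)
  assigned <- rep(FALSE, n)
  groups <- list()
  if (!is.null(manual_groups)) {
    for (g in manual_groups) {
      g <- as.integer(g)
      if (any(g < 1L | g > n))
        stop("manual group references unknown scaffold row(s): ",
             paste(g[g < 1L | g > n], collapse = ", "), call. = FALSE)
      if (any(assigned[g]))
        stop("manual groups overlap", call. = FALSE)
      assigned[g] <- TRUE
      groups[[length(groups) + 1L]] <- g
    }
  }
  rest <- which(!assigned)
  if (length(rest) > 0) {
    by_sk <- split(rest, scaffolds$skeleton_smiles[rest])
    groups <- c(groups, unname(by_sk))
  }
  lapply(groups, function(g) list(
    scaffold_idx = g,
    skeletons = unique(scaffolds$skeleton_smiles[g]),
    member_ids = unlist(scaffolds$member_ids[g], use.names = FALSE)))
}

# Deterministic atom ranks on a molecular graph via iterative neighborhood
# refinement (Morgan-style); ties within symmetry orbits share a rank.
canonical_ranks <- function(graph) {
  n <- length(graph$elements)
  deg <- integer(n)
  for (k in seq_len(nrow(graph$bonds))) {
    deg[graph$bonds$a[k]] <- deg[graph$bonds$a[k]] + 1L
    deg[graph$bonds$b[k]] <- deg[graph$bonds$b[k]] + 1L
  }
  start <- paste(graph$elements, deg)
  inv <- match(start, sort(unique(start)))
  nbrs <- lapply(seq_len(n), function(i)
    c(graph$bonds$b[graph$bonds$a == i], graph$bonds$a[graph$bonds$b == i]))
  repeat {
    key <- vapply(seq_len(n), function(i)
      paste(inv[i], paste(sort(inv[nbrs[[i]]]), collapse = "|")),
      character(1))
    nxt <- match(key, sort(unique(key)))
    if (length(unique(nxt)) == length(unique(inv))) break
    inv <- nxt
  }
  inv
}

#' Simplified R-group decomposition against a scaffold core
#'
#' For members whose Murcko scaffold equals `core_smiles`, lists each side
#' chain with its attachment position on the core. Positions are numbered by
#' the symmetry-aware rank of the attachment atom on the member's framework,
#' so chemically equivalent positions share a label. Members whose scaffold
#' differs from the core are reported in the `"unmatched"` attribute.
#'
#' @param member_smiles character vector of member SMILES.
#' @param core_smiles scaffold SMILES (will be canonicalized).
#' @param member_ids optional ids; defaults to the SMILES.
#' @return data.frame with `compound_id`, `position` (e.g. `"R1"`),
#'   `substituent` (canonical SMILES); attribute `unmatched`.
#' @export
rgroup_decompose <- function(member_smiles, core_smiles,
                             member_ids = member_smiles) {
  if (!is_valid_smiles(core_smiles))
    stop("core is not a valid structure", call. = FALSE)
  core_canon <- murcko_scaffold(core_smiles)
  if (core_canon == "")
    stop("core has no ring system", call. = FALSE)
  rows <- list()
  unmatched <- character(0)
  for (j in seq_along(member_smiles)) {
    s <- member_smiles[j]
    if (murcko_scaffold(s) != core_canon) {
      unmatched <- c(unmatched, member_ids[j])
      next
    }
    g <- mol_graph(s)
    fw <- framework_atoms(g)
    ranks <- canonical_ranks(subgraph(g, fw))
    side <- setdiff(seq_along(g$elements), fw)
    if (length(side) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = member_ids[j], position = NA_character_,
        substituent = "", stringsAsFactors = FALSE)
      next
    }
    # connected components of the side-chain atoms
    comp <- seq_along(g$elements)
    repeat {
      moved <- FALSE
      for (k in seq_len(nrow(g$bonds))) {
        a <- g$bonds$a[k]; b <- g$bonds$b[k]
        if (a %in% side && b %in% side && comp[a] != comp[b]) {
          comp[comp == max(comp[a], comp[b])] <- min(comp[a], comp[b])
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    for (cc in unique(comp[side])) {
      atoms <- side[comp[side] == cc]
      touching <- g$bonds[(g$bonds$a %in% atoms & g$bonds$b %in% fw) |
                          (g$bonds$b %in% atoms & g$bonds$a %in% fw), ,
                          drop = FALSE]
      anchor <- unique(ifelse(touching$a %in% fw, touching$a, touching$b))
      pos <- ranks[match(anchor[1], fw)]
      sub_smi <- graph_to_smiles_checked(subgraph(g, sort(atoms)))
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = member_ids[j], position = paste0("R", pos),
        substituent = sub_smi, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(compound_id = character(0), position = character(0),
               substituent = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, unmatched = unmatched, core = core_canon)
}
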