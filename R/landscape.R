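# Structure-activity landscape: pairwise Tanimoto similarity, SAS-map
# quadrants, SALI scores, activity-cliff pairs and AC generators.

#' Pairwise Tanimoto similarity matrix
#'
#' Tanimoto = |A and B| / |A or B| for binary fingerprints; the generalized
#' form sum(min)/sum(max) for count fingerprints. Pairs of all-zero
#' fingerprints get similarity 0 with a warning.
#'
#' @param fingerprints numeric matrix, one row per compound (same scheme and
#'   width for all rows).
#' @return symmetric n x n similarity matrix with unit diagonal (except
#'   all-zero rows).
#' @export
pairwise_similarity <- function(fingerprints) {
  x <- as.matrix(fingerprints)
  if (nrow(x) < 2L) stop("need at least two fingerprints", call. = FALSE)
  binary <- all(x %in% c(0, 1))
  if (binary) {
    inter <- tcrossprod(x)
    ones <- rowSums(x)
    union <- outer(ones, ones, `+`) - inter
  } else {
    n <- nrow(x)
    inter <- union <- matrix(0, n, n)
    for (i in seq_len(n)) {
      mins <- t(pmin(t(x), x[i, ]))
      maxs <- t(pmax(t(x), x[i, ]))
      inter[i, ] <- rowSums(mins)
      union[i, ] <- rowSums(maxs)
    }
  }
  sim <- ifelse(union > 0, inter / union, 0)
  if (any(union == 0))
    warning("all-zero fingerprint pair(s): similarity set to 0")
  dimnames(sim) <- list(rownames(x), rownames(x))
  sim
}

#' Structure-activity landscape index (SALI)
#'
#' SALI = activity difference / (1 - similarity). Identical structures
#' (similarity 1) with differing activity give `Inf`; with equal activity,
#' 0 by convention.
#'
#' @param activity_diff non-negative activity differences (pIC50 units).
#' @param similarity similarities in \[0, 1\].
#' @return numeric vector (possibly containing `Inf`).
#' @export
sali <- function(activity_diff, similarity) {
  stopifnot(all(activity_diff >= 0), all(similarity >= 0 & similarity <= 1))
  out <- ifelse(similarity < 1, activity_diff / (1 - similarity),
                ifelse(activity_diff > 0, Inf, 0))
  as.numeric(out)
}

#' Build a SAS map from a curated dataset
#'
#' Emits all n(n-1)/2 unordered compound pairs with their fingerprint
#' similarity, absolute pIC50 difference, SALI score and SAS-map quadrant:
#' `activity_cliff` (similar, large activity gap), `smooth` (similar,
#' similar activity), `scaffold_hop` (dissimilar, similar activity) and
#' `nondescript` (dissimilar, large gap). Thresholds are recorded as
#' attributes.
#'
#' @param records curated data.frame (`compound_id`, `pic50`).
#' @param fingerprints fingerprint matrix with rows aligned to `records`
#'   (or rownames matching `compound_id`).
#' @param sim_threshold similarity boundary (default 0.5).
#' @param act_threshold activity-difference boundary in pIC50 units
#'   (default 2.0).
#' @return data.frame of SAS points `id_a`, `id_b`, `similarity`,
#'   `activity_diff`, `sali`, `quadrant`; `id_a < id_b` lexicographically.
#' @export
sas_map <- function(records, fingerprints, sim_threshold = 0.5,
                    act_threshold = 2.0) {
  n <- nrow(records)
  if (n < 2L) {
    warning("fewer than two records: empty SAS map")
    return(structure(data.frame(id_a = character(0), id_b = character(0),
                                similarity = numeric(0),
                                activity_diff = numeric(0),
                                sali = numeric(0), quadrant = character(0)),
                     sim_threshold = sim_threshold,
                     act_threshold = act_threshold))
  }
  fp <- as.matrix(fingerprints)
  if (!is.null(rownames(fp)) && all(records$compound_id %in% rownames(fp)))
    fp <- fp[records$compound_id, , drop = FALSE]
  stopifnot(nrow(fp) == n)
  sim <- pairwise_similarity(fp)
  pair <- which(upper.tri(sim), arr.ind = TRUE)
  ids <- as.character(records$compound_id)
  a <- ids[pair[, 1]]; b <- ids[pair[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  s <- sim[pair]
  d <- abs(records$pic50[pair[, 1]] - records$pic50[pair[, 2]])
  quadrant <- ifelse(s >= sim_threshold,
                     ifelse(d >= act_threshold, "activity_cliff", "smooth"),
                     ifelse(d < act_threshold, "scaffold_hop",
                            "nondescript"))
  out <- data.frame(id_a = a, id_b = b, similarity = s, activity_diff = d,
                    sali = sali(d, s), quadrant = quadrant,
                    stringsAsFactors = FALSE)
  structure(out[order(out$id_a, out$id_b), , drop = FALSE],
            sim_threshold = sim_threshold, act_threshold = act_threshold)
}

#' Activity-cliff generators from a SAS map
#'
#' Counts, per compound, the activity-cliff pairs it participates in and
#' keeps compounds reaching `min_count`, ranked by count (descending) then
#' id.
#'
#' @param points a [sas_map()] result.
#' @param min_count minimum number of AC pairs (default 2).
#' @return list with `ac_pairs` (the activity-cliff rows of `points`) and
#'   `generators` (data.frame `compound_id`, `count`).
#' @export
ac_generators <- function(points, min_count = 2L) {
  ac <- points[points$quadrant == "activity_cliff", , drop = FALSE]
  counts <- table(c(ac$id_a, ac$id_b))
  keep <- counts[counts >= min_count]
  gen <- data.frame(compound_id = as.character(names(keep)),
                    count = as.integer(keep), stringsAsFactors = FALSE)
  if (nrow(gen) == 0L)
    gen <- data.frame(compound_id = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  gen <- gen[order(-gen$count, gen$compound_id), , drop = FALSE]
  rownames(gen) <- NULL
  list(ac_pairs = ac, generators = gen)
}

#' Consensus AC generators across fingerprint schemes
#'
#' The generators present in every scheme's report (the "maximum common"
#' generators).
#'
#' @param reports list of [ac_generators()] results.
#' @return character vector of consensus compound ids.
#' @export
consensus_generators <- function(reports) {
  sets <- lapply(reports, function(r) r$generators$compound_id)
  Reduce(intersect, sets)
}
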