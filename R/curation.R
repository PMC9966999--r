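# Dataset curation: loading activity tables, pIC50 transformation, potency
# class binning, random oversampling and train/test splitting.

unit_factors <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Potency class scheme on the pIC50 scale
#'
#' Default cut points 8, 7 and 6 define four classes: potent (pIC50 >= 8),
#' active (8 > pIC50 >= 7), intermediate (7 > pIC50 >= 6) and inactive
#' (pIC50 < 6). Boundaries belong to the upper class. The potent and active
#' classes together form the binary positive class used for enrichment and
#' binary collapse.
#'
#' @param thresholds strictly decreasing numeric cut points.
#' @param labels class labels, most potent first; one more than thresholds.
#' @param binary_positive labels counted as "active" in binary summaries.
#' @return an object of class `activity_scheme`.
#' @export
activity_class_scheme <- function(thresholds = c(8, 7, 6),
                                  labels = c("potent", "active",
                                             "intermediate", "inactive"),
                                  binary_positive = c("potent", "active")) {
  stopifnot(length(labels) == length(thresholds) + 1L,
            all(diff(thresholds) < 0),
            all(binary_positive %in% labels))
  structure(list(thresholds = thresholds, labels = labels,
                 binary_positive = binary_positive),
            class = "activity_scheme")
}

#' Convert an IC50 value to pIC50
#'
#' pIC50 = -log10(IC50 in mol/L).
#'
#' @param value positive IC50 values.
#' @param unit concentration unit, one of `"M"`, `"mM"`, `"uM"`, `"nM"`,
#'   `"pM"`; recycled against `value`.
#' @return numeric pIC50 values.
#' @export
compute_pic50 <- function(value, unit = "nM") {
  if (any(!is.finite(value) | value <= 0))
    stop("IC50 values must be positive and finite", call. = FALSE)
  unit <- match.arg(unit, names(unit_factors), several.ok = TRUE)
  unname(-log10(value * unit_factors[unit]))
}

#' Assign potency classes from pIC50 values
#'
#' @param pic50 numeric pIC50 values.
#' @param scheme an [activity_class_scheme()].
#' @return factor of class labels, ordered most potent first.
#' @export
assign_activity_class <- function(pic50, scheme = activity_class_scheme()) {
  if (any(!is.finite(pic50))) stop("pIC50 must be finite", call. = FALSE)
  k <- length(scheme$thresholds)
  idx <- (k + 1L) - findInterval(pic50, rev(scheme$thresholds))
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Load and curate a compound activity table
#'
#' Reads a CSV/TSV table (or an SDF with activity properties), salt-strips
#' and canonicalizes structures, computes pIC50 from IC50 where needed, and
#' assigns potency classes. Rows with unparseable SMILES, non-positive IC50,
#' duplicated compound ids or duplicated structures are rejected; the reasons
#' are attached as the `"rejected"` attribute and reported via `message()`.
#'
#' @param path input file.
#' @param format `"csv"`, `"tsv"` or `"sdf"`.
#' @param column_map named list mapping the roles `compound_id`, `smiles`,
#'   `ic50`, `unit`, `pic50`, `category` to column (or SDF property) names.
#' @param ic50_unit fallback IC50 unit when the table has no unit column.
#'   When IC50 values are present without any declared unit, nanomolar is
#'   assumed and announced loudly.
#' @param scheme an [activity_class_scheme()].
#' @return data.frame with columns `compound_id`, `smiles`, `ic50` (mol/L,
#'   `NA` if only pIC50 was given), `pic50`, `activity_class`, `category`.
#' @export
load_dataset <- function(path,
                         format = c("csv", "tsv", "sdf"),
                         column_map = list(),
                         ic50_unit = NULL,
                         scheme = activity_class_scheme()) {
  format <- match.arg(format)
  cmap <- utils::modifyList(
    list(compound_id = "compound_id", smiles = "smiles", ic50 = "ic50",
         unit = "ic50_unit", pic50 = "pic50", category = "category"),
    column_map)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format %in% c("csv", "tsv")) {
    raw <- utils::read.table(path, header = TRUE,
                             sep = if (format == "csv") "," else "\t",
                             stringsAsFactors = FALSE, comment.char = "",
                             quote = "\"")
  } else {
    sdfs <- ChemmineR::read.SDFset(path)
    props <- lapply(ChemmineR::datablock(sdfs), function(x) as.list(x))
    smi <- tryCatch(
      vapply(seq_along(sdfs), function(i) {
        txt <- paste(c(as(sdfs[[i]], "character"), ""), collapse = "\n")
        sub("[\t\n].*$", "", ChemmineOB::convertFormat("SDF", "CAN", txt))
      }, character(1)),
      error = function(e) stop("SDF conversion failed: ", conditionMessage(e),
                               call. = FALSE))
    grab <- function(key) vapply(props, function(p)
      if (!is.null(p[[key]])) as.character(p[[key]]) else NA_character_,
      character(1))
    raw <- data.frame(stringsAsFactors = FALSE,
                      check.names = FALSE, smiles = smi)
    raw[[cmap$compound_id]] <- ChemmineR::sdfid(sdfs)
    for (role in c("ic50", "unit", "pic50", "category"))
      raw[[cmap[[role]]]] <- grab(cmap[[role]])
    cmap$smiles <- "smiles"
  }

  if (!cmap$smiles %in% names(raw))
    stop("missing required SMILES column '", cmap$smiles, "'", call. = FALSE)
  has_ic50 <- cmap$ic50 %in% names(raw)
  has_pic50 <- cmap$pic50 %in% names(raw)
  if (!has_ic50 && !has_pic50)
    stop("need an IC50 or a pIC50 column", call. = FALSE)

  n <- nrow(raw)
  if (n == 0L) stop("empty dataset: no rows", call. = FALSE)
  ids <- if (cmap$compound_id %in% names(raw))
    as.character(raw[[cmap$compound_id]]) else sprintf("cmpd_%04d", seq_len(n))
  smiles_in <- as.character(raw[[cmap$smiles]])
  category <- if (cmap$category %in% names(raw))
    as.character(raw[[cmap$category]]) else rep("unknown", n)
  category[is.na(category) | !nzchar(category)] <- "unknown"

  units <- NULL
  if (has_ic50) {
    if (cmap$unit %in% names(raw)) {
      units <- as.character(raw[[cmap$unit]])
    } else if (!is.null(ic50_unit)) {
      units <- rep(ic50_unit, n)
    } else {
      message("No IC50 unit column and no ic50_unit given: ",
              "assuming nanomolar (nM) for all IC50 values.")
      units <- rep("nM", n)
    }
  }

  rejected <- data.frame(row = integer(0), compound_id = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  reject <- function(i, why) {
    rejected[nrow(rejected) + 1L, ] <<- list(i, ids[i], why)
  }

  keep <- logical(n)
  smiles_clean <- pic50 <- ic50_mol <- rep(NA_real_, n)
  smiles_clean <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(smiles_in[i]) || !is_valid_smiles(smiles_in[i])) {
      reject(i, "unparseable SMILES"); next
    }
    smiles_clean[i] <- strip_salts_and_canonicalize(smiles_in[i])
    p <- if (has_pic50) suppressWarnings(as.numeric(raw[[cmap$pic50]][i]))
         else NA_real_
    v <- if (has_ic50) suppressWarnings(as.numeric(raw[[cmap$ic50]][i]))
         else NA_real_
    if (is.na(p) && is.na(v)) { reject(i, "no activity value"); next }
    if (!is.na(v)) {
      if (v <= 0) { reject(i, "non-positive IC50"); next }
      u <- units[i]
      if (is.na(u) || !u %in% names(unit_factors)) {
        reject(i, paste0("unknown IC50 unit '", u, "'")); next
      }
      ic50_mol[i] <- v * unit_factors[[u]]
      p_from_ic50 <- -log10(ic50_mol[i])
      if (!is.na(p) && abs(p - p_from_ic50) > 1e-6) {
        reject(i, "inconsistent IC50 and pIC50"); next
      }
      p <- p_from_ic50
    }
    pic50[i] <- p
    keep[i] <- TRUE
  }

  # duplicate ids, then duplicate structures: keep first occurrence
  idx <- which(keep)
  dup_id <- idx[duplicated(ids[idx])]
  for (i in dup_id) { reject(i, "duplicate compound_id"); keep[i] <- FALSE }
  idx <- which(keep)
  dup_str <- idx[duplicated(smiles_clean[idx])]
  for (i in dup_str) { reject(i, "duplicate structure"); keep[i] <- FALSE }

  if (nrow(rejected) > 0)
    message(nrow(rejected), " row(s) rejected: ",
            paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
                  collapse = "; "))
  if (!any(keep)) stop("empty dataset: no valid rows", call. = FALSE)

  out <- data.frame(compound_id = ids[keep], smiles = smiles_clean[keep],
                    ic50 = ic50_mol[keep], pic50 = pic50[keep],
                    stringsAsFactors = FALSE)
  out$activity_class <- assign_activity_class(out$pic50, scheme)
  out$category <- factor(category[keep],
                         levels = union(c("steroidal", "nonsteroidal",
                                          "unknown"), unique(category[keep])))
  attr(out, "rejected") <- rejected
  rownames(out) <- NULL
  out
}

#' Balance potency classes by random oversampling
#'
#' Randomly duplicates records within each minority class until every class
#' count equals the majority class count. All original records are retained;
#' duplicates are drawn uniformly with replacement.
#'
#' @param records curated data.frame with an `activity_class` column.
#' @param seed integer seed; the result is deterministic for a fixed seed.
#' @return data.frame with equal class counts.
#' @export
balance_by_oversampling <- function(records, seed = 42) {
  if (is.null(records) || nrow(records) == 0L)
    stop("empty dataset", call. = FALSE)
  counts <- table(droplevels(records$activity_class))
  target <- max(counts)
  extra <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(records$activity_class == cl)
      need <- target - length(idx)
      if (need > 0) idx[sample.int(length(idx), need, replace = TRUE)]
      else integer(0)
    }))
  })
  out <- rbind(records, records[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Split records into training and test sets
#'
#' The test set holds `ceiling(test_fraction * N)` records. With
#' `stratify = TRUE` the split preserves class proportions (per-class counts
#' are rounded so totals match exactly, largest fractional remainders first).
#'
#' @param records data.frame with an `activity_class` column.
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @param stratify stratify by `activity_class`?
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(records, test_fraction = 0.2, seed = 42,
                             stratify = TRUE) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  n <- nrow(records)
  if (n < 2L) stop("need at least two records to split", call. = FALSE)
  n_test <- ceiling(test_fraction * n)

  test_idx <- with_seed(seed, {
    if (!stratify) {
      sample(n, n_test)
    } else {
      cls <- droplevels(factor(records$activity_class))
      per <- test_fraction * table(cls)
      take <- floor(per)
      rem <- n_test - sum(take)
      if (rem > 0) {
        order_frac <- order(per - take, decreasing = TRUE)
        take[order_frac[seq_len(rem)]] <- take[order_frac[seq_len(rem)]] + 1L
      }
      unlist(lapply(levels(cls), function(cl) {
        idx <- which(cls == cl)
        k <- min(take[[cl]], length(idx))
        idx[sample.int(length(idx), k)]
      }))
    }
  })
  test_idx <- sort(test_idx)
  list(train = records[-test_idx, , drop = FALSE],
       test = records[test_idx, , drop = FALSE])
}

#' Write a curated dataset to CSV
#'
#' @param records curated data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  utils::write.csv(
    records[, c("compound_id", "smiles", "pic50", "activity_class",
                "category")],
    path, row.names = FALSE)
  invisible(path)
}
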