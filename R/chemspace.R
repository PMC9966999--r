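# Chemical-space projection: correlation-matrix PCA of the descriptor table
# and a PCA-score bounding-box applicability domain.

#' Fit a PCA model on a descriptor matrix
#'
#' Descriptors are z-score standardized (the six drug-likeness descriptors
#' have incommensurate units) and eigen-decomposed; components are ordered
#' by explained variance. Constant columns are dropped with a warning. The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive, making the output deterministic up to that convention.
#'
#' @param x numeric matrix or data.frame, one row per compound.
#' @param n_components number of components to retain (default: all).
#' @return an object of class `pca_model` with elements `means`, `scales`,
#'   `loadings` (columns = components), `explained_variance_ratio`
#'   (all components of the fit), `cumulative_variance` (percent) and
#'   `columns` (descriptors used).
#' @export
fit_pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least two rows", call. = FALSE)
  if (anyNA(x)) stop("missing values in descriptor matrix", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant descriptor column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  d <- ncol(x)
  if (is.null(n_components)) n_components <- d
  stopifnot(n_components >= 1L, n_components <= d)

  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    means = pc$center, scales = pc$scale,
    loadings = rotation[, seq_len(n_components), drop = FALSE],
    explained_variance_ratio = evr,
    cumulative_variance = cumsum(evr) * 100,
    columns = colnames(x)), class = "pca_model")
}

#' Project descriptor rows onto a fitted PCA model
#'
#' @param model a [fit_pca()] model.
#' @param x descriptor rows with the columns the model was fitted on.
#' @return numeric score matrix (rows x components).
#' @export
project_pca <- function(model, x) {
  x <- as.matrix(as.data.frame(x)[, model$columns, drop = FALSE])
  if (!identical(colnames(x), model$columns))
    stop("descriptor set does not match the fitted model", call. = FALSE)
  scale(x, center = model$means, scale = model$scales) %*% model$loadings
}

#' Loadings and cumulative-variance report
#'
#' @param model a [fit_pca()] model.
#' @return data.frame of loadings with a final `cumulative_variance_pct`
#'   row, mirroring a principal-component composition table.
#' @export
pca_report <- function(model) {
  k <- ncol(model$loadings)
  out <- as.data.frame(rbind(model$loadings,
                             cumulative_variance_pct =
                               model$cumulative_variance[seq_len(k)]))
  names(out) <- paste0("PC", seq_len(k))
  out
}

#' Bounding-box applicability domain from training scores
#'
#' Per-component [min, max] intervals of the training-set PCA scores,
#' optionally expanded on each side by `margin` times the component range.
#'
#' @param training_scores score matrix from [project_pca()].
#' @param n_components number of leading components the box uses; default
#'   `NULL` means all columns of `training_scores`.
#' @param margin fractional expansion (default 0).
#' @return object of class `bounding_box`: list with `lower`, `upper`,
#'   `margin`.
#' @export
bounding_box <- function(training_scores, n_components = NULL, margin = 0) {
  s <- as.matrix(training_scores)
  if (nrow(s) < 1L) stop("need at least one training score row",
                         call. = FALSE)
  if (!is.null(n_components)) s <- s[, seq_len(n_components), drop = FALSE]
  lo <- apply(s, 2, min)
  hi <- apply(s, 2, max)
  pad <- margin * (hi - lo)
  structure(list(lower = lo - pad, upper = hi + pad, margin = margin),
            class = "bounding_box")
}

# Number of leading components whose cumulative variance reaches `coverage`.
components_for_coverage <- function(model, coverage = 0.9) {
  which(model$cumulative_variance >= coverage * 100)[1]
}

#' Check scores against a bounding-box applicability domain
#'
#' A row is in-domain iff every component used by the box lies inside its
#' closed interval.
#'
#' @param box a [bounding_box()].
#' @param scores score matrix with at least as many columns as the box.
#' @return list with `in_domain` (logical per row) and `coverage` (fraction
#'   in-domain; `NA` for an empty score set).
#' @export
check_in_domain <- function(box, scores) {
  s <- as.matrix(scores)
  k <- length(box$lower)
  if (ncol(s) < k) stop("score matrix has fewer components than the box",
                        call. = FALSE)
  s <- s[, seq_len(k), drop = FALSE]
  if (nrow(s) == 0L) return(list(in_domain = logical(0), coverage = NA_real_))
  ok <- apply(s, 1, function(r) all(r >= box$lower - 1e-12 &
                                    r <= box$upper + 1e-12))
  list(in_domain = as.logical(ok), coverage = mean(ok))
}
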