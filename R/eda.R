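# Exploratory statistics for drug-likeness descriptors: per-group moment
# summaries and a two-group Mann-Whitney comparison with an exact small-n
# mode.

#' Summarize a descriptor within a group
#'
#' Reports n, min, max, median, mean, bias-corrected sample skewness, excess
#' kurtosis and a Shapiro-Wilk normality p-value. Skewness and kurtosis are
#' `NA` (undefined) for degenerate samples (n < 3 or zero variance) rather
#' than 0. Set `excess_kurtosis = FALSE` to report raw (Pearson) kurtosis.
#'
#' @param values numeric vector, n >= 1.
#' @param group label recorded in the output.
#' @param excess_kurtosis report kurtosis as excess (normal = 0)?
#' @return one-row data.frame.
#' @export
summarize_descriptor <- function(values, group = "all",
                                 excess_kurtosis = TRUE) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("need at least one value", call. = FALSE)
  degenerate <- n < 3L || stats::var(values) == 0
  skew <- if (degenerate) NA_real_ else e1071::skewness(values, type = 2)
  kurt <- if (degenerate || n < 4L) NA_real_ else {
    k <- e1071::kurtosis(values, type = 2)
    if (excess_kurtosis) k else k + 3
  }
  norm_p <- if (!degenerate && n >= 3L && n <= 5000L)
    stats::shapiro.test(values)$p.value else NA_real_
  data.frame(group = group, n = n, min = min(values), max = max(values),
             median = stats::median(values), mean = mean(values),
             skewness = skew, kurtosis = kurt, normality_p = norm_p,
             stringsAsFactors = FALSE)
}

# Mann-Whitney U statistic for group a against group b (ties count 1/2).
mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-group Mann-Whitney comparison
#'
#' Two-sided Mann-Whitney U test. When both groups have at most
#' `exact_limit` observations the p-value is computed by exact enumeration
#' of all group assignments of the pooled sample (ties handled by the 1/2
#' convention); otherwise a normal approximation with tie correction and
#' continuity correction is used. The p-value is symmetric in the group
#' order.
#'
#' @param a,b numeric vectors, each n >= 1.
#' @param exact_limit largest per-group size for the exact mode.
#' @return list with `u_statistic` (for group `a`), `p_value` and `method`
#'   (`"exact"` or `"normal_approximation"`).
#' @export
compare_groups <- function(a, b, exact_limit = 8L) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  u_obs <- mw_u_statistic(a, b)
  mu <- n1 * n2 / 2

  if (n1 <= exact_limit && n2 <= exact_limit) {
    pooled <- c(a, b)
    idx <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(u_obs - mu)
    devs <- apply(idx, 2, function(take)
      abs(mw_u_statistic(pooled[take], pooled[-take]) - mu))
    p <- mean(devs >= dev_obs - 1e-9)
    return(list(u_statistic = u_obs, p_value = p, method = "exact"))
  }

  nn <- n1 + n2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(list(u_statistic = u_obs, p_value = 1,
                               method = "normal_approximation"))
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
  list(u_statistic = u_obs, p_value = p, method = "normal_approximation")
}

#' Descriptor summary table across groups
#'
#' Builds a long-format table of per-group descriptor summaries plus the
#' two-group Mann-Whitney p-value for each descriptor, for curated records
#' restricted to `pic50 >= activity_min`. This is the machinery behind
#' group-comparison tables of drug-likeness properties.
#'
#' @param records curated data.frame (see [load_dataset()]).
#' @param descriptors data.frame of descriptors aligned with `records`
#'   (e.g. from [compute_druglikeness()]).
#' @param group_by column of `records` defining the two groups.
#' @param activity_min minimum pIC50 for inclusion; `-Inf` keeps all.
#' @return data.frame with one row per descriptor x group, plus a
#'   `p_value` column (repeated within descriptor) comparing the two groups.
#' @export
eda_report <- function(records, descriptors, group_by = "category",
                       activity_min = 7.0) {
  stopifnot(nrow(records) == nrow(descriptors))
  keep <- records$pic50 >= activity_min
  records <- records[keep, , drop = FALSE]
  descriptors <- descriptors[keep, , drop = FALSE]
  groups <- droplevels(factor(records[[group_by]]))
  if (nlevels(groups) != 2L)
    stop("eda_report compares exactly two groups; found ",
         nlevels(groups), call. = FALSE)
  out <- do.call(rbind, lapply(names(descriptors), function(d) {
    vals <- split(descriptors[[d]], groups)
    cmp <- compare_groups(vals[[1]], vals[[2]])
    res <- do.call(rbind, lapply(names(vals), function(g)
      summarize_descriptor(vals[[g]], group = g)))
    res$descriptor <- d
    res$p_value <- cmp$p_value
    res$p_method <- cmp$method
    res
  }))
  out[, c("descriptor", setdiff(names(out), "descriptor"))]
}
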