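# Valid-value accounting, the protein-selection cutoff, Winsorisation
# filtering, and profile-wise standardisation.

#' Count valid (observed) values per protein or per profile
#'
#' @param mat An [abundance_matrix()] or a numeric matrix with `NA` for
#'   missing entries.
#' @param axis `"protein"` (rows) or `"profile"` (columns).
#' @return Named integer vector of observed-value counts.
#' @export
count_valid <- function(mat, axis = c("protein", "profile")) {
  axis <- match.arg(axis)
  m <- if (inherits(mat, "abundance_matrix")) mat$mask else !is.na(mat)
  if (axis == "protein") rowSums(m) else colSums(m)
}

#' Select proteins by the steepest-slope valid-value cutoff
#'
#' Proteins are sorted by descending number of valid values. The cutoff is
#' placed after the last protein whose valid count `v` still exceeds its
#' missing count (`v > n_profiles - v`, i.e. `v > n_profiles / 2`): beyond
#' that point each additional protein adds more missing than valid cells.
#' Ties at the boundary count are all included. The `"geometric"` variant
#' instead cuts at the steepest drop of the sorted-count curve.
#'
#' @param counts Per-protein valid counts (named by accession if available).
#' @param n_profiles Total number of profiles.
#' @param method `"marginal"` (default) or `"geometric"`.
#' @return A list of class `cutoff_result`: `order` (accessions or indices
#'   sorted by descending count), `chosen_index`, `selected`,
#'   `captured_valid_fraction`, `included_missing_fraction`.
#' @export
select_by_steepest_slope <- function(counts, n_profiles,
                                     method = c("marginal", "geometric")) {
  method <- match.arg(method)
  if (!length(counts)) stop("empty counts")
  if (any(counts < 0 | counts > n_profiles))
    stop("counts must lie in [0, n_profiles]")
  ids <- if (!is.null(names(counts))) names(counts)
         else as.character(seq_along(counts))
  ord <- order(counts, decreasing = TRUE)
  cs <- counts[ord]
  if (method == "marginal") {
    k <- sum(cs > n_profiles / 2)
  } else {
    drops <- -diff(cs)
    k <- if (!length(drops) || all(drops == 0)) length(cs)
         else which.max(drops)
  }
  if (k == 0) warning("no protein exceeds half-valid; empty selection")
  sel <- if (k > 0) ids[ord][seq_len(k)] else character()
  missing <- n_profiles - counts
  structure(list(
    order = ids[ord],
    chosen_index = k,
    selected = sel,
    captured_valid_fraction =
      if (sum(counts) > 0) sum(cs[seq_len(k)]) / sum(counts) else 0,
    included_missing_fraction =
      if (sum(missing) > 0) sum((n_profiles - cs)[seq_len(k)]) /
        sum(missing) else 0),
    class = "cutoff_result")
}

#' Winsorisation filter on protein mean abundance
#'
#' Retains proteins whose mean observed abundance lies within the
#' \[`lower`, `upper`\] percentile band of all protein means (inclusive);
#' extreme-mean proteins are excluded before PCA.
#'
#' @param mat An [abundance_matrix()] or numeric matrix (`NA` = missing).
#' @param lower,upper Percentile bounds (defaults 0.05 and 0.95).
#' @return Character vector of retained protein identifiers (or indices if
#'   unnamed).
#' @export
winsorise_filter <- function(mat, lower = 0.05, upper = 0.95) {
  v <- if (inherits(mat, "abundance_matrix")) mat$values else mat
  ids <- if (!is.null(rownames(v))) rownames(v) else as.character(seq_len(nrow(v)))
  means <- rowMeans(v, na.rm = TRUE)
  if (nrow(v) < 20) {
    warning("fewer than 20 proteins; percentile filter skipped")
    return(ids)
  }
  q <- stats::quantile(means, c(lower, upper), na.rm = TRUE)
  ids[means >= q[1] & means <= q[2]]
}

#' Standardise each profile to zero mean and unit SD
#'
#' Population (1/n) standard deviation is used, so a column `c(1, 2, 3)`
#' maps to `c(-1.2247, 0, 1.2247)`.
#'
#' @param values Complete numeric matrix (proteins x profiles).
#' @return Matrix with each column centred and scaled.
#' @export
standardise_profiles <- function(values) {
  if (anyNA(values)) stop("standardisation requires a complete matrix")
  n <- nrow(values)
  ctr <- colMeans(values)
  sds <- sqrt(colMeans(values^2) - ctr^2)
  if (any(sds == 0))
    stop("zero-variance profile(s): ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  out <- sweep(sweep(values, 2, ctr), 2, sds, `/`)
  dimnames(out) <- dimnames(values)
  out
}
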