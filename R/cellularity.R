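# Relative cellularity inferred from histone and housekeeping-protein
# abundance. Histone content tracks cell numbers in bulk tissue, so the
# per-profile mean of detected histone subunits serves as a cellularity
# index, cross-checked against GAPDH/ACTA2 co-expression.

#' Histone marker presets
#'
#' `"all10"`: the ten histone subunits detected in the spatial proteome
#' (H1 and H2 families); `"core4"`: the four subunits detected in over 60
#' profiles, for users who prefer widely detected markers only.
#'
#' @param preset `"all10"` or `"core4"`.
#' @return Character vector of gene symbols.
#' @export
histone_markers <- function(preset = c("all10", "core4")) {
  preset <- match.arg(preset)
  if (preset == "all10") HISTONE_MARKERS
  else c("HIST1H1C", "HIST1H2BL", "HIST1H4A", "HIST2H2AC")
}

#' Per-profile marker index
#'
#' Mean of the observed log2 values of the marker proteins in each profile;
#' profiles where no marker is detected get `NA`. The index is invariant to
#' marker ordering and to markers absent from every profile.
#'
#' @param mat An [abundance_matrix()].
#' @param markers Gene symbols (default the 10-histone preset).
#' @return Named numeric vector (one value per profile).
#' @export
marker_index <- function(mat, markers = histone_markers()) {
  rows <- which(mat$proteins$gene_symbol %in% markers)
  if (!length(rows)) stop("no marker present in matrix")
  v <- mat$values[rows, , drop = FALSE]
  idx <- colMeans(v, na.rm = TRUE)
  idx[colSums(!is.na(v)) == 0] <- NA
  stats::setNames(idx, mat$profiles$profile_id)
}

#' Co-expression of two marker sets
#'
#' Pearson correlation between the two marker indices over profiles where
#' both are defined.
#'
#' @param mat An [abundance_matrix()].
#' @param setA,setB Gene-symbol sets.
#' @return List: `r`, `p`, `n`.
#' @export
marker_coexpression <- function(mat, setA, setB) {
  a <- marker_index(mat, setA)
  b <- marker_index(mat, setB)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 co-detected profiles")
  ct <- stats::cor.test(a[ok], b[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Compare a marker index between groups
#'
#' Two-sided Wilcoxon rank-sum tests on the index for every pair of groups.
#' The exact distribution is used for groups of up to 10 profiles (no ties
#' permitting), the normal approximation with tie correction otherwise.
#'
#' @param index Named per-profile index (from [marker_index()]).
#' @param meta Profile metadata.
#' @param grouping `"age"` or `"compartment"`.
#' @return Data frame: groupA, groupB, nA, nB, W, p.
#' @export
group_compare <- function(index, meta, grouping = c("age", "compartment")) {
  grouping <- match.arg(grouping)
  col <- if (grouping == "age") "age_group" else "compartment"
  g <- meta[[col]][match(names(index), meta$profile_id)]
  ok <- !is.na(index)
  g <- g[ok]; x <- index[ok]
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 groups")
  rows <- list()
  for (pair in utils::combn(lev, 2, simplify = FALSE)) {
    xa <- x[g == pair[1]]; xb <- x[g == pair[2]]
    if (length(xa) < 2 || length(xb) < 2) stop("need >= 2 profiles per group")
    exact <- max(length(xa), length(xb)) <= 10
    wt <- suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                         correct = !exact))
    rows[[length(rows) + 1L]] <- data.frame(
      groupA = pair[1], groupB = pair[2],
      nA = length(xa), nB = length(xb),
      W = unname(wt$statistic), p = wt$p.value,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
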