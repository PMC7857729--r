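# Spatial protein modules: hierarchical clustering of variable-set proteins
# with (1 - correlation) distance, per-module z-score pooling along an
# anatomical axis, Gaussian-process trend fits, and young-vs-aged trend
# contrasts.

#' Cluster proteins into co-expression modules
#'
#' Agglomerative clustering with (1 - Pearson correlation) distance on
#' pairwise-complete observations. Average linkage by default (`"complete"`
#' available). Proteins with fewer than 3 pairwise-complete observations
#' against the rest are dropped with a warning; correlations that remain
#' undefined (no overlap) are treated as 0.
#'
#' @param values Proteins x profiles matrix (`NA` = missing), usually the
#'   variable set.
#' @param n_modules Number of modules to cut (default 4, the young-scheme
#'   module count; 6 fits the cross-age heatmap).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return List of class `module_set`: `tree` (hclust), `modules` (named
#'   integer vector per protein), `n_modules`, `dropped`.
#' @export
cluster_modules <- function(values, n_modules = 4L,
                            linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(values) < 2) stop("need at least 2 proteins to cluster")
  obs <- !is.na(values)
  # pairwise-complete count against the best partner; require >= 3
  co <- obs %*% t(obs)
  diag(co) <- 0
  dropped <- rownames(values)[apply(co, 1, max) < 3]
  if (length(dropped)) {
    warning(length(dropped),
            " protein(s) dropped: <3 pairwise-complete observations")
    values <- values[!(rownames(values) %in% dropped), , drop = FALSE]
  }
  if (nrow(values) < 2) stop("too few proteins left after dropping")
  cm <- suppressWarnings(stats::cor(t(values),
                                    use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  tree <- stats::hclust(d, method = linkage)
  k <- min(n_modules, nrow(values))
  modules <- stats::cutree(tree, k = k)
  structure(list(tree = tree, modules = modules, n_modules = k,
                 dropped = dropped),
            class = "module_set")
}

#' Pool module z-scores along an anatomical axis
#'
#' Each protein is z-scored across the scoped profiles (observed values
#' only; constant proteins are excluded), then all (position, z) points of
#' the module's proteins are pooled over disc levels. Lateral positions 1-7
#' and anteroposterior positions 1-5 are mapped to the unit axis (outer
#' annulus at 0 and 1, NP at 0.5).
#'
#' @param mat An [abundance_matrix()].
#' @param module_proteins Accessions of the module members.
#' @param axis `"lateral"` or `"anteroposterior"`.
#' @param age Optional age group to scope to (`NULL` = all profiles).
#' @param level Optional disc level to scope to (`NULL` = levels pooled).
#' @return Data frame: `position` (unit axis), `z`, `protein`, `level`,
#'   `profile_id`.
#' @export
module_zscores <- function(mat, module_proteins,
                           axis = c("lateral", "anteroposterior"),
                           age = NULL, level = NULL) {
  axis <- match.arg(axis)
  meta <- mat$profiles
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(age)) keep <- keep & meta$age_group == age
  if (!is.null(level)) keep <- keep & meta$level == level
  on_axis <- if (axis == "lateral") !is.na(meta$lateral_pos)
             else !is.na(meta$ap_pos)
  keep <- keep & on_axis
  if (!any(keep)) stop("no profiles on the requested axis/scope")
  pos <- if (axis == "lateral") (meta$lateral_pos[keep] - 1) / 6
         else (meta$ap_pos[keep] - 1) / 4
  rows <- match(module_proteins, mat$proteins$accession)
  rows <- rows[!is.na(rows)]
  out <- list()
  for (i in rows) {
    y <- mat$values[i, keep]
    ok <- !is.na(y)
    if (sum(ok) < 2) next
    mu <- mean(y[ok])
    sd_pop <- sqrt(mean((y[ok] - mu)^2))       # population SD, as for
    if (sd_pop == 0) next                      # profile standardisation
    z <- (y[ok] - mu) / sd_pop
    out[[length(out) + 1L]] <- data.frame(
      position = pos[ok], z = z,
      protein = mat$proteins$accession[i],
      level = meta$level[keep][ok],
      profile_id = meta$profile_id[keep][ok],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no usable proteins in module")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a Gaussian-process trend to pooled module z-scores
#'
#' Squared-exponential kernel with nugget, hyperparameters by marginal-
#' likelihood maximisation; the trend is the posterior mean with a +-1
#' posterior-SD band over a dense grid. The shape class compares the
#' interior extremum of the posterior mean against both end values: concave
#' if an interior maximum exceeds both ends by at least `margin`, convex if
#' an interior minimum undercuts both ends by `margin`, flat otherwise.
#'
#' @param points Data frame with columns `position` and `z` (from
#'   [module_zscores()]), or numeric vectors via `position`/`z`.
#' @param margin Shape-classification margin in z units (default 0.2).
#' @param nugget Fixed noise variance, or `NULL` to estimate.
#' @param axis Optional axis label carried through.
#' @return List of class `trend_fit`: `grid`, `mean`, `sd`, `band` (lower/
#'   upper), `shape_class`, `gp`, `axis`.
#' @export
fit_gpe_trend <- function(points, margin = 0.2, nugget = NULL, axis = NA) {
  x <- points$position; y <- points$z
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct positions for a trend fit")
  gp <- fit_gp(x, y, nugget = nugget)
  shape <- classify_shape(gp$mean, margin)
  structure(list(grid = gp$grid, mean = gp$mean, sd = gp$sd,
                 band = list(lower = gp$mean - gp$sd,
                             upper = gp$mean + gp$sd),
                 shape_class = shape, gp = gp, axis = axis),
            class = "trend_fit")
}

classify_shape <- function(mean_curve, margin) {
  n <- length(mean_curve)
  ends <- mean_curve[c(1, n)]
  interior <- mean_curve[2:(n - 1)]
  if (max(interior) >= max(ends) + margin) "concave"
  else if (min(interior) <= min(ends) - margin) "convex"
  else "flat"
}

#' Contrast a young and an aged trend fit
#'
#' Amplitude is the largest deviation of the posterior mean from the edge
#' mean (average of the two end values). Reports the aged/young amplitude
#' ratio and any shape transition.
#'
#' @param young,aged `trend_fit` objects for the same module and axis.
#' @return List: `amplitude_young`, `amplitude_aged`, `amplitude_ratio`,
#'   `shape_young`, `shape_aged`, `transition`.
#' @export
compare_trends <- function(young, aged) {
  amp <- function(tf) {
    edge <- mean(tf$mean[c(1, length(tf$mean))])
    max(abs(tf$mean - edge))
  }
  ay <- amp(young); aa <- amp(aged)
  list(amplitude_young = ay, amplitude_aged = aa,
       amplitude_ratio = if (ay > 0) aa / ay else NA_real_,
       shape_young = young$shape_class, shape_aged = aged$shape_class,
       transition = if (identical(young$shape_class, aged$shape_class))
         "none" else paste(young$shape_class, "->", aged$shape_class))
}
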