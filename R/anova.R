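# Per-protein one-way ANOVA against phenotypic factors, aggregated by
# matrisome category. Observed values only: no imputation enters the
# variance partition.

FACTOR_COLUMNS <- c(age = "age_group", compartment = "compartment",
                    level = "level", direction = "direction")

#' Factor-wise ANOVA of protein abundance
#'
#' For each protein and each phenotypic factor, a one-way ANOVA on the
#' observed log2 values yields an F statistic, p-value and variance fraction
#' (between-group sum of squares over total, i.e. eta squared). Proteins are
#' analysed only where observed in at least half of the scoped profiles.
#' Category summaries average the variance fractions of member proteins; the
#' dominant factor per category is the one with the highest mean fraction.
#'
#' @param mat An [abundance_matrix()].
#' @param factors Subset of `c("age", "compartment", "level", "direction")`.
#' @param scope `"combined"`, `"young"` or `"aged"`.
#' @return List of class `anova_table`: `per_protein` (protein, factor, F,
#'   p, variance_fraction, n_used), `category_summary` (category, factor,
#'   mean_variance_fraction), `dominant` (named vector, factor per
#'   category).
#' @export
anova_by_factors <- function(mat,
                             factors = c("age", "compartment", "level",
                                         "direction"),
                             scope = c("combined", "young", "aged")) {
  scope <- match.arg(scope)
  factors <- match.arg(factors, several.ok = TRUE)
  keep <- if (scope == "combined") rep(TRUE, nrow(mat$profiles))
          else mat$profiles$age_group == scope
  meta <- mat$profiles[keep, ]
  v <- mat$values[, keep, drop = FALSE]
  n_prof <- ncol(v)
  usable <- character()
  for (f in factors) {
    lv <- unique(meta[[FACTOR_COLUMNS[f]]])
    if (length(lv) < 2) {
      warning("factor '", f, "' is constant within scope; dropped")
    } else usable <- c(usable, f)
  }
  if (!length(usable)) stop("no usable factors in scope")
  detected <- rowSums(!is.na(v)) >= n_prof / 2
  rows <- list()
  for (f in usable) {
    g <- factor(meta[[FACTOR_COLUMNS[f]]])
    for (i in which(detected)) {
      y <- v[i, ]
      ok <- !is.na(y)
      st <- oneway_stats(y[ok], droplevels(g[ok]))
      if (is.null(st)) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein = mat$proteins$accession[i], factor = f,
        F = st["F"], p = st["p"], variance_fraction = st["eta2"],
        n_used = sum(ok), stringsAsFactors = FALSE)
    }
  }
  per_protein <- do.call(rbind, rows)
  rownames(per_protein) <- NULL
  cls <- stats::setNames(mat$proteins$matrisome_class,
                         mat$proteins$accession)
  per_protein$category <- unname(cls[per_protein$protein])
  agg <- stats::aggregate(variance_fraction ~ category + factor,
                          per_protein, mean)
  names(agg)[3] <- "mean_variance_fraction"
  dominant <- vapply(split(agg, agg$category), function(d)
    d$factor[which.max(d$mean_variance_fraction)], "")
  structure(list(per_protein = per_protein, category_summary = agg,
                 dominant = dominant, scope = scope),
            class = "anova_table")
}

# Closed-form one-way ANOVA: F, p, and eta squared.
oneway_stats <- function(y, g) {
  k <- nlevels(g)
  n <- length(y)
  if (k < 2 || n <= k) return(NULL)
  m <- mean(y)
  mg <- tapply(y, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (mg - m)^2)
  sst <- sum((y - m)^2)
  if (sst == 0) return(NULL)
  ssw <- sst - ssb
  Fst <- (ssb / (k - 1)) / (ssw / (n - k))
  c(F = Fst, p = stats::pf(Fst, k - 1, n - k, lower.tail = FALSE),
    eta2 = ssb / sst)
}
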