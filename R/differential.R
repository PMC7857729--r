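# The dropout-aware three-strategy differential-expression caller and the
# pairwise comparison scheme. Detection counts route each protein to exactly
# one tier:
#   (i)  detections > half in BOTH groups       -> two-sample t-test,
#        Benjamini-Hochberg FDR across tier-(i) proteins of the comparison;
#   (ii) detections > half in one group, zero in the other -> exclusive;
#   (iii) detections <= half in both (>= 1 each) -> fold-change threshold;
#   anything else -> no call.
# "Over half" is strict (> n/2), so e.g. 4 of 6 or 2 of 3.

#' Define a two-group comparison
#'
#' @param name Comparison label.
#' @param groupA,groupB Disjoint, non-empty profile-id sets.
#' @return A list of class `comparison`.
#' @export
make_comparison <- function(name, groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    stop("comparison groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("comparison groups overlap: ",
         paste(intersect(groupA, groupB), collapse = ", "))
  structure(list(name = name, groupA = groupA, groupB = groupB),
            class = "comparison")
}

#' Call differentially expressed proteins for one comparison
#'
#' @param mat An [abundance_matrix()].
#' @param comparison A [make_comparison()] object.
#' @param fdr_threshold FDR cutoff for the statistical tier (default 0.05).
#' @param fc_threshold Fold-change cutoff for the low-detection tier
#'   (default 2, i.e. 1 log2 unit).
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return Data frame with one row per protein: `protein`, `comparison`,
#'   `tier` (routing), `strategy` (called strategy or `"none"`),
#'   `direction`, `statistic`, `p`, `fdr`, `log2fc`, `detectA`, `detectB`,
#'   `called`.
#' @export
call_deps <- function(mat, comparison, fdr_threshold = 0.05,
                      fc_threshold = 2, var_equal = TRUE) {
  stopifnot(inherits(comparison, "comparison"))
  ia <- match(comparison$groupA, mat$profiles$profile_id)
  ib <- match(comparison$groupB, mat$profiles$profile_id)
  if (anyNA(ia) || anyNA(ib))
    stop("comparison profiles missing from matrix: ",
         paste(c(comparison$groupA[is.na(ia)],
                 comparison$groupB[is.na(ib)]), collapse = ", "))
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 profiles")
  A <- mat$values[, ia, drop = FALSE]
  B <- mat$values[, ib, drop = FALSE]
  nA <- length(ia); nB <- length(ib)
  dA <- rowSums(!is.na(A)); dB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)

  tier <- rep("unroutable", nrow(A))
  tier[dA > nA / 2 & dB > nB / 2] <- "statistical"
  tier[(dA > nA / 2 & dB == 0) | (dB > nB / 2 & dA == 0)] <- "exclusive"
  tier[dA <= nA / 2 & dB <= nB / 2 & dA >= 1 & dB >= 1] <- "fold_change"

  stat <- p <- fdr <- rep(NA_real_, nrow(A))
  t_idx <- which(tier == "statistical")
  for (i in t_idx) {
    tt <- stats::t.test(A[i, ], B[i, ], var.equal = var_equal)
    stat[i] <- unname(tt$statistic); p[i] <- tt$p.value
  }
  fdr[t_idx] <- stats::p.adjust(p[t_idx], method = "BH")

  log2fc <- mA - mB
  log2fc[tier == "exclusive" & dA == 0] <- -Inf
  log2fc[tier == "exclusive" & dB == 0] <- Inf

  called <- (tier == "statistical" & !is.na(fdr) & fdr < fdr_threshold) |
    (tier == "exclusive") |
    (tier == "fold_change" & abs(log2fc) >= log2(fc_threshold))
  strategy <- ifelse(called, tier, "none")
  direction <- ifelse(log2fc >= 0, "A_higher", "B_higher")
  out <- data.frame(
    protein = mat$proteins$accession, comparison = comparison$name,
    tier = tier, strategy = strategy, direction = direction,
    statistic = stat, p = p, fdr = fdr, log2fc = log2fc,
    detectA = dA, detectB = dB, called = called,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run a list of comparisons
#'
#' @param mat An [abundance_matrix()].
#' @param scheme List of [make_comparison()] objects.
#' @param ... Passed to [call_deps()].
#' @return Named list of per-comparison call tables.
#' @export
run_comparison_scheme <- function(mat, scheme, ...) {
  out <- lapply(scheme, function(cmp) call_deps(mat, cmp, ...))
  names(out) <- vapply(scheme, `[[`, "", "name")
  out
}

#' Built-in pairwise comparison scheme
#'
#' Reconstruction of the study contrasts: within each age, the six
#' compartment pairs, OAF versus the pooled inner disc (NP, NP/IAF, IAF),
#' and the three level pairs (10 per age); plus three cross-age contrasts
#' (all young vs all aged, inner vs inner, OAF vs OAF) - 23 comparisons in
#' all. The enumeration is a best-effort reconstruction of the published
#' panel layout.
#'
#' @param meta Profile metadata.
#' @param ages Which age groups get within-age blocks.
#' @return List of [make_comparison()] objects.
#' @export
default_comparison_scheme <- function(meta, ages = c("young", "aged")) {
  ids <- function(cond) meta$profile_id[cond]
  inner <- c("NP", "NP/IAF", "IAF")
  scheme <- list()
  for (a in intersect(ages, unique(meta$age_group))) {
    in_age <- meta$age_group == a
    cps <- utils::combn(COMPARTMENTS, 2, simplify = FALSE)
    for (cp in cps)
      scheme[[length(scheme) + 1L]] <- make_comparison(
        sprintf("%s:%s_vs_%s", a, cp[1], cp[2]),
        ids(in_age & meta$compartment == cp[1]),
        ids(in_age & meta$compartment == cp[2]))
    scheme[[length(scheme) + 1L]] <- make_comparison(
      sprintf("%s:OAF_vs_inner", a),
      ids(in_age & meta$compartment == "OAF"),
      ids(in_age & meta$compartment %in% inner))
    lps <- utils::combn(DISC_LEVELS, 2, simplify = FALSE)
    for (lp in lps)
      scheme[[length(scheme) + 1L]] <- make_comparison(
        sprintf("%s:%s_vs_%s", a, gsub("/", "", lp[1]), gsub("/", "", lp[2])),
        ids(in_age & meta$level == lp[1]),
        ids(in_age & meta$level == lp[2]))
  }
  if (all(c("young", "aged") %in% meta$age_group)) {
    young <- meta$age_group == "young"; aged <- meta$age_group == "aged"
    scheme[[length(scheme) + 1L]] <- make_comparison(
      "cross:young_vs_aged", ids(young), ids(aged))
    scheme[[length(scheme) + 1L]] <- make_comparison(
      "cross:inner_young_vs_aged",
      ids(young & meta$compartment %in% inner),
      ids(aged & meta$compartment %in% inner))
    scheme[[length(scheme) + 1L]] <- make_comparison(
      "cross:OAF_young_vs_aged",
      ids(young & meta$compartment == "OAF"),
      ids(aged & meta$compartment == "OAF"))
  }
  scheme
}

#' Partition proteins into variable, constant and marginal sets
#'
#' The variable set is the union of DEPs over all comparisons; the constant
#' set is the non-DEPs detected in strictly more than
#' `min_detection_fraction` of the scoped profiles (the baseline proteome);
#' the remaining non-DEPs are marginal.
#'
#' @param mat An [abundance_matrix()] restricted to the scoped profiles.
#' @param calls List of call tables from [run_comparison_scheme()].
#' @param min_detection_fraction Detection cutoff (default 0.5).
#' @return List with character vectors `variable`, `constant`, `marginal`.
#' @export
partition_variable_constant <- function(mat, calls,
                                        min_detection_fraction = 0.5) {
  deps <- unique(unlist(lapply(calls, function(d) d$protein[d$called])))
  det <- count_valid(mat, "protein")
  n <- ncol(mat$values)
  non <- setdiff(mat$proteins$accession, deps)
  constant <- non[det[non] > min_detection_fraction * n]
  list(variable = deps, constant = constant,
       marginal = setdiff(non, constant))
}

#' Threshold-based differential expression for transcriptome data
#'
#' A gene is a DEG when the absolute log2 fold change exceeds `fc_log2` and
#' the pooled mean expression (log scale) exceeds `min_mean`.
#'
#' @param expr Complete gene x sample log2 expression matrix.
#' @param groupA,groupB Column ids or indices.
#' @param fc_log2 Fold-change threshold in log2 units (default 3).
#' @param min_mean Mean-expression floor (default 10).
#' @return Data frame: gene, meanA, meanB, log2fc, pooled_mean, deg.
#' @export
call_degs <- function(expr, groupA, groupB, fc_log2 = 3, min_mean = 10) {
  if (anyNA(expr)) stop("transcriptome matrix must be complete")
  A <- expr[, groupA, drop = FALSE]; B <- expr[, groupB, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  pooled <- rowMeans(cbind(A, B))
  lfc <- mA - mB
  data.frame(gene = rownames(expr), meanA = mA, meanB = mB, log2fc = lfc,
             pooled_mean = pooled,
             deg = abs(lfc) > fc_log2 & pooled > min_mean,
             row.names = NULL, stringsAsFactors = FALSE)
}
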