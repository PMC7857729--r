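# Chained-equations imputation with predictive mean matching (PMM).
# Proteins are the variables, profiles the cases: each protein with missing
# cells is regressed on its most-correlated peers (using current filled-in
# values) and each missing cell receives the observed value of a donor drawn
# from the k cases nearest in predicted value. Sweeps repeat until the
# largest cell change falls below `tol` or `max_iter` is reached.

#' Impute missing abundances by chained equations with PMM
#'
#' @param mat An [abundance_matrix()] or numeric matrix with `NA` for
#'   missing cells. Every protein and every profile must have at least two
#'   observed values.
#' @param max_iter Maximum number of sweeps (default 50).
#' @param n_imputations Number of completed matrices; when > 1 they are
#'   combined by cell-wise mean (the completed matrix fed to PCA).
#' @param k_donors Donor-pool size for PMM (default 5); donor ties are
#'   broken by lowest case index for determinism.
#' @param n_predictors Number of peer proteins used as regressors.
#' @param tol Convergence tolerance on the maximum absolute cell change
#'   (log2 units); 1e-3 is well below quantification noise.
#' @param seed Integer seed.
#' @return A list of class `imputed_matrix`: `values` (complete matrix),
#'   `provenance` (TRUE = observed, FALSE = imputed), `n_iterations`
#'   (per imputation), `seed`.
#' @export
impute_chained <- function(mat, max_iter = 50L, n_imputations = 5L,
                           k_donors = 5L, n_predictors = 10L,
                           tol = 1e-3, seed = 1L) {
  v <- if (inherits(mat, "abundance_matrix")) mat$values else as.matrix(mat)
  obs <- !is.na(v)
  if (any(rowSums(obs) < 2))
    stop("protein(s) with fewer than 2 observed values must be excluded ",
         "upstream: ", paste(utils::head(rownames(v)[rowSums(obs) < 2], 5),
                             collapse = ", "))
  if (any(colSums(obs) < 2))
    stop("profile(s) with fewer than 2 observed values")
  if (all(obs)) {
    return(structure(list(values = v, provenance = obs,
                          n_iterations = 0L, seed = seed),
                     class = "imputed_matrix"))
  }
  imps <- vector("list", n_imputations)
  iters <- integer(n_imputations)
  for (imp in seq_len(n_imputations)) {
    set.seed(seed + imp - 1L)
    res <- impute_once(v, obs, max_iter, k_donors, n_predictors, tol)
    imps[[imp]] <- res$values
    iters[imp] <- res$iter
  }
  out <- Reduce(`+`, imps) / n_imputations
  out[obs] <- v[obs]               # observed cells are never touched
  structure(list(values = out, provenance = obs, n_iterations = iters,
                 seed = seed),
            class = "imputed_matrix")
}

impute_once <- function(v, obs, max_iter, k_donors, n_predictors, tol) {
  filled <- v
  row_means <- rowMeans(v, na.rm = TRUE)
  for (i in seq_len(nrow(v)))
    filled[i, !obs[i, ]] <- row_means[i]   # mean start
  targets <- which(rowSums(!obs) > 0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    max_change <- 0
    # correlations on the current completed matrix, once per sweep
    cm <- suppressWarnings(stats::cor(t(filled)))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    for (i in targets) {
      miss <- which(!obs[i, ])
      cases <- which(obs[i, ])
      npred <- min(n_predictors, nrow(v) - 1L, max(1L, length(cases) - 2L))
      pred_rows <- order(abs(cm[i, ]), decreasing = TRUE)[seq_len(npred)]
      X <- cbind(1, t(filled[pred_rows, , drop = FALSE]))
      fit <- stats::lm.fit(X[cases, , drop = FALSE], v[i, cases])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      yhat <- drop(X %*% beta)
      for (j in miss) {
        d <- abs(yhat[cases] - yhat[j])
        pool <- cases[order(d, cases)][seq_len(min(k_donors, length(cases)))]
        donor <- pool[sample.int(length(pool), 1L)]
        new_val <- v[i, donor]
        max_change <- max(max_change, abs(new_val - filled[i, j]))
        filled[i, j] <- new_val
      }
    }
    if (max_change < tol || iter >= max_iter) break
  }
  list(values = filled, iter = iter)
}
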