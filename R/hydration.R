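# The hydration matrisome: proteome-wide association of matrisome proteins
# with region MRI intensity, and a LASSO model predicting intensity from
# the candidate ECM proteins across cohorts.

#' Associate matrisome proteins with region MRI intensity
#'
#' Pearson correlation, per matrisome protein, between observed abundances
#' and the MRI intensity of the matched region (profiles are matched to
#' regions by level and anatomical location). Proteins with unadjusted
#' p < `alpha` form the candidate set ("hydration matrisome"), split into
#' positively and negatively correlated halves. A BH-FDR option is
#' available; the unadjusted default reflects that no adjustment procedure
#' is attached to the published candidate count.
#'
#' @param mat An [abundance_matrix()] restricted to the profiles with MRI.
#' @param intensities Data frame `level`, `location`, `intensity`; locations
#'   follow [disc_locations()] codes.
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param min_pairs Minimum co-observed profiles per protein (default 3).
#' @return Data frame: `accession`, `gene_symbol`, `matrisome_class`, `r`,
#'   `p`, `n`, `sign`, `candidate`.
#' @export
hydration_association <- function(mat, intensities, alpha = 0.05,
                                  adjust = c("none", "BH"), min_pairs = 3L) {
  adjust <- match.arg(adjust)
  iv <- profile_region_intensity(mat$profiles, intensities)
  ecm <- which(mat$proteins$matrisome_class != "non_matrisome")
  rows <- list()
  for (i in ecm) {
    y <- mat$values[i, ]
    ok <- !is.na(y) & !is.na(iv)
    if (sum(ok) < min_pairs || stats::sd(y[ok]) == 0 ||
        stats::sd(iv[ok]) == 0) next
    ct <- stats::cor.test(y[ok], iv[ok])
    rows[[length(rows) + 1L]] <- data.frame(
      accession = mat$proteins$accession[i],
      gene_symbol = mat$proteins$gene_symbol[i],
      matrisome_class = mat$proteins$matrisome_class[i],
      r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no matrisome protein with enough observations")
  res <- do.call(rbind, rows)
  padj <- if (adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$sign <- ifelse(res$r >= 0, "positive", "negative")
  res$candidate <- padj < alpha
  rownames(res) <- NULL
  res
}

# Intensity of the region each profile was cut from; the NP centre cell is
# shared between the lateral and anteroposterior axes.
profile_region_intensity <- function(meta, intensities) {
  locs <- disc_locations()
  loc_of <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    match_row <- which(
      (is.na(locs$lateral_pos) | locs$lateral_pos %in% meta$lateral_pos[i]) &
      (is.na(locs$ap_pos) | locs$ap_pos %in% meta$ap_pos[i]) &
      locs$compartment == meta$compartment[i] &
      locs$direction == meta$direction[i])
    loc_of[i] <- locs$location[match_row[1]]
  }
  idx <- match(paste(meta$level, loc_of),
               paste(intensities$level, intensities$location))
  intensities$intensity[idx]
}

#' Fit the LASSO hydration model
#'
#' L1-penalised linear regression of region MRI intensity on the candidate
#' ECM proteins. Candidates missing in more than `missing_ceiling` of the
#' profiles are excluded; the rest are completed by chained-equations
#' imputation, standardised, and fed to cross-validated LASSO. The penalty
#' is chosen by the minimum-CV-error rule (`"1se"` optional); coefficients
#' are reported on the original abundance scale.
#'
#' @param mat An [abundance_matrix()] of the training cohort.
#' @param intensities Region intensity data frame (`level`, `location`,
#'   `intensity`).
#' @param candidates Accessions of the hydration-matrisome candidates.
#' @param cv_folds Cross-validation folds (default 10; reduced with a
#'   warning when profiles are scarce).
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param missing_ceiling Maximum tolerated missing fraction per candidate
#'   (default 0.5).
#' @param seed Integer seed (fold assignment and imputation).
#' @return List of class `hydration_model`: `coefficients` (original
#'   scale), `intercept`, `lambda`, `cv_folds`, `predictors`, `selected`
#'   (nonzero predictors), `excluded` (too-missing candidates),
#'   `training_means`, `training_sds`, `glmnet_fit`.
#' @export
fit_hydration_lasso <- function(mat, intensities, candidates,
                                cv_folds = 10L,
                                lambda_rule = c("min", "1se"),
                                missing_ceiling = 0.5, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  y <- profile_region_intensity(mat$profiles, intensities)
  if (anyNA(y)) stop("every profile must map to a region intensity")
  rows <- match(candidates, mat$proteins$accession)
  if (anyNA(rows)) stop("unknown candidate accession(s)")
  v <- mat$values[rows, , drop = FALSE]
  miss_frac <- rowMeans(is.na(v))
  excluded <- candidates[miss_frac > missing_ceiling]
  keep <- miss_frac <= missing_ceiling
  if (sum(keep) < 2) stop("fewer than 2 usable candidate predictors")
  v <- v[keep, , drop = FALSE]
  preds <- candidates[keep]
  if (anyNA(v))
    v <- impute_chained(v, seed = seed)$values
  n <- ncol(v)
  folds <- cv_folds
  if (n < cv_folds) {
    folds <- max(3L, n %/% 2L)
    warning("fewer profiles than folds; using ", folds, " folds")
  }
  mu <- rowMeans(v); sds <- apply(v, 1, stats::sd)
  sds[sds == 0] <- 1
  x <- t((v - mu) / sds)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, nfolds = folds,
                          standardize = FALSE)
  lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  co <- as.matrix(stats::coef(cv, s = lambda))
  beta_std <- co[-1, 1]
  beta_orig <- beta_std / sds
  intercept <- co[1, 1] - sum(beta_orig * mu)
  structure(list(
    coefficients = stats::setNames(beta_orig, preds),
    coefficients_std = stats::setNames(beta_std, preds),
    intercept = intercept, lambda = lambda, cv_folds = folds,
    predictors = preds, selected = preds[beta_std != 0],
    excluded = excluded,
    training_means = stats::setNames(mu, preds),
    training_sds = stats::setNames(sds, preds),
    glmnet_fit = cv),
    class = "hydration_model")
}

#' Predict region MRI intensity for a new cohort
#'
#' Linear prediction from the fitted hydration model; missing predictor
#' values in the new cohort are filled with the training means. When
#' observed intensities are supplied the prediction is evaluated by Pearson
#' and Spearman correlation and by the ROC AUC separating IAF from OAF
#' profiles on predicted intensity.
#'
#' @param model A `hydration_model`.
#' @param mat An [abundance_matrix()] of the new cohort.
#' @param intensities Optional observed intensities for evaluation.
#' @return List: `predicted` (per profile), and when evaluable `pearson`,
#'   `pearson_p`, `spearman`, `auc_iaf_oaf`.
#' @export
predict_hydration <- function(model, mat, intensities = NULL) {
  rows <- match(model$predictors, mat$proteins$accession)
  if (anyNA(rows))
    stop("new cohort lacks model predictors: ",
         paste(model$predictors[is.na(rows)], collapse = ", "))
  v <- mat$values[rows, , drop = FALSE]
  for (i in seq_len(nrow(v)))
    v[i, is.na(v[i, ])] <- model$training_means[i]
  pred <- drop(crossprod(v, model$coefficients)) + model$intercept
  names(pred) <- mat$profiles$profile_id
  out <- list(predicted = pred)
  cmp <- mat$profiles$compartment
  if (all(c("IAF", "OAF") %in% cmp)) {
    sel <- cmp %in% c("IAF", "OAF")
    if (stats::sd(pred[sel]) > 0) {
      # AUC = P(predicted IAF intensity > predicted OAF intensity):
      # the inner annulus is the brighter (more hydrated) compartment
      roc <- pROC::roc(response = cmp[sel], predictor = pred[sel],
                       levels = c("OAF", "IAF"), direction = "<",
                       quiet = TRUE)
      out$auc_iaf_oaf <- as.numeric(pROC::auc(roc))
    } else {
      out$auc_iaf_oaf <- 0.5     # constant predictor carries no ranking
    }
  }
  if (!is.null(intensities)) {
    obs <- profile_region_intensity(mat$profiles, intensities)
    ok <- !is.na(obs)
    ct <- stats::cor.test(pred[ok], obs[ok])
    out$pearson <- unname(ct$estimate)
    out$pearson_p <- ct$p.value
    out$spearman <- stats::cor(pred[ok], obs[ok], method = "spearman")
    out$observed <- obs
  }
  out
}
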