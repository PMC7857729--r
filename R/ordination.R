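# PCA over profiles, protein-PC association, and polynomial-kernel SVM
# decision boundaries with probability contours.

#' Principal component analysis of profiles
#'
#' Profiles are the observations, proteins the variables. Computed by
#' singular-value decomposition of the (profile-standardised, complete)
#' matrix after per-protein centring; loadings carry no extra scaling. Each
#' component's loading vector is sign-flipped so its largest-magnitude
#' loading is positive, making scores reproducible rather than sign-
#' ambiguous.
#'
#' @param values Complete numeric matrix (proteins x profiles), typically
#'   from [standardise_profiles()].
#' @return List of class `pca_result`: `scores` (profile x component),
#'   `loadings` (protein x component), `variance_fraction`, `center`.
#' @export
run_pca <- function(values) {
  if (anyNA(values)) stop("PCA requires a complete matrix")
  x <- t(values)                       # profiles as rows
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = vf, center = pc$center),
            class = "pca_result")
}

#' Reconstruct the input matrix from a PCA result
#'
#' @param pca A `pca_result`.
#' @param n_components Number of components to use (default all).
#' @return Proteins x profiles matrix on the scale of the PCA input.
#' @export
pca_reconstruct <- function(pca, n_components = ncol(pca$scores)) {
  k <- seq_len(n_components)
  x <- pca$scores[, k, drop = FALSE] %*% t(pca$loadings[, k, drop = FALSE])
  t(sweep(x, 2, pca$center, `+`))
}

#' Rank proteins by correlation with a principal component
#'
#' Pearson correlation of each protein's (imputed) abundance across profiles
#' with the PC score; the `top_n` most positively and most negatively
#' correlated proteins are returned with their matrisome classes. Constant
#' proteins have undefined correlation and are excluded with a warning; ties
#' are broken by gene symbol.
#'
#' @param values Complete proteins x profiles matrix.
#' @param pca A `pca_result` (or a score matrix).
#' @param pc Component index.
#' @param top_n List length per direction (default 100).
#' @param proteins Optional protein table (`accession`, `gene_symbol`,
#'   `matrisome_class`) aligned with rows of `values`.
#' @return List with data frames `positive` and `negative` (accession,
#'   gene_symbol, matrisome_class, cor).
#' @export
correlate_with_pc <- function(values, pca, pc = 1L, top_n = 100L,
                              proteins = NULL) {
  scores <- if (inherits(pca, "pca_result")) pca$scores else pca
  if (pc > ncol(scores)) stop("pc exceeds computed components")
  s <- scores[, pc]
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant protein(s) excluded from correlation")
  }
  keep <- which(sds > 0)
  r <- as.vector(stats::cor(t(values[keep, , drop = FALSE]), s))
  if (is.null(proteins)) {
    ids <- rownames(values)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
    proteins <- data.frame(accession = ids, gene_symbol = ids,
                           matrisome_class = "non_matrisome",
                           stringsAsFactors = FALSE)
  }
  tab <- data.frame(proteins[keep, c("accession", "gene_symbol",
                                     "matrisome_class")],
                    cor = r, stringsAsFactors = FALSE)
  pos <- tab[order(-tab$cor, tab$gene_symbol), ]
  neg <- tab[order(tab$cor, tab$gene_symbol), ]
  list(positive = utils::head(pos, top_n),
       negative = utils::head(neg, top_n))
}

#' Fit a polynomial-kernel SVM decision boundary in a 2-D ordination
#'
#' Degree-2 polynomial-kernel maximum-margin classifier with sigmoid
#' probability calibration, evaluated on a mesh spanning the data range plus
#' a 10% margin. Contour polylines are extracted at calibrated class
#' probabilities 0.25, 0.5 and 0.75 (the central hard boundary and two
#' "soft" probability-offset boundaries at +-0.5).
#'
#' @param scores Two-column matrix of coordinates.
#' @param labels Binary labels (factor or coercible).
#' @param cost Soft-margin regularisation constant (default 1).
#' @param mesh_n Mesh resolution per axis (default 200).
#' @param mesh_margin Fractional margin added around the data (default 0.1).
#' @param seed Seed for the internal calibration cross-validation.
#' @return List of class `boundary_model`: `model`, `labels`, `positive`
#'   (class whose probability is contoured), `mesh` (`x`, `y`, `prob`),
#'   `contours` (data frame: level, piece, x, y), `training_accuracy`.
#' @export
fit_boundary <- function(scores, labels, cost = 1, mesh_n = 200L,
                         mesh_margin = 0.1, seed = 1L) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly two columns")
  y <- factor(labels)
  if (nlevels(y) != 2) stop("exactly two classes required")
  if (any(table(y) < 3)) stop("need at least 3 points per class")
  set.seed(seed)
  fit <- e1071::svm(x = scores, y = y, kernel = "polynomial", degree = 2,
                    coef0 = 1, cost = cost, probability = TRUE, scale = TRUE)
  pos <- levels(y)[2]
  rng <- apply(scores, 2, range)
  pad <- mesh_margin * (rng[2, ] - rng[1, ])
  gx <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = mesh_n)
  gy <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = mesh_n)
  mesh <- as.matrix(expand.grid(x = gx, y = gy))
  colnames(mesh) <- colnames(scores)
  pr <- attr(stats::predict(fit, mesh, probability = TRUE), "probabilities")
  pmat <- matrix(pr[, pos], mesh_n, mesh_n)
  cl <- grDevices::contourLines(gx, gy, pmat, levels = c(0.25, 0.5, 0.75))
  contours <- if (length(cl)) do.call(rbind, lapply(seq_along(cl), function(i)
    data.frame(level = cl[[i]]$level, piece = i,
               x = cl[[i]]$x, y = cl[[i]]$y))) else
    data.frame(level = numeric(), piece = integer(),
               x = numeric(), y = numeric())
  acc <- mean(stats::predict(fit, scores) == y)
  structure(list(model = fit, labels = y, positive = pos,
                 mesh = list(x = gx, y = gy, prob = pmat),
                 contours = contours, training_accuracy = acc),
            class = "boundary_model")
}

#' Predict class labels from a fitted boundary model
#' @param object A `boundary_model`.
#' @param newdata Two-column coordinate matrix.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.boundary_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- colnames(object$model$SV)
  stats::predict(object$model, newdata)
}
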