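# Gaussian-process regression in one dimension: squared-exponential kernel
# plus an observation-noise (nugget) term, hyperparameters by marginal-
# likelihood maximisation. Replicated inputs are handled exactly through
# sufficient statistics: for m unique positions with counts n_i, means
# ybar_i and within-position sum of squares SSW, the marginal likelihood
# factorises into a GP term on the means (noise variance sn2/n_i) and a
# pure-noise term for the within-position scatter. This keeps the fit
# O(m^3) regardless of how many points are pooled per position.

se_kernel <- function(u1, u2, s2, ell) {
  s2 * exp(-0.5 * outer(u1, u2, `-`)^2 / ell^2)
}

gp_suffstats <- function(x, y) {
  u <- sort(unique(x))
  idx <- match(x, u)
  n_i <- tabulate(idx, length(u))
  ybar <- vapply(split(y, idx), mean, 0)
  ssw <- sum((y - ybar[idx])^2)
  list(u = u, n = n_i, ybar = ybar, ssw = ssw, N = length(y))
}

gp_nll <- function(log_par, ss, fixed_nugget = NULL) {
  s2 <- exp(log_par[1]); ell <- exp(log_par[2])
  sn2 <- if (is.null(fixed_nugget)) exp(log_par[3]) else fixed_nugget
  m <- length(ss$u)
  K <- se_kernel(ss$u, ss$u, s2, ell) + diag(sn2 / ss$n + 1e-12 * s2, m)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  yc <- ss$ybar - mean(ss$ybar)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  nll <- 0.5 * sum(yc * alpha) + sum(log(diag(ch))) +
    0.5 * (ss$N - m) * log(sn2) + ss$ssw / (2 * sn2)
  if (!is.finite(nll)) 1e10 else nll
}

#' Fit a one-dimensional Gaussian-process regression
#'
#' @param x Numeric positions (replicates allowed).
#' @param y Responses.
#' @param nugget Observation-noise variance; `NULL` (default) estimates it
#'   by marginal likelihood, a number fixes it.
#' @param lengthscale `NULL` to estimate; a number fixes the kernel
#'   length-scale.
#' @param grid Prediction grid; default 101 points over the data range.
#' @return List of class `gp_fit`: `grid`, `mean` (posterior mean of the
#'   latent function), `sd` (posterior SD), hyperparameters `s2`, `ell`,
#'   `sn2`, and the constant prior mean `mu`.
#' @export
fit_gp <- function(x, y, nugget = NULL, lengthscale = NULL, grid = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ss <- gp_suffstats(x, y)
  span <- diff(range(ss$u))
  if (span == 0) stop("all positions identical")
  vy <- max(stats::var(y), 1e-6)
  init <- c(log(vy), log(span / 3),
            log(max(if (ss$N > length(ss$u)) ss$ssw / (ss$N - length(ss$u))
                    else vy / 10, 1e-6)))
  free <- c(TRUE, is.null(lengthscale), is.null(nugget))
  obj <- function(p) {
    full <- init
    full[free] <- p
    if (!is.null(lengthscale)) full[2] <- log(lengthscale)
    gp_nll(full, ss, fixed_nugget = nugget)
  }
  # the length-scale is bounded below by the spacing of the position grid:
  # anything shorter just interpolates replicate noise at the observed
  # positions (pooled points share per-profile offsets, so the per-position
  # means are far less certain than the raw point count suggests)
  ell_min <- if (length(ss$u) > 1) min(diff(ss$u)) else span / 10
  lower <- c(log(1e-8), log(ell_min), log(1e-8))
  upper <- c(log(1e6), log(span * 10), log(1e6))
  init[2] <- max(init[2], log(ell_min))
  par0 <- init[free]
  opt <- tryCatch(
    stats::optim(par0, obj, method = "L-BFGS-B",
                 lower = lower[free], upper = upper[free]),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    warning("hyperparameter optimisation failed; ",
            "falling back to length-scale = span/3")
    lengthscale <- span / 3
    full <- init
    s2 <- vy
    sn2 <- if (is.null(nugget)) max(vy / 10, 1e-6) else nugget
  } else {
    full <- init
    full[free] <- opt$par
    s2 <- exp(full[1])
    if (is.null(lengthscale)) lengthscale <- exp(full[2])
    sn2 <- if (is.null(nugget)) exp(full[3]) else nugget
  }
  if (is.null(grid)) grid <- seq(min(ss$u), max(ss$u), length.out = 101L)
  m <- length(ss$u)
  K <- se_kernel(ss$u, ss$u, s2, lengthscale) +
    diag(sn2 / ss$n + 1e-12 * s2, m)
  ch <- chol(K)
  mu <- mean(ss$ybar)
  yc <- ss$ybar - mu
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  Ks <- se_kernel(grid, ss$u, s2, lengthscale)
  post_mean <- mu + drop(Ks %*% alpha)
  V <- forwardsolve(t(ch), t(Ks))
  post_var <- pmax(s2 - colSums(V^2), 0)
  structure(list(grid = grid, mean = post_mean, sd = sqrt(post_var),
                 s2 = s2, ell = lengthscale, sn2 = sn2, mu = mu,
                 x = x, y = y),
            class = "gp_fit")
}

#' Posterior mean of a GP fit at new positions
#' @param object A `gp_fit`.
#' @param newdata Numeric positions.
#' @param ... Unused.
#' @export
predict.gp_fit <- function(object, newdata, ...) {
  ss <- gp_suffstats(object$x, object$y)
  m <- length(ss$u)
  K <- se_kernel(ss$u, ss$u, object$s2, object$ell) +
    diag(object$sn2 / ss$n + 1e-12 * object$s2, m)
  alpha <- solve(K, ss$ybar - object$mu)
  object$mu + drop(se_kernel(newdata, ss$u, object$s2, object$ell) %*% alpha)
}
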