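test_that("region intensity averages pixels then stacks, and is linear", {
  img <- function(val) matrix(val, 10, 14)
  grid <- data.frame(level = "L3/4", location = "NP",
                     row0 = 2, row1 = 5, col0 = 3, col1 = 8)
  expect_equal(region_intensity(list("L3/4" = list(img(100))), grid)$intensity,
               100)
  stacks <- list("L3/4" = list(img(100), img(120), img(140)))
  reg <- region_intensity(stacks, grid)
  expect_equal(reg$intensity, 120)
  expect_equal(c(reg$stack1, reg$stack2, reg$stack3), c(100, 120, 140))
  # linearity: scaling all pixels scales every region intensity
  scaled <- lapply(stacks, function(s) lapply(s, function(m) 0.5 * m))
  expect_equal(region_intensity(scaled, grid)$intensity, 0.5 * 120)
  bad <- transform(grid, row1 = 99)
  expect_error(region_intensity(stacks, bad), "exceeds image bounds")
})

test_that("PNG stacks round-trip through disk within quantisation error", {
  ints <- data.frame(level = "L4/5", location = disc_locations()$location,
                     intensity = seq(50, 200, length.out = 11))
  toy <- generate_toy_images(ints, stacks = 2, pixel_noise_sd = 0, seed = 1)
  dir <- withr::local_tempdir()
  write_toy_images(toy, dir)
  back <- read_image_stacks(dir)
  reg <- region_intensity(back$images, back$grid)
  expect_equal(reg$intensity,
               ints$intensity[match(reg$location, ints$location)],
               tolerance = 0.5)   # 8-bit quantisation
})

test_that("biclustering merges identical levels first and separates blocks", {
  locs <- disc_locations()$location
  inner <- locs %in% c("NP", "NPIAF_L", "NPIAF_R", "NPIAF_A", "NPIAF_P",
                       "IAF_L", "IAF_R")
  base <- ifelse(inner, 200, 60)
  reg <- data.frame(level = rep(c("L3/4", "L4/5", "L5/S1"), each = 11),
                    location = rep(locs, 3),
                    intensity = c(base, base, base + 20))
  bic <- bicluster_intensity(reg)
  # the two identical levels join at height zero
  expect_equal(bic$row_tree$height[1], 0)
  first_pair <- rownames(bic$matrix)[abs(bic$row_tree$merge[1, ])]
  expect_setequal(first_pair, c("L3/4", "L4/5"))
  # the first column split separates inner from outer locations
  cl <- stats::cutree(bic$col_tree, 2)
  expect_length(unique(cl[colnames(bic$matrix) %in% locs[inner]]), 1)
  expect_length(unique(cl[colnames(bic$matrix) %in% locs[!inner]]), 1)
  expect_false(cl[["NP"]] == cl[["OAF_L"]])
  # single level: column clustering only, with a warning
  expect_warning(b1 <- bicluster_intensity(reg[reg$level == "L3/4", ]),
                 "single level")
  expect_null(b1$row_tree)
})

test_that("hydration association flags perfect predictors and ignores non-matrisome", {
  set.seed(1)
  meta66 <- discproteome:::full_design_meta()
  aged <- meta66[meta66$age_group == "aged", ]
  ints <- data.frame(level = aged$level, location = aged$location,
                     intensity = runif(33, 50, 200))
  v <- rbind(ints$intensity,                        # perfect ECM predictor
             rnorm(33, 27, 1),                      # noise ECM
             ints$intensity)                        # perfect but non-matrisome
  prot <- data.frame(accession = c("E1", "E2", "N1"),
                     gene_symbol = c("E1", "E2", "N1"),
                     matrisome_class = c("proteoglycan", "collagen",
                                         "non_matrisome"))
  mat <- abundance_matrix(v, prot, aged[, setdiff(names(aged), "location")])
  res <- hydration_association(mat, ints)
  expect_true(res$candidate[res$accession == "E1"])
  expect_equal(res$r[res$accession == "E1"], 1, tolerance = 1e-10)
  expect_equal(res$sign[res$accession == "E1"], "positive")
  expect_false("N1" %in% res$accession)   # scope rule: matrisome only
})

test_that("null matrisome proteins become candidates at roughly the alpha rate", {
  set.seed(2)
  meta66 <- discproteome:::full_design_meta()
  aged <- meta66[meta66$age_group == "aged", ]
  ints <- data.frame(level = aged$level, location = aged$location,
                     intensity = runif(33, 50, 200))
  n <- 400
  v <- matrix(rnorm(n * 33, 27, 1), n, 33)
  prot <- data.frame(accession = sprintf("E%03d", 1:n),
                     gene_symbol = sprintf("E%03d", 1:n),
                     matrisome_class = "glycoprotein")
  mat <- abundance_matrix(v, prot, aged[, setdiff(names(aged), "location")])
  rate <- mean(hydration_association(mat, ints)$candidate)
  mc_se <- sqrt(0.05 * 0.95 / n)
  expect_lt(rate, 0.05 + 3 * mc_se)
})

test_that("LASSO selects a perfect predictor, shrinks all at high lambda, path is monotone", {
  set.seed(3)
  bench <- simulate_hydration_benchmark(n_predictors = 20, n_nonzero = 1,
                                        snr = 50, seed = 5)
  fx <- hydration_fixture(bench$x, bench$y)
  fit <- fit_hydration_lasso(fx$mat, fx$intensities, colnames(bench$x),
                             seed = 5)
  expect_true(colnames(bench$x)[1] %in% fit$selected)
  expect_lte(length(fit$selected), 8)
  # penalty limit: all coefficients zero, intercept = mean intensity
  path <- fit$glmnet_fit$glmnet.fit
  co_inf <- as.matrix(stats::coef(path, s = max(fit$glmnet_fit$lambda) * 10))
  expect_true(all(abs(co_inf[-1, ]) < 1e-10))
  expect_equal(co_inf[1, 1], mean(bench$y), tolerance = 1e-6)
  # support size never grows as lambda increases
  nz <- colSums(as.matrix(path$beta) != 0)
  expect_true(all(diff(nz[order(path$lambda)]) <= 0))
})

test_that("too-missing candidates are excluded before imputation", {
  set.seed(4)
  bench <- simulate_hydration_benchmark(n_predictors = 10, n_nonzero = 1,
                                        snr = 50, seed = 6)
  x <- bench$x
  x[1:25, 10] <- NA                     # 76% missing
  x[1:3, 9] <- NA                       # 9% missing: imputed, kept
  fx <- hydration_fixture(x, bench$y)
  fit <- fit_hydration_lasso(fx$mat, fx$intensities, colnames(x), seed = 6)
  expect_equal(fit$excluded, colnames(x)[10])
  expect_true(colnames(x)[9] %in% fit$predictors)
})

test_that("cross-cohort prediction evaluates correlation and IAF/OAF separation", {
  bench <- simulate_hydration_benchmark(snr = 100, seed = 7)
  tr <- hydration_fixture(bench$x, bench$y, "aged")
  te <- hydration_fixture(bench$x_new, bench$y_new, "young")
  fit <- fit_hydration_lasso(tr$mat, tr$intensities, colnames(bench$x),
                             seed = 7)
  pr <- predict_hydration(fit, te$mat, te$intensities)
  expect_gte(pr$pearson, 0.9)
  expect_true(is.finite(pr$spearman))
  # constant predictors: flat prediction, chance-level AUC
  cx <- bench$x_new; cx[] <- 1
  const <- hydration_fixture(cx, bench$y_new, "young")
  fit0 <- fit
  fit0$coefficients[] <- 0
  pr0 <- predict_hydration(fit0, const$mat)
  expect_equal(unname(pr0$auc_iaf_oaf), 0.5)
  expect_length(unique(pr0$predicted), 1)
})
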