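test_that("anti-correlated blocks split into exactly two modules", {
  set.seed(1)
  base <- rnorm(20)
  v <- rbind(matrix(rep(base, 5), 5, 20, byrow = TRUE),
             matrix(rep(-base, 5), 5, 20, byrow = TRUE)) +
    matrix(rnorm(200, 0, 0.01), 10, 20)
  rownames(v) <- sprintf("P%02d", 1:10)
  ms <- cluster_modules(v, 2)
  expect_equal(ms$n_modules, 2)
  expect_length(unique(ms$modules[1:5]), 1)
  expect_length(unique(ms$modules[6:10]), 1)
  expect_false(ms$modules[1] == ms$modules[6])
})

test_that("a duplicated protein collapses into one module and sparse rows drop", {
  set.seed(2)
  v <- matrix(rep(rnorm(12), 10), 10, 12, byrow = TRUE) +
    matrix(rnorm(120, 0, 0.05), 10, 12)
  rownames(v) <- sprintf("D%02d", 1:10)
  ms <- cluster_modules(v, 1)
  expect_length(unique(ms$modules), 1)
  v[1, ] <- NA; v[1, 1:2] <- c(27, 28)    # only 2 pairwise-complete obs
  expect_warning(ms2 <- cluster_modules(v, 2), "dropped")
  expect_false("D01" %in% names(ms2$modules))
})

test_that("module z-scores match the closed form and pool across proteins", {
  meta <- discproteome:::full_design_meta()
  young <- meta[meta$age_group == "young" & meta$level == "L3/4" &
                  !is.na(meta$lateral_pos), ]
  young <- young[order(young$lateral_pos), ]
  v <- matrix(NA_real_, 2, nrow(young))
  v[1, 1:3] <- c(10, 12, 14)
  v[2, ] <- 30                              # constant: excluded
  prot <- fixture_proteins(2)
  mat <- abundance_matrix(v, prot, young[, setdiff(names(young), "location")])
  pts <- module_zscores(mat, c("P001", "P002"), "lateral")
  expect_equal(sort(pts$z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_setequal(pts$protein, "P001")
  # pooling two informative proteins doubles the points
  v2 <- rbind(v[1, ], v[1, ] + rnorm(nrow(young), 0, 0.1))
  mat2 <- abundance_matrix(v2, prot, young[, setdiff(names(young), "location")])
  pts2 <- module_zscores(mat2, c("P001", "P002"), "lateral")
  expect_equal(nrow(pts2), 2 * sum(!is.na(v2[1, ])))
})

test_that("GP trend interpolates noiseless shapes and needs 4 positions", {
  x <- seq(0, 1, length.out = 7)
  conc <- data.frame(position = x, z = 4 * (1 - 4 * (x - 0.5)^2))
  tr <- fit_gpe_trend(conc, nugget = 1e-8)
  expect_equal(tr$shape_class, "concave")
  expect_lt(max(abs(predict(tr$gp, x) - conc$z)), 1e-3)
  conv <- data.frame(position = x, z = 4 * 4 * (x - 0.5)^2)
  expect_equal(fit_gpe_trend(conv, nugget = 1e-8)$shape_class, "convex")
  expect_error(fit_gpe_trend(data.frame(position = c(0, 1), z = c(0, 1))),
               "4 distinct positions")
  # the band encloses the posterior mean
  expect_true(all(tr$band$lower <= tr$mean & tr$mean <= tr$band$upper))
})

test_that("pure noise is classified flat in at least 90% of replicates", {
  set.seed(3)
  x <- rep(seq(0, 1, length.out = 7), each = 10)
  flat_rate <- mean(replicate(100, {
    fit_gpe_trend(data.frame(position = x, z = rnorm(70)))$shape_class ==
      "flat"
  }))
  expect_gte(flat_rate, 0.9)
})

test_that("shape classification is equivariant to affine relabelling of positions", {
  set.seed(4)
  x <- seq(0, 1, length.out = 7)
  z <- 3 * (1 - 4 * (x - 0.5)^2) + rnorm(7, 0, 0.1)
  s1 <- fit_gpe_trend(data.frame(position = x, z = z))$shape_class
  s2 <- fit_gpe_trend(data.frame(position = 10 + 5 * x, z = z))$shape_class
  expect_equal(s1, s2)
})

test_that("trend contrasts report amplitude ratios and shape transitions", {
  x <- seq(0, 1, length.out = 7)
  young <- fit_gpe_trend(data.frame(position = x,
                                    z = 4 * (1 - 4 * (x - 0.5)^2)),
                         nugget = 1e-8)
  same <- compare_trends(young, young)
  expect_equal(same$amplitude_ratio, 1)
  expect_equal(same$transition, "none")
  halved <- fit_gpe_trend(data.frame(position = x,
                                     z = 2 * (1 - 4 * (x - 0.5)^2)),
                          nugget = 1e-8)
  expect_equal(compare_trends(young, halved)$amplitude_ratio, 0.5,
               tolerance = 0.05)
  inverted <- fit_gpe_trend(data.frame(position = x,
                                       z = -4 * (1 - 4 * (x - 0.5)^2)),
                            nugget = 1e-8)
  expect_equal(compare_trends(young, inverted)$transition,
               "concave -> convex")
})

test_that("planted modules are recovered from a synthetic disc", {
  sim <- generate_disc_dataset(synthetic_config(seed = 2))
  truth <- sim$truth$module
  planted <- names(truth)[!is.na(truth)]
  young <- subset_abundance(sim$matrix,
                            profiles = sim$matrix$profiles$age_group ==
                              "young")
  v <- young$values[match(planted, young$proteins$accession), ]
  rownames(v) <- planted
  v <- v[rowSums(!is.na(v)) > ncol(v) / 2, , drop = FALSE]
  ms <- suppressWarnings(cluster_modules(v, 4))
  ari <- mclust::adjustedRandIndex(ms$modules, truth[names(ms$modules)])
  expect_gte(ari, 0.9)
  # the concave module trends concave in young; over replicate discs the
  # aged fit is flattened (ratio < 1 in median -- single fits can chase
  # module-factor wobble, so this is a distributional property)
  ratios <- vapply(1:5, function(s) {
    rs <- generate_disc_dataset(synthetic_config(seed = 30 + s))
    tm <- rs$truth$module
    m1 <- names(tm)[which(tm == "M1")]
    tr_y <- fit_gpe_trend(module_zscores(rs$matrix, m1, "lateral",
                                         age = "young"))
    tr_a <- fit_gpe_trend(module_zscores(rs$matrix, m1, "lateral",
                                         age = "aged"))
    expect_equal(tr_y$shape_class, "concave")
    compare_trends(tr_y, tr_a)$amplitude_ratio
  }, 0)
  expect_lt(median(ratios), 1)
})
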