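test_that("count_valid counts observed cells along either axis", {
  v <- matrix(rnorm(20, 27), 4, 5)
  expect_equal(unname(count_valid(fixture_matrix(v), "protein")), rep(5, 4))
  v[1, 1:3] <- NA
  m <- fixture_matrix(v)
  expect_equal(unname(count_valid(m, "protein"))[1], 2)
  expect_equal(unname(count_valid(m, "profile")), c(3, 3, 3, 4, 4))
})

test_that("steepest-slope cutoff keeps proteins adding more valid than missing cells", {
  res <- select_by_steepest_slope(c(10, 9, 8, 6, 5, 4), 10)
  expect_equal(res$chosen_index, 4)   # stops after the count-6 protein
  expect_equal(res$captured_valid_fraction, 33 / 42)
  expect_equal(res$included_missing_fraction, 7 / 18)
  # no missingness: everything selected
  all10 <- select_by_steepest_slope(rep(10, 5), 10)
  expect_equal(all10$chosen_index, 5)
  # degenerate: nothing above half
  expect_warning(none <- select_by_steepest_slope(c(3, 2, 1), 10), "empty")
  expect_equal(none$chosen_index, 0)
  expect_error(select_by_steepest_slope(numeric(), 10), "empty")
})

test_that("cutoff agrees with a brute-force oracle over random matrices", {
  # oracle: scan every cut point of the sorted counts, maximising the
  # cumulative valid-minus-missing margin
  oracle <- function(counts, n) {
    cs <- sort(counts, decreasing = TRUE)
    gain <- cumsum(2 * cs - n)
    if (all(gain <= 0)) 0 else which.max(gain)
  }
  set.seed(7)
  for (r in 1:25) {
    counts <- sample(0:66, 200, replace = TRUE)
    res <- suppressWarnings(select_by_steepest_slope(counts, 66))
    expect_equal(res$chosen_index, oracle(counts, 66))
  }
})

test_that("winsorisation keeps the central 90% band of protein means", {
  set.seed(1)
  v <- matrix(rnorm(100 * 6, 27, 0.1), 100, 6) + seq_len(100)  # distinct means
  rownames(v) <- sprintf("P%03d", 1:100)
  kept <- winsorise_filter(v)
  expect_length(kept, 90)
  # a single extreme protein is excluded
  v[1, ] <- v[1, ] + 100
  expect_false("P001" %in% winsorise_filter(v))
  # identical means: inclusive bounds keep everything
  v2 <- matrix(27, 30, 4, dimnames = list(sprintf("Q%02d", 1:30), NULL))
  expect_length(winsorise_filter(v2), 30)
  # too few proteins: warn and pass through
  expect_warning(all_kept <- winsorise_filter(v[1:5, ]), "fewer than 20")
  expect_length(all_kept, 5)
})

test_that("imputation leaves complete matrices untouched and is deterministic", {
  v <- matrix(rnorm(40, 27), 8, 5)
  res <- impute_chained(fixture_matrix(v))
  expect_equal(unname(res$values), unname(v))
  expect_equal(res$n_iterations, 0L)
  # forced donor pool: all donors share one value
  v2 <- matrix(c(rep(20, 5), rnorm(35, 27)), 8, 5, byrow = TRUE)
  v2[1, ] <- 20; v2[1, 3] <- NA
  r2 <- impute_chained(v2, seed = 4)
  expect_equal(r2$values[1, 3], 20)
  # reproducible under a fixed seed
  v3 <- matrix(rnorm(200, 27, 2), 20, 10)
  v3[sample(length(v3), 30)] <- NA
  expect_identical(impute_chained(v3, seed = 9)$values,
                   impute_chained(v3, seed = 9)$values)
  # proteins with < 2 observed values are a contract violation
  v4 <- v3; v4[1, ] <- NA; v4[1, 1] <- 27
  expect_error(impute_chained(v4), "fewer than 2")
})

test_that("imputation error on synthetic truth is close to the noise floor", {
  cfg <- synthetic_config(n_proteins = 150, seed = 21,
                          dropout_midpoint = 22)   # ~10% dropout
  sim <- generate_disc_dataset(cfg)
  mat <- sim$matrix
  keep <- count_valid(mat, "protein") >= ncol(mat$values) / 2
  sub <- subset_abundance(mat, proteins = which(keep))
  imp <- impute_chained(sub, n_imputations = 3, seed = 1)
  truth <- sim$truth$true_means[match(sub$proteins$accession,
                                      rownames(sim$truth$true_means)), ]
  miss <- !sub$mask
  mae <- mean(abs(imp$values[miss] - truth[miss]))
  # a noise-free oracle predicting the true mean still pays the observation
  # noise on average; PMM should land within 1 log2 unit of that floor
  oracle_mae <- cfg$noise_sd * sqrt(2 / pi)
  expect_lt(mae, oracle_mae + 1)
})

test_that("observed cells keep their within-profile ranks through the pipeline", {
  set.seed(2)
  v <- matrix(rnorm(300, 27, 3), 30, 10)
  v[sample(length(v), 40)] <- NA
  mat <- fixture_matrix(v, fixture_meta(10))
  cut <- select_by_steepest_slope(count_valid(mat, "protein"), 10)
  sub <- subset_abundance(mat, proteins = cut$selected)
  imp <- impute_chained(sub, seed = 1)
  for (j in seq_len(ncol(v))) {
    obs <- which(sub$mask[, j])
    expect_equal(rank(imp$values[obs, j]), rank(sub$values[obs, j]))
  }
})

test_that("profile standardisation matches the closed form", {
  expect_equal(drop(standardise_profiles(cbind(c(1, 2, 3)))),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  s <- standardise_profiles(matrix(rnorm(50, 27, 4), 10, 5))
  expect_true(all(abs(colMeans(s)) < 1e-10))
  pop_sd <- sqrt(colMeans(s^2) - colMeans(s)^2)
  expect_equal(unname(pop_sd), rep(1, 5))
  expect_error(standardise_profiles(cbind(rep(2, 4))), "zero-variance")
})
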