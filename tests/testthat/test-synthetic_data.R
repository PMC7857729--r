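test_that("same seed gives bit-identical datasets", {
  a <- generate_disc_dataset(synthetic_config(seed = 42, n_proteins = 100,
                                              module_specs = list()))
  b <- generate_disc_dataset(synthetic_config(seed = 42, n_proteins = 100,
                                              module_specs = list()))
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$mri, b$mri)
})

test_that("no noise and no dropout reproduce the true means exactly", {
  cfg <- synthetic_config(
    n_proteins = 60,
    module_specs = list(list(name = "M1", size = 10, shape = "concave",
                             amplitude = 2, age_effect = "flatten")),
    noise_sd = 0, module_cor_sd = 0,
    dropout_steepness = Inf, dropout_midpoint = 0, seed = 3)
  sim <- generate_disc_dataset(cfg)
  expect_true(all(sim$matrix$mask))
  expect_equal(sim$matrix$values, sim$truth$true_means, tolerance = 1e-12)
})

test_that("a concave module's true NP - OAF contrast equals its amplitude at every level", {
  cfg <- synthetic_config(seed = 5)
  sim <- generate_disc_dataset(cfg)
  amp <- cfg$module_specs[[1]]$amplitude
  m1 <- names(sim$truth$module)[which(sim$truth$module == "M1")]
  meta <- sim$matrix$profiles
  tm <- sim$truth$true_means
  for (lev in unique(meta$level)) {
    young <- meta$age_group == "young" & meta$level == lev
    np <- which(young & meta$compartment == "NP")
    oaf <- which(young & meta$compartment == "OAF")
    contrast <- rowMeans(tm[m1, np, drop = FALSE]) -
      rowMeans(tm[m1, oaf, drop = FALSE])
    expect_equal(unname(contrast), rep(amp, length(m1)), tolerance = 1e-12)
  }
})

test_that("dropout frequency decreases with true abundance", {
  sim <- generate_disc_dataset(synthetic_config(seed = 11))
  tm <- as.vector(sim$truth$true_means)
  miss <- as.vector(!sim$matrix$mask)
  bins <- cut(tm, stats::quantile(tm, seq(0, 1, 0.1)), include.lowest = TRUE)
  rate <- tapply(miss, bins, mean)
  # monotone non-increasing over abundance bins (rank test)
  expect_lt(stats::cor(seq_along(rate), rate, method = "spearman"), -0.9)
  expect_true(all(diff(rate) <= 0.02))
})

test_that("observed values stay within the configured log2 range", {
  cfg <- synthetic_config(seed = 2)
  sim <- generate_disc_dataset(cfg)
  obs <- sim$matrix$values[sim$matrix$mask]
  inside <- mean(obs >= cfg$log2_range[1] & obs <= cfg$log2_range[2])
  expect_gte(inside, 0.999)
})

test_that("age flattening shrinks the aged concave contrast on truth means", {
  cfg <- synthetic_config(seed = 8)
  sim <- generate_disc_dataset(cfg)
  m1 <- names(sim$truth$module)[which(sim$truth$module == "M1")]
  meta <- sim$matrix$profiles
  tm <- sim$truth$true_means
  contrast <- function(age) {
    sel <- meta$age_group == age
    mean(tm[m1, sel & meta$compartment == "NP"]) -
      mean(tm[m1, sel & meta$compartment == "OAF"])
  }
  expect_lt(abs(contrast("aged")), abs(contrast("young")))
})

test_that("toy images reproduce planted intensities", {
  ints <- data.frame(level = "L3/4",
                     location = disc_locations()$location,
                     intensity = seq(40, 240, length.out = 11))
  toy <- generate_toy_images(ints, stacks = 3, pixel_noise_sd = 0, seed = 1)
  reg <- region_intensity(toy$images, toy$grid)
  expect_equal(reg$intensity,
               ints$intensity[match(reg$location, ints$location)],
               tolerance = 1e-12)
  # saturation: planted 255 with zero noise stays exactly 255
  ints255 <- transform(ints, intensity = 255)
  toy255 <- generate_toy_images(ints255, pixel_noise_sd = 0)
  g <- toy255$grid[1, ]
  expect_true(all(toy255$images[["L3/4"]][[1]][g$row0:g$row1,
                                               g$col0:g$col1] == 255))
  # averaging stacks beats the single-stack noise (CLT bound, simulated)
  toyn <- generate_toy_images(ints, stacks = 3, pixel_noise_sd = 8, seed = 2)
  regn <- region_intensity(toyn$images, toyn$grid)
  npix <- (toyn$grid$row1 - toyn$grid$row0 + 1) *
    (toyn$grid$col1 - toyn$grid$col0 + 1)
  bound <- 5 * 8 / sqrt(3 * min(npix))
  err <- abs(regn$intensity -
               ints$intensity[match(regn$location, ints$location)])
  expect_true(all(err < bound))
  expect_error(generate_toy_images(ints, shape = c(3, 4)), "too small")
})
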