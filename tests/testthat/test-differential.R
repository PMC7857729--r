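two_group_mat <- function(valsA, valsB, nA = 6, nB = 6) {
  v <- cbind(valsA, valsB)
  meta <- fixture_meta(nA + nB,
                       compartment = rep(c("NP", "OAF"), c(nA, nB)))
  fixture_matrix(v, meta)
}
cmp_ab <- function(nA = 6, nB = 6)
  make_comparison("AvB", sprintf("S%02d", 1:nA),
                  sprintf("S%02d", nA + 1:nB))

test_that("tier routing and calls follow the three published rules", {
  set.seed(1)
  # P1: strong statistical DEP; P2: exclusive 4/6 vs 0/6; P3: low-detection
  # small difference (no call); P4: low-detection large difference (FC call)
  A <- rbind(rnorm(6, 30, 0.1), c(rnorm(4, 28, 0.5), NA, NA),
             c(27.2, 27.3, NA, NA, NA, NA), c(29, 29.4, NA, NA, NA, NA))
  B <- rbind(rnorm(6, 26, 0.1), rep(NA, 6),
             c(26.8, 26.9, NA, NA, NA, NA), c(26.5, 27, NA, NA, NA, NA))
  mat <- two_group_mat(A, B)
  d <- call_deps(mat, cmp_ab())
  expect_equal(d$tier, c("statistical", "exclusive", "fold_change",
                         "fold_change"))
  expect_equal(d$called, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(d$direction[d$called], rep("A_higher", 3))
  expect_equal(d$log2fc[2], Inf)
  # statistical tier agrees with the stock pooled t-test
  tt <- stats::t.test(A[1, ], B[1, ], var.equal = TRUE)
  expect_equal(d$p[1], tt$p.value, tolerance = 1e-12)
  expect_equal(d$detectA, c(6, 4, 2, 2))
  expect_equal(d$detectB, c(6, 0, 2, 2))
})

test_that("routing is a partition and respects the strict over-half rule", {
  set.seed(2)
  v <- matrix(rnorm(400 * 12, 27, 2), 400, 12)
  v[matrix(runif(400 * 12) < 0.35, 400, 12)] <- NA
  mat <- two_group_mat(v[, 1:6], v[, 7:12])
  d <- call_deps(mat, cmp_ab())
  expect_true(all(d$tier %in% c("statistical", "exclusive", "fold_change",
                                "unroutable")))
  # recompute routing independently from detection counts
  dA <- rowSums(!is.na(v[, 1:6])); dB <- rowSums(!is.na(v[, 7:12]))
  expected <- ifelse(dA > 3 & dB > 3, "statistical",
               ifelse((dA > 3 & dB == 0) | (dB > 3 & dA == 0), "exclusive",
                ifelse(dA <= 3 & dB <= 3 & dA >= 1 & dB >= 1,
                       "fold_change", "unroutable")))
  expect_equal(d$tier, expected)
  # BH adjustment is computed within the statistical tier only
  st <- d$tier == "statistical"
  expect_equal(d$fdr[st], p.adjust(d$p[st], "BH"))
  expect_true(all(is.na(d$fdr[!st])))
})

test_that("swapping the groups flips direction and nothing else", {
  set.seed(3)
  v <- matrix(rnorm(100 * 12, 27, 1), 100, 12)
  v[sample(length(v), 150)] <- NA
  keep <- rowSums(!is.na(v[, 1:6])) >= 2 & rowSums(!is.na(v[, 7:12])) >= 2
  v <- v[keep, ]
  mat <- two_group_mat(v[, 1:6], v[, 7:12])
  fwd <- call_deps(mat, cmp_ab())
  rev <- call_deps(mat, make_comparison("AvB", sprintf("S%02d", 7:12),
                                        sprintf("S%02d", 1:6)))
  expect_equal(fwd$called, rev$called)
  expect_equal(fwd$log2fc, -rev$log2fc)
  flips <- c(A_higher = "B_higher", B_higher = "A_higher")
  expect_equal(unname(flips[fwd$direction[fwd$called]]),
               rev$direction[rev$called])
})

test_that("group overlap and missing profiles are rejected", {
  mat <- two_group_mat(matrix(27, 3, 6), matrix(27, 3, 6))
  expect_error(make_comparison("x", "S01", c("S01", "S02")), "overlap")
  expect_error(call_deps(mat, make_comparison("x", "S01", "S99")),
               "missing from matrix")
})

test_that("the built-in scheme has 23 comparisons with the published group sizes", {
  meta <- discproteome:::full_design_meta()
  meta <- meta[, setdiff(names(meta), "location")]
  scheme <- default_comparison_scheme(meta)
  expect_length(scheme, 23)
  oaf_inner <- scheme[[which(vapply(scheme, `[[`, "", "name") ==
                               "young:OAF_vs_inner")]]
  expect_length(oaf_inner$groupA, 12)   # 4 OAF locations x 3 levels
  expect_length(oaf_inner$groupB, 21)   # 7 inner locations x 3 levels
  # empty scheme: empty result
  sim <- generate_disc_dataset(synthetic_config(n_proteins = 30, seed = 1,
                                                module_specs = list()))
  expect_length(run_comparison_scheme(sim$matrix, list()), 0)
})

test_that("variable/constant/marginal partition follows the detection cutoff", {
  set.seed(4)
  n <- 33
  meta <- fixture_meta(n, compartment = rep(c("NP", "OAF", "IAF"), 11))
  v <- matrix(rnorm(3 * n, 27, 0.5), 3, n)
  v[1, meta$compartment == "OAF"] <- v[1, meta$compartment == "OAF"] + 8
  v[2, sample(n, 16)] <- NA            # detected in 17/33 (> half)
  v[3, sample(n, 28)] <- NA            # detected in 5/33
  mat <- fixture_matrix(v, meta)
  cmp <- make_comparison("np_vs_oaf",
                         meta$profile_id[meta$compartment == "NP"],
                         meta$profile_id[meta$compartment == "OAF"])
  calls <- run_comparison_scheme(mat, list(cmp))
  parts <- partition_variable_constant(mat, calls)
  expect_true("P001" %in% parts$variable)
  expect_true("P002" %in% parts$constant)
  expect_true("P003" %in% parts$marginal)
})

test_that("the statistical tier controls its false-call rate under a global null", {
  calls <- tested <- 0
  for (r in 1:3) {
    s <- simulate_two_group(1000, 6, n_planted = 0, seed = 300 + r)
    d <- call_deps(s$matrix, make_comparison("AvB", s$groupA, s$groupB))
    calls <- calls + sum(d$strategy == "statistical")
    tested <- tested + sum(d$tier == "statistical")
  }
  mc_se <- sqrt(0.05 * 0.95 / tested)
  expect_lte(calls / tested, 0.05 + 2 * mc_se)
})

test_that("the exclusive tier recovers proteins planted below the dropout midpoint", {
  set.seed(5)
  n <- 200
  v <- matrix(rnorm(n * 12, 27, 1), n, 12)
  v[1:50, 7:12] <- matrix(rnorm(50 * 6, 18, 1), 50, 6)  # far below midpoint
  pd <- stats::plogis(-(v - 24))
  v[matrix(runif(n * 12), n, 12) < pd] <- NA
  mat <- two_group_mat(v[, 1:6], v[, 7:12])
  d <- call_deps(mat, cmp_ab())
  expect_gte(mean(d$strategy[1:50] == "exclusive"), 0.8)
})

test_that("DEG thresholding applies both the fold-change and expression floors", {
  expr <- rbind(g1 = c(12.5, 12.5, 8.5, 8.5),  # delta 4, pooled 10.5 -> DEG
                g2 = c(11, 11, 7, 7),          # delta 4, pooled 9    -> no
                g3 = c(16.25, 16.25, 13.75, 13.75))  # delta 2.5      -> no
  res <- call_degs(expr, 1:2, 3:4)
  expect_equal(res$deg, c(TRUE, FALSE, FALSE))
  expect_error(call_degs(rbind(c(1, NA, 3, 4)), 1:2, 3:4), "complete")
})
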