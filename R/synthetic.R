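# Synthetic spatial disc proteomes with known ground truth. The generator
# emulates the design of a two-cadaver spatial LFQ study: 2 ages x 3 lumbar
# levels x 11 locations = 66 profiles, log2 abundances on a bell-shaped
# baseline, abundance-dependent dropout, planted spatial modules (concave
# NP-high, convex OAF-high), age-dependent flattening or inversion of those
# modules, a cellularity gradient carried by histone/housekeeping markers,
# and region MRI intensities generated as a sparse linear function of ECM
# protein abundance plus noise.

HISTONE_MARKERS <- c("HIST1H1B", "HIST1H1C", "HIST1H1D", "HIST1H1E",
                     "HIST1H2BL", "HIST1H3A", "HIST1H4A",
                     "HIST2H2AC", "HIST2H2BE", "HIST2H3A")

#' Configuration for the synthetic disc generator
#'
#' Defaults define the simulated study conditions and are not meant to be
#' tuned per run: a 66-profile design, baseline log2 abundance N(27, 3)
#' (spanning roughly the 15--41 log2 LFQ range of real data), four planted
#' spatial modules patterned on the young disc modules (one concave NP-high
#' module that flattens with age, three convex OAF-high modules of which one
#' inverts with age), logistic abundance-dependent dropout, and a sparse
#' linear proteome-to-MRI map.
#'
#' @param n_proteins Number of background proteins (markers are appended).
#' @param frac_matrisome Fraction of proteins annotated as matrisome.
#' @param module_specs List of module definitions: `name`, `size`, `shape`
#'   (`"concave"`, `"convex"` or `"flat"`), `amplitude` (log2 units),
#'   `age_effect` (`"flatten"`, `"invert"`, `"none"`).
#' @param flatten_factor Multiplier applied to module amplitude in aged
#'   profiles when `age_effect = "flatten"`.
#' @param baseline_mean,baseline_sd Mean/SD of per-protein baseline log2
#'   abundance.
#' @param log2_range Soft range the observed values should span.
#' @param dropout_midpoint Log2 abundance at which dropout probability is
#'   0.5.
#' @param dropout_steepness Slope of the dropout logistic (1/log2 units);
#'   `Inf` gives a hard detection threshold.
#' @param noise_sd Observation noise SD (log2 units).
#' @param module_cor_sd SD of the per-module shared latent factor (log2
#'   units). Members of a functional module co-vary beyond their common
#'   spatial trend (co-regulation); this factor is what makes modules
#'   identifiable by correlation clustering. Not part of the true spatial
#'   means.
#' @param cell_amplitude Cellularity gradient amplitude (log2 units,
#'   OAF-high convex); `cell_age_drop` is subtracted in aged profiles.
#' @param cell_age_drop Aged-vs-young drop of the cellularity index.
#' @param hydration_spec List: `n_predictors` (ECM proteins feeding MRI
#'   intensity), `coefficient_scale`, `noise_sd` (on the raw linear
#'   predictor scale).
#' @param seed Integer seed fixing all randomness; stage sub-streams are
#'   derived by fixed offsets.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 600,
                             frac_matrisome = 0.25,
                             module_specs = list(
                               list(name = "M1", size = 40, shape = "concave",
                                    amplitude = 3, age_effect = "flatten"),
                               list(name = "M2", size = 40, shape = "convex",
                                    amplitude = 3, age_effect = "none"),
                               list(name = "M3", size = 30, shape = "convex",
                                    amplitude = 2.5, age_effect = "flatten"),
                               list(name = "M4", size = 30, shape = "convex",
                                    amplitude = 2.5, age_effect = "invert")),
                             flatten_factor = 0.4,
                             baseline_mean = 27, baseline_sd = 3,
                             log2_range = c(15, 41),
                             dropout_midpoint = 24,
                             dropout_steepness = 1,
                             noise_sd = 1,
                             module_cor_sd = 1.5,
                             cell_amplitude = 4,
                             cell_age_drop = 2,
                             hydration_spec = list(n_predictors = 5,
                                                   coefficient_scale = 1,
                                                   noise_sd = 0.25),
                             seed = 1L) {
  cfg <- as.list(environment())
  sizes <- vapply(cfg$module_specs, `[[`, 0, "size")
  if (sum(sizes) > cfg$n_proteins)
    stop("module sizes exceed n_proteins")
  stopifnot(cfg$frac_matrisome >= 0, cfg$frac_matrisome <= 1,
            cfg$noise_sd >= 0, is.numeric(cfg$seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# Unit-axis coordinate of a location: OAF at 0/1, NP at 0.5. Lateral
# positions 1-7 and anteroposterior 1-5 are both mapped onto [0, 1]; the
# lateral coordinate is used where present.
location_x <- function(meta) {
  x <- ifelse(!is.na(meta$lateral_pos), (meta$lateral_pos - 1) / 6,
              (meta$ap_pos - 1) / 4)
  x
}

module_shape_effect <- function(shape, amplitude, x) {
  switch(shape,
         concave = amplitude * (1 - 4 * (x - 0.5)^2),
         convex  = amplitude * 4 * (x - 0.5)^2,
         flat    = rep(0, length(x)),
         stop("unknown module shape: ", shape))
}

# Full 66-profile metadata: 2 ages x 3 levels x 11 locations.
full_design_meta <- function() {
  locs <- disc_locations()
  grid <- expand.grid(age_group = AGE_GROUPS, level = DISC_LEVELS,
                      loc = seq_len(nrow(locs)), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  l <- locs[grid$loc, ]
  meta <- data.frame(
    profile_id = sprintf("%s_%s_%s", grid$age_group,
                         gsub("/", "", grid$level), l$location),
    age_group = grid$age_group, level = grid$level,
    compartment = l$compartment, direction = l$direction,
    lateral_pos = l$lateral_pos, ap_pos = l$ap_pos,
    location = l$location, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  meta
}

#' Generate a synthetic spatial disc dataset
#'
#' @param config A [synthetic_config()].
#' @return A list with elements:
#'   * `matrix`: an [abundance_matrix()] of 66 profiles with dropout applied;
#'   * `truth`: ground truth (`true_means` matrix, per-protein `module`,
#'     `cell_log2` per profile, hydration `predictors`/`coefficients`/
#'     `intercept` on the 8-bit intensity scale);
#'   * `mri`: data frame of region MRI intensities (8-bit) per
#'     (age_group, level, location).
#' @export
generate_disc_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  meta_full <- full_design_meta()
  meta <- meta_full[, setdiff(names(meta_full), "location")]
  x <- location_x(meta_full)
  aged <- meta_full$age_group == "aged"
  n_bg <- config$n_proteins
  n_mark <- length(HISTONE_MARKERS) + 2L

  # protein table: background proteins, then cellularity markers
  n_mat <- round(config$frac_matrisome * n_bg)
  mat_classes <- rep(setdiff(MATRISOME_CLASSES, "non_matrisome"),
                     length.out = n_mat)
  proteins <- data.frame(
    accession = c(sprintf("P%04d", seq_len(n_bg)),
                  paste0("MK_", c(HISTONE_MARKERS, "GAPDH", "ACTA2"))),
    gene_symbol = c(sprintf("GENE%04d", seq_len(n_bg)),
                    c(HISTONE_MARKERS, "GAPDH", "ACTA2")),
    matrisome_class = c(mat_classes,
                        rep("non_matrisome", n_bg - n_mat + n_mark)),
    stringsAsFactors = FALSE)
  n_prot <- nrow(proteins)
  n_prof <- nrow(meta)

  # module membership: consecutive blocks at the top of the protein list,
  # so modules overlap the matrisome block
  module <- rep(NA_character_, n_prot)
  at <- 1L
  for (ms in config$module_specs) {
    module[at:(at + ms$size - 1L)] <- ms$name
    at <- at + ms$size
  }

  set.seed(config$seed)             # stage 1: baselines
  base <- stats::rnorm(n_bg, config$baseline_mean, config$baseline_sd)
  # markers sit comfortably above the dropout zone so indices are computable
  base <- c(base, stats::rnorm(n_mark, config$baseline_mean + 2, 1))

  true_means <- matrix(base, n_prot, n_prof)
  for (ms in config$module_specs) {
    idx <- which(module == ms$name)
    eff_young <- module_shape_effect(ms$shape, ms$amplitude, x)
    amp_aged <- switch(ms$age_effect,
                       flatten = ms$amplitude * config$flatten_factor,
                       invert  = -ms$amplitude,
                       none    = ms$amplitude)
    eff_aged <- module_shape_effect(ms$shape, amp_aged, x)
    eff <- ifelse(aged, eff_aged, eff_young)
    true_means[idx, ] <- true_means[idx, ] + rep(eff, each = length(idx))
  }
  # cellularity: convex (OAF-high) gradient on the markers, lower when aged
  cell_log2 <- module_shape_effect("convex", config$cell_amplitude, x) -
    ifelse(aged, config$cell_age_drop, 0)
  mark_idx <- n_bg + seq_len(n_mark)
  true_means[mark_idx, ] <- true_means[mark_idx, ] +
    rep(cell_log2, each = n_mark)

  set.seed(config$seed + 1L)        # stage 2: noise + module co-regulation
  values <- true_means +
    matrix(stats::rnorm(n_prot * n_prof, 0, config$noise_sd), n_prot, n_prof)
  # module programs are independent by construction: factors are drawn and
  # then orthogonalised (against the constant and each other) so planted
  # between-module correlation is not inflated by finite-sample chance
  k_mod <- length(config$module_specs)
  if (k_mod > 0 && config$module_cor_sd > 0) {
    u_raw <- matrix(stats::rnorm(n_prof * k_mod), n_prof, k_mod)
    u_mat <- u_raw
    for (blk in split(seq_len(n_prof), aged)) {   # per age group
      q <- qr.Q(qr(cbind(1, u_raw[blk, , drop = FALSE])))[, -1, drop = FALSE]
      u_mat[blk, ] <- apply(q, 2, function(col) col / stats::sd(col)) *
        config$module_cor_sd
    }
    for (j in seq_len(k_mod)) {
      idx <- which(module == config$module_specs[[j]]$name)
      values[idx, ] <- values[idx, ] + rep(u_mat[, j], each = length(idx))
    }
  }

  set.seed(config$seed + 2L)        # stage 3: dropout
  d <- config$dropout_steepness * (true_means - config$dropout_midpoint)
  d[is.nan(d)] <- 0                 # Inf * 0 at the midpoint
  p_drop <- stats::plogis(-d)
  drop <- matrix(stats::runif(n_prot * n_prof), n_prot, n_prof) < p_drop
  values[drop] <- NA

  # stage 4: MRI intensity as a sparse linear function of ECM truth
  set.seed(config$seed + 3L)
  hs <- config$hydration_spec
  ecm <- which(proteins$matrisome_class != "non_matrisome")
  # predictors are ECM proteins, preferentially from the first (NP-high)
  # module so regional intensity tracks the hydrated centre
  pred <- if (length(config$module_specs))
    intersect(which(module == config$module_specs[[1]]$name), ecm)
  else integer()
  if (length(pred) < hs$n_predictors) pred <- union(pred, ecm)
  if (length(pred) < hs$n_predictors)
    stop("not enough matrisome proteins for the hydration predictors")
  pred <- pred[seq_len(hs$n_predictors)]
  coefs <- hs$coefficient_scale * (1 + stats::runif(hs$n_predictors))
  raw <- drop(crossprod(true_means[pred, , drop = FALSE], coefs)) +
    stats::rnorm(n_prof, 0, hs$noise_sd * sqrt(sum(coefs^2)))
  # affine rescale to the 8-bit range, kept identical across ages
  a <- 180 / (max(raw) - min(raw))
  b <- 40 - a * min(raw)
  intensity <- pmin(255, pmax(0, a * raw + b))
  mri <- data.frame(age_group = meta$age_group, level = meta$level,
                    location = meta_full$location, intensity = intensity,
                    stringsAsFactors = FALSE)

  mat <- abundance_matrix(values, proteins, meta)
  truth <- list(
    module = stats::setNames(module, proteins$accession),
    true_means = `dimnames<-`(true_means,
                              list(proteins$accession, meta$profile_id)),
    cell_log2 = stats::setNames(cell_log2, meta$profile_id),
    hydration = list(predictors = proteins$accession[pred],
                     coefficients = coefs * a,   # 8-bit scale
                     intercept = b,
                     raw_scale = c(slope = a, offset = b)),
    config = config)
  list(matrix = mat, truth = truth, mri = mri)
}

#' Generate toy grayscale image stacks for planted region intensities
#'
#' Each disc level becomes one image (repeated over `stacks` acquisitions):
#' a 5 x 7 anatomical grid in which the 11 sampled locations occupy the
#' central row (lateral axis) and central column (anteroposterior axis).
#' Pixels of a region are drawn around its planted intensity with Gaussian
#' noise and clamped to the 8-bit range.
#'
#' @param intensities Data frame with columns `level`, `location`,
#'   `intensity` (one age group).
#' @param stacks Number of image stacks per level (default 3).
#' @param shape Image `c(height, width)` in pixels.
#' @param pixel_noise_sd Pixel noise SD (intensity units).
#' @param background Intensity of unsampled pixels.
#' @param seed Integer seed.
#' @return List with `images` (per level, a list of `stacks` matrices) and
#'   `grid` (data frame: level, location, row/col pixel rectangle, 1-based
#'   inclusive).
#' @export
generate_toy_images <- function(intensities, stacks = 3L, shape = c(40L, 56L),
                                pixel_noise_sd = 2, background = 10,
                                seed = 1L) {
  stopifnot(all(c("level", "location", "intensity") %in% names(intensities)))
  h <- shape[1]; w <- shape[2]
  if (h < 5 || w < 7)
    stop("image shape too small for the 5 x 7 anatomical grid")
  locs <- disc_locations()
  cw <- floor(w / 7); ch <- floor(h / 5)
  if (cw < 1 || ch < 1) stop("grid exceeds image bounds")
  cell_of <- function(loc) {
    l <- locs[locs$location == loc, ]
    col <- if (!is.na(l$lateral_pos)) l$lateral_pos else 4L
    row <- if (!is.na(l$ap_pos)) l$ap_pos else 3L
    c(row0 = (row - 1L) * ch + 1L, row1 = row * ch,
      col0 = (col - 1L) * cw + 1L, col1 = col * cw)
  }
  set.seed(seed)
  images <- list(); grid <- NULL
  for (lev in unique(intensities$level)) {
    sub <- intensities[intensities$level == lev, ]
    stack_list <- vector("list", stacks)
    for (s in seq_len(stacks)) {
      img <- matrix(background, h, w)
      for (i in seq_len(nrow(sub))) {
        rc <- cell_of(sub$location[i])
        px <- (rc["row1"] - rc["row0"] + 1) * (rc["col1"] - rc["col0"] + 1)
        img[rc["row0"]:rc["row1"], rc["col0"]:rc["col1"]] <-
          sub$intensity[i] + stats::rnorm(px, 0, pixel_noise_sd)
      }
      stack_list[[s]] <- pmin(pmax(img, 0), 255)
    }
    images[[lev]] <- stack_list
    g <- do.call(rbind, lapply(sub$location, cell_of))
    grid <- rbind(grid, data.frame(level = lev, location = sub$location,
                                   g, stringsAsFactors = FALSE))
  }
  rownames(grid) <- NULL
  list(images = images, grid = grid)
}

#' Write toy image stacks as 8-bit grayscale PNGs plus a JSON grid map
#'
#' @param toy Result of [generate_toy_images()].
#' @param dir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_toy_images <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (lev in names(toy$images)) {
    for (s in seq_along(toy$images[[lev]])) {
      f <- file.path(dir, sprintf("%s_stack%d.png", gsub("/", "", lev), s))
      png::writePNG(toy$images[[lev]][[s]] / 255, f)
      files <- c(files, f)
    }
  }
  jf <- file.path(dir, "grid.json")
  jsonlite::write_json(toy$grid, jf, dataframe = "rows")
  invisible(c(files, jf))
}

#' Simulate a two-group LFQ comparison with planted effects
#'
#' Benchmark generator for the dropout-aware DEP caller: `n_proteins`
#' proteins measured in two groups of `n_per_group` profiles, baseline
#' abundance N(27, 3), iid noise, logistic abundance-dependent dropout
#' (defaults give roughly 20% missing cells overall), and `n_planted`
#' proteins shifted by `effect` noise-SDs in group B (random sign).
#'
#' @param n_proteins,n_per_group Problem size.
#' @param n_planted Number of proteins with a planted mean shift.
#' @param effect Shift magnitude in units of `noise_sd`.
#' @param noise_sd Within-group SD (log2 units).
#' @param dropout_midpoint,dropout_steepness Dropout logistic parameters.
#' @param seed Integer seed.
#' @return List: `matrix` ([abundance_matrix()] with placeholder metadata),
#'   `groupA`/`groupB` profile ids, `planted` accessions.
#' @export
simulate_two_group <- function(n_proteins = 1000L, n_per_group = 6L,
                               n_planted = 0L, effect = 2,
                               noise_sd = 1, dropout_midpoint = 24,
                               dropout_steepness = 1, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_group
  base <- stats::rnorm(n_proteins, 27, 3)
  shift <- rep(0, n_proteins)
  if (n_planted > 0)
    shift[seq_len(n_planted)] <-
      effect * noise_sd * sample(c(-1, 1), n_planted, replace = TRUE)
  true_means <- matrix(base, n_proteins, n) +
    outer(shift, c(rep(0, n_per_group), rep(1, n_per_group)))
  values <- true_means + matrix(stats::rnorm(n_proteins * n, 0, noise_sd),
                                n_proteins, n)
  p_drop <- stats::plogis(-dropout_steepness *
                            (true_means - dropout_midpoint))
  values[matrix(stats::runif(n_proteins * n), n_proteins, n) < p_drop] <- NA
  ids <- sprintf("S%02d", seq_len(n))
  meta <- placeholder_meta(ids)
  proteins <- data.frame(accession = sprintf("P%04d", seq_len(n_proteins)),
                         gene_symbol = sprintf("GENE%04d", seq_len(n_proteins)),
                         matrisome_class = "non_matrisome",
                         stringsAsFactors = FALSE)
  list(matrix = abundance_matrix(values, proteins, meta),
       groupA = ids[seq_len(n_per_group)],
       groupB = ids[n_per_group + seq_len(n_per_group)],
       planted = proteins$accession[shift != 0])
}

#' Simulate a sparse proteome-to-MRI regression benchmark
#'
#' Training cohort of `n_profiles` regions with `n_predictors` standardised
#' protein abundances, `n_nonzero` of which carry nonzero coefficients;
#' response noise is scaled so that var(signal)/var(noise) = `snr`. A second
#' cohort is generated from the same coefficients for cross-cohort
#' prediction.
#'
#' @param n_profiles,n_predictors,n_nonzero Problem size.
#' @param snr Signal-to-noise variance ratio.
#' @param seed Integer seed.
#' @return List with `x`, `y` (training), `x_new`, `y_new` (test cohort),
#'   `beta` (true coefficients), `support` (nonzero indices).
#' @export
simulate_hydration_benchmark <- function(n_profiles = 33L,
                                         n_predictors = 76L,
                                         n_nonzero = 5L, snr = 5,
                                         seed = 1L) {
  set.seed(seed)
  # equal-magnitude random-sign coefficients: the standard sparse-recovery
  # benchmark design (recovery is then not confounded by coefficient scale)
  beta <- rep(0, n_predictors)
  beta[seq_len(n_nonzero)] <- sample(c(-1, 1), n_nonzero, replace = TRUE)
  gen <- function(n) {
    x <- matrix(stats::rnorm(n * n_predictors), n, n_predictors,
                dimnames = list(NULL, sprintf("P%04d", seq_len(n_predictors))))
    sig <- drop(x %*% beta)
    y <- sig + stats::rnorm(n, 0, sqrt(stats::var(sig) / snr))
    list(x = x, y = y)
  }
  tr <- gen(n_profiles); te <- gen(n_profiles)
  list(x = tr$x, y = tr$y, x_new = te$x, y_new = te$y,
       beta = beta, support = seq_len(n_nonzero))
}
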