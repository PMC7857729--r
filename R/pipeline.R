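# End-to-end orchestration over a synthetic disc dataset, plus the
# benchmark-count routine for users holding the processed 66-profile
# spatial matrix.

#' Run the full analysis pipeline on a synthetic disc dataset
#'
#' Stages run in dependency order: simulate, preprocess (cutoff,
#' imputation, Winsorisation, standardisation), pca (+ age boundary), anova,
#' dep (23-comparison scheme + variable/constant partition), modules,
#' trends (young and aged lateral fits per module), cellularity, mri (toy
#' image stacks, region quantification, biclustering), hydrate (association,
#' LASSO on the aged cohort, prediction on the young cohort), report. Each
#' stage writes plain-text artifacts under `out_dir` and the manifest
#' records parameters and file checksums, so a rerun with the same config is
#' bit-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [synthetic_config()]; its seed drives every stage.
#' @param n_modules Modules to cut from the variable set (default 4).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(out_dir, config = synthetic_config(),
                         n_modules = 4L, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  res <- list(config = config)

  say("simulate: 66-profile synthetic disc")
  sim <- generate_disc_dataset(config)
  mat <- sim$matrix
  write_lfq_matrix(mat, file.path(out_dir, "abundance.tsv"),
                   file.path(out_dir, "metadata.tsv"))
  write_result_table(sim$mri, file.path(out_dir, "mri_regions.tsv"))
  res$sim <- sim

  say("preprocess: cutoff, imputation, winsorisation, standardisation")
  counts <- count_valid(mat, "protein")
  cut <- select_by_steepest_slope(counts, ncol(mat$values))
  sel <- subset_abundance(mat, proteins = cut$selected)
  imp <- impute_chained(sel, n_imputations = 3L, seed = config$seed)
  keep <- winsorise_filter(imp$values)
  vals <- imp$values[keep, , drop = FALSE]
  std <- standardise_profiles(vals)
  res$preprocess <- list(cutoff = cut, imputed = imp, winsorised = keep)

  say("pca: ordination and age boundary")
  pca <- run_pca(std)
  write_result_table(data.frame(profile_id = rownames(pca$scores),
                                pca$scores[, 1:3]),
                     file.path(out_dir, "pca_scores.tsv"))
  bd <- fit_boundary(pca$scores[, 1:2],
                     sel$profiles$age_group, seed = config$seed)
  jsonlite::write_json(bd$contours, file.path(out_dir, "age_boundary.json"),
                       dataframe = "columns", digits = NA)
  res$pca <- pca; res$boundary <- bd

  say("anova: factor-wise variance partition")
  av <- anova_by_factors(mat, scope = "combined")
  write_result_table(av$per_protein, file.path(out_dir, "anova.tsv"))
  res$anova <- av

  say("dep: comparison scheme and variable/constant partition")
  scheme <- default_comparison_scheme(mat$profiles)
  calls <- run_comparison_scheme(mat, scheme)
  union_tab <- do.call(rbind, lapply(calls, function(d) d[d$called, ]))
  write_result_table(union_tab, file.path(out_dir, "deps.tsv"))
  young <- subset_abundance(mat,
                            profiles = mat$profiles$age_group == "young")
  young_calls <- calls[grepl("^young:", names(calls))]
  parts <- partition_variable_constant(young, young_calls)
  res$deps <- calls; res$partition <- parts

  say("modules: clustering the variable set")
  yvals <- young$values[match(parts$variable, young$proteins$accession), ,
                        drop = FALSE]
  mods <- cluster_modules(yvals, n_modules = n_modules)
  write_result_table(data.frame(protein = names(mods$modules),
                                module = unname(mods$modules)),
                     file.path(out_dir, "modules.tsv"))
  res$modules <- mods

  say("trends: GP fits along the lateral axis, young vs aged")
  trends <- list()
  for (k in sort(unique(mods$modules))) {
    prot <- names(mods$modules)[mods$modules == k]
    tr <- list()
    for (a in c("young", "aged")) {
      pts <- tryCatch(module_zscores(mat, prot, "lateral", age = a),
                      error = function(e) NULL)
      tr[[a]] <- if (!is.null(pts) && length(unique(pts$position)) >= 4)
        fit_gpe_trend(pts, axis = "lateral") else NULL
    }
    trends[[as.character(k)]] <- c(tr, list(
      contrast = if (!is.null(tr$young) && !is.null(tr$aged))
        compare_trends(tr$young, tr$aged) else NULL))
  }
  tr_json <- lapply(trends, function(t) list(
    shape_young = if (!is.null(t$young)) t$young$shape_class else NA,
    shape_aged = if (!is.null(t$aged)) t$aged$shape_class else NA,
    amplitude_ratio = if (!is.null(t$contrast)) t$contrast$amplitude_ratio
                      else NA))
  jsonlite::write_json(tr_json, file.path(out_dir, "trends.json"),
                       auto_unbox = TRUE, digits = NA)
  res$trends <- trends

  say("cellularity: histone index and group contrasts")
  idx <- marker_index(mat)
  cmp_age <- group_compare(idx, mat$profiles, "age")
  coexp <- marker_coexpression(mat, "GAPDH", "ACTA2")
  write_result_table(data.frame(profile_id = names(idx),
                                histone_index = unname(idx)),
                     file.path(out_dir, "cellularity.tsv"))
  res$cellularity <- list(index = idx, age_contrast = cmp_age,
                          gapdh_acta2 = coexp)

  say("mri: toy stacks, region quantification, biclustering")
  aged_mri <- sim$mri[sim$mri$age_group == "aged", ]
  toy <- generate_toy_images(aged_mri, seed = config$seed + 4L)
  write_toy_images(toy, file.path(out_dir, "mri"))
  region <- region_intensity(toy$images, toy$grid)
  bic <- bicluster_intensity(region)
  res$mri <- list(region = region, bicluster = bic)

  say("hydrate: association, LASSO, cross-age prediction")
  aged <- subset_abundance(mat, profiles = mat$profiles$age_group == "aged")
  assoc <- hydration_association(aged, aged_mri)
  cand <- assoc$accession[assoc$candidate]
  hyd <- pred <- NULL
  if (length(cand) >= 2) {
    hyd <- fit_hydration_lasso(aged, aged_mri, cand, seed = config$seed)
    young_mri <- sim$mri[sim$mri$age_group == "young", ]
    pred <- predict_hydration(hyd, young, young_mri)
    write_result_table(data.frame(profile_id = names(pred$predicted),
                                  predicted = unname(pred$predicted),
                                  observed = pred$observed),
                       file.path(out_dir, "hydration_prediction.tsv"))
  }
  res$hydration <- list(association = assoc, model = hyd,
                        prediction = pred)

  say("report: manifest")
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("discproteome")),
    seed = config$seed,
    n_proteins = config$n_proteins,
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Reproduce the headline counts from a processed spatial matrix
#'
#' For users holding the processed 66-profile spatial LFQ matrix (log2
#' values, `NA` for missing) and its metadata: recomputes the quantities the
#' original study prints — median valid proteins per profile, the
#' steepest-slope selection size, PC1+PC2 variance explained, the young
#' proteome size, the young variable (DEP union) and constant sets, the
#' young and aged OAF-vs-inner DEP splits, and the cross-age DEP count.
#'
#' @param matrix_path TSV of log2 abundances (first column accession).
#' @param meta_path Profile metadata TSV.
#' @return Named list of counts.
#' @export
benchmark_counts <- function(matrix_path, meta_path) {
  meta <- read_metadata(meta_path)
  mat <- read_lfq_matrix(matrix_path, dialect = "plain_tsv",
                         profiles = meta)
  n_prof <- ncol(mat$values)
  median_valid <- stats::median(count_valid(mat, "profile"))
  cut <- select_by_steepest_slope(count_valid(mat, "protein"), n_prof)
  sel <- subset_abundance(mat, proteins = cut$selected)
  imp <- impute_chained(sel, seed = 1L)
  keep <- winsorise_filter(imp$values)
  std <- standardise_profiles(imp$values[keep, , drop = FALSE])
  pca <- run_pca(std)
  young <- subset_abundance(mat,
                            profiles = mat$profiles$age_group == "young")
  aged <- subset_abundance(mat, profiles = mat$profiles$age_group == "aged")
  y_detect <- sum(count_valid(young, "protein") > 0)
  scheme <- default_comparison_scheme(mat$profiles)
  calls <- run_comparison_scheme(mat, scheme)
  y_calls <- calls[grepl("^young:", names(calls))]
  parts <- partition_variable_constant(young, y_calls)
  oaf_split <- function(tab) {
    c(higher_OAF = sum(tab$called & tab$direction == "A_higher"),
      higher_inner = sum(tab$called & tab$direction == "B_higher"))
  }
  list(
    median_valid_per_profile = median_valid,
    n_selected = cut$chosen_index,
    captured_valid_fraction = cut$captured_valid_fraction,
    included_missing_fraction = cut$included_missing_fraction,
    pc12_variance_pct = 100 * sum(pca$variance_fraction[1:2]),
    young_proteins = y_detect,
    young_variable_set = length(parts$variable),
    young_constant_set = length(parts$constant),
    young_oaf_vs_inner = oaf_split(calls[["young:OAF_vs_inner"]]),
    aged_oaf_vs_inner = oaf_split(calls[["aged:OAF_vs_inner"]]),
    cross_age_deps = sum(calls[["cross:young_vs_aged"]]$called))
}
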