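#!/usr/bin/env Rscript
# Stage 2: valid-value cutoff, imputation, Winsorisation, PCA with an
# age decision boundary.

library(discproteome)

out <- "results"
meta <- read_metadata(file.path(out, "metadata.tsv"))
mat <- read_lfq_matrix(file.path(out, "abundance.tsv"), "plain_tsv",
                       profiles = meta)

counts <- count_valid(mat, "protein")
cut <- select_by_steepest_slope(counts, ncol(mat$values))
cat(sprintf("Cutoff keeps %d of %d proteins (%.1f%% of valid cells, %.1f%% of missing cells).\n",
            cut$chosen_index, nrow(mat$values),
            100 * cut$captured_valid_fraction,
            100 * cut$included_missing_fraction))

sel <- subset_abundance(mat, proteins = cut$selected)
imp <- impute_chained(sel, n_imputations = 3, seed = 1)
cat(sprintf("Chained-equations imputation ran %s sweep(s) per completed matrix.\n",
            paste(imp$n_iterations, collapse = "/")))

keep <- winsorise_filter(imp$values)
std <- standardise_profiles(imp$values[keep, , drop = FALSE])
pca <- run_pca(std)
cat(sprintf("PC1/PC2/PC3 explain %.1f%% / %.1f%% / %.1f%% of variance.\n",
            100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2],
            100 * pca$variance_fraction[3]))

write_result_table(data.frame(profile_id = rownames(pca$scores),
                              pca$scores[, 1:3], check.names = FALSE),
                   file.path(out, "pca_scores.tsv"))
top <- correlate_with_pc(std, pca, 1, top_n = 20, proteins = sel$proteins[
  match(rownames(std), sel$proteins$accession), ])
write_result_table(rbind(cbind(direction = "positive", top$positive),
                         cbind(direction = "negative", top$negative)),
                   file.path(out, "pc1_correlates.tsv"))

bd <- fit_boundary(pca$scores[, 1:2], sel$profiles$age_group, seed = 1)
cat(sprintf("Degree-2 SVM age boundary: training accuracy %.2f.\n",
            bd$training_accuracy))
jsonlite::write_json(bd$contours, file.path(out, "age_boundary.json"),
                     dataframe = "columns", digits = NA)
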