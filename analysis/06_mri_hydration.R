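#!/usr/bin/env Rscript
# Stage 6: region MRI quantification, the hydration matrisome, and the
# cross-age LASSO prediction of MRI intensity from ECM proteins.

library(discproteome)

out <- "results"
meta <- read_metadata(file.path(out, "metadata.tsv"))
mat <- read_lfq_matrix(file.path(out, "abundance.tsv"), "plain_tsv",
                       profiles = meta)
mri <- read_result_table(file.path(out, "mri_regions.tsv"))

# toy image stacks for the aged discs, then recover region intensities
aged_mri <- mri[mri$age_group == "aged", ]
toy <- generate_toy_images(aged_mri, seed = 5)
write_toy_images(toy, file.path(out, "mri_images"))
region <- region_intensity(toy$images, toy$grid)
err <- abs(region$intensity -
             aged_mri$intensity[match(paste(region$level, region$location),
                                      paste(aged_mri$level,
                                            aged_mri$location))])
cat(sprintf("Region quantification recovers planted intensities within %.2f (max over %d regions).\n",
            max(err), nrow(region)))
bic <- bicluster_intensity(region)
cat("Reordered intensity matrix (levels x locations):\n")
print(round(bic$reordered, 1))

# hydration matrisome on the aged cohort
aged <- subset_abundance(mat, profiles = meta$age_group == "aged")
assoc <- hydration_association(aged, aged_mri)
cand <- assoc$accession[assoc$candidate]
cat(sprintf("Hydration matrisome: %d candidate ECM proteins (%d positive, %d negative).\n",
            length(cand), sum(assoc$candidate & assoc$sign == "positive"),
            sum(assoc$candidate & assoc$sign == "negative")))
write_result_table(assoc, file.path(out, "hydration_candidates.tsv"))

fit <- fit_hydration_lasso(aged, aged_mri, cand, seed = 5)
cat(sprintf("LASSO kept %d of %d candidates at lambda = %.3f (%d-fold CV; %d excluded for missingness).\n",
            length(fit$selected), length(fit$predictors), fit$lambda,
            fit$cv_folds, length(fit$excluded)))

young <- subset_abundance(mat, profiles = meta$age_group == "young")
young_mri <- mri[mri$age_group == "young", ]
pred <- predict_hydration(fit, young, young_mri)
cat(sprintf("Cross-age prediction on young discs: PCC %.3f (p = %.1e), Spearman %.3f, IAF/OAF AUC %.3f.\n",
            pred$pearson, pred$pearson_p, pred$spearman,
            pred$auc_iaf_oaf))
write_result_table(data.frame(profile_id = names(pred$predicted),
                              predicted = unname(pred$predicted),
                              observed = pred$observed),
                   file.path(out, "hydration_prediction.tsv"))
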