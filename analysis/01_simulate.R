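#!/usr/bin/env Rscript
# Stage 1: generate the synthetic spatial disc cohort.
#
# 2 ages x 3 lumbar levels x 11 locations = 66 LFQ profiles with planted
# spatial modules, abundance-dependent dropout, cellularity markers, and
# region MRI intensities driven by five ECM proteins. Everything downstream
# reads the TSVs written here.

library(discproteome)

out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- synthetic_config(seed = 1)
sim <- generate_disc_dataset(cfg)

write_lfq_matrix(sim$matrix, file.path(out, "abundance.tsv"),
                 file.path(out, "metadata.tsv"))
write_result_table(sim$mri, file.path(out, "mri_regions.tsv"))
write_result_table(
  data.frame(accession = names(sim$truth$module),
             module = unname(sim$truth$module)),
  file.path(out, "truth_modules.tsv"))

cat(sprintf("Simulated %d proteins x %d profiles; %.1f%% of cells missing.\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            100 * mean(!sim$matrix$mask)))
obs <- sim$matrix$values[sim$matrix$mask]
cat(sprintf("Observed log2 LFQ values span %.1f-%.1f.\n", min(obs), max(obs)))
cat(sprintf("Planted modules: %s.\n",
            paste(vapply(cfg$module_specs, function(m)
              sprintf("%s (%s, n=%d)", m$name, m$shape, m$size), ""),
              collapse = ", ")))
cat(sprintf("MRI intensities planted from %d ECM predictors.\n",
            length(sim$truth$hydration$predictors)))
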