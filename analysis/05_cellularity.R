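#!/usr/bin/env Rscript
# Stage 5: cellularity inferred from histone and housekeeping markers.

library(discproteome)

out <- "results"
meta <- read_metadata(file.path(out, "metadata.tsv"))
mat <- read_lfq_matrix(file.path(out, "abundance.tsv"), "plain_tsv",
                       profiles = meta)

idx <- marker_index(mat)                       # 10-histone preset
gapdh <- marker_index(mat, "GAPDH")
acta2 <- marker_index(mat, "ACTA2")
write_result_table(data.frame(profile_id = names(idx),
                              histone_index = unname(idx),
                              gapdh = unname(gapdh),
                              acta2 = unname(acta2)),
                   file.path(out, "cellularity.tsv"))

age_cmp <- group_compare(idx, meta, "age")
cat(sprintf("Histone index, young vs aged: Wilcoxon p = %.2e (n = %d/%d).\n",
            age_cmp$p, age_cmp$nA, age_cmp$nB))
cmp_cmp <- group_compare(idx, meta, "compartment")
write_result_table(rbind(cbind(grouping = "age", age_cmp),
                         cbind(grouping = "compartment", cmp_cmp)),
                   file.path(out, "cellularity_contrasts.tsv"))

co <- marker_coexpression(mat, "GAPDH", "ACTA2")
cat(sprintf("GAPDH ~ ACTA2 co-expression: r = %.3f (p = %.2e, n = %d).\n",
            co$r, co$p, co$n))
co_h <- marker_coexpression(mat, histone_markers(), "GAPDH")
cat(sprintf("Histones ~ GAPDH: r = %.3f.\n", co_h$r))
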