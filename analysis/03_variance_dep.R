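#!/usr/bin/env Rscript
# Stage 3: factor-wise variance partition and the dropout-aware
# differential-expression scheme with the variable/constant split.

library(discproteome)

out <- "results"
meta <- read_metadata(file.path(out, "metadata.tsv"))
mat <- read_lfq_matrix(file.path(out, "abundance.tsv"), "plain_tsv",
                       profiles = meta)

av <- suppressWarnings(anova_by_factors(mat, scope = "combined"))
write_result_table(av$per_protein, file.path(out, "anova.tsv"))
write_result_table(av$category_summary, file.path(out, "anova_summary.tsv"))
cat("Dominant factor per matrisome category (combined ages):\n")
for (cat_name in names(av$dominant))
  cat(sprintf("  %-16s %s\n", cat_name, av$dominant[cat_name]))

scheme <- default_comparison_scheme(meta)
calls <- run_comparison_scheme(mat, scheme)
cat(sprintf("Ran %d pairwise comparisons.\n", length(calls)))
union_tab <- do.call(rbind, lapply(calls, function(d) d[d$called, ]))
rownames(union_tab) <- NULL
write_result_table(union_tab, file.path(out, "deps.tsv"))
cat(sprintf("DEP calls by strategy: %s.\n",
            paste(sprintf("%s=%d", names(table(union_tab$strategy)),
                          table(union_tab$strategy)), collapse = ", ")))

young <- subset_abundance(mat, profiles = meta$age_group == "young")
parts <- partition_variable_constant(young,
                                     calls[grepl("^young:", names(calls))])
cat(sprintf("Young proteome partition: %d variable, %d constant, %d marginal.\n",
            length(parts$variable), length(parts$constant),
            length(parts$marginal)))
write_result_table(
  data.frame(protein = c(parts$variable, parts$constant, parts$marginal),
             set = rep(c("variable", "constant", "marginal"),
                       c(length(parts$variable), length(parts$constant),
                         length(parts$marginal)))),
  file.path(out, "young_partition.tsv"))
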