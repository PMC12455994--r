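#!/usr/bin/env Rscript
# Stage 3: cross-study normalization (log2 relative abundance + quantiles)
# and the per-sample Spearman scan of composition vs expression with
# per-strain Bonferroni correction.

suppressMessages(library(endoreg))

em <- read_expression_tsv("results/data/expression.tsv")
norm <- normalize_expression(em)
write.table(norm, "results/normalized.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

prof <- read.delim("results/composition_og.tsv")
strains <- unique(norm$strain)
res <- correlate_samples(prof, norm,
                         strain_genome = setNames(strains, strains))
write.table(res, "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
smry <- summarize_significance(res, alpha = 0.05)
write.table(smry, "results/correlation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d samples x %d parameters tested",
                nrow(unique(res[, c("strain", "condition")])),
                length(unique(res$parameter))))
for (i in seq_len(nrow(smry)))
  message(sprintf("  %-12s significant in %d/%d samples, rho %.2f..%.2f",
                  smry$parameter[i], smry$n_significant[i],
                  smry$n_samples[i], smry$rho_min[i], smry$rho_max[i]))
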