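#!/usr/bin/env Rscript
# Stage 5: does midA expression modulate the composition-expression
# correlations? GAMM of per-sample rho on midA quantile expression with a
# strain random intercept, BH-adjusted over the seven parameters; plus the
# co-expression/PCA check that no other gene shares midA's pattern.

suppressMessages(library(endoreg))

res <- read.delim("results/correlations.tsv")
norm <- read.delim("results/normalized.tsv")
mida_tab <- read.delim("results/data/truth_mida.tsv")
mida_og <- mida_tab$value[mida_tab$key == "mida_og"]

pts <- build_sample_points(res, mida_expression(norm, mida_og))
mod <- fit_modulation_all(pts)
write.table(mod, "results/modulation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pts, "results/sample_points.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("midA modulation of composition-expression correlations:")
for (i in seq_len(nrow(mod)))
  message(sprintf("  %-12s %-10s p_bh = %.3g", mod$parameter[i],
                  mod$direction[i], mod$p_bh[i]))

cx <- coexpression_profile(norm, mida_id = mida_og)
coords <- data.frame(condition = rownames(cx$pca$x),
                     cx$pca$x[, 1:min(5, ncol(cx$pca$x))])
write.table(coords, "results/pca_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
s <- cx$mida_summary
message(sprintf("midA pairwise co-correlation: max %.2f, min %.2f, median %.2f (nearest: %s)",
                s$rho_max, s$rho_min, s$rho_median, s$nearest_gene))
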