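#!/usr/bin/env Rscript
# Stage 7: topological (Penny-Hendy / Robinson-Foulds) distance of each
# gene tree to the species tree, the distance-vs-length trend, outlier
# flags, and a tanglegram report for the midA-analogue focal gene (the
# gene tree with the largest distance among long genes).

suppressMessages(library(endoreg))

sp <- ape::read.tree("results/data/species_tree.nwk")
gts <- ape::read.tree("results/data/gene_trees.nwk")
recs <- read.delim("results/data/gene_tree_records.tsv")
names(gts) <- recs$gene_id

td <- tree_distances(sp, gts, lengths = recs)
trend <- distance_vs_length(td)
write.table(trend$records, "results/tree_distances.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(rho = trend$rho, p = trend$p),
            "results/tree_trend.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("distance vs gene length: Spearman rho = %.2f (p = %.2g) over %d genes",
                trend$rho, trend$p, nrow(td)))
message(sprintf("flagged HGT-candidate outliers: %d",
                sum(trend$records$outlier)))

focal <- td$gene_id[which.max(td$distance)]
rep <- paired_tree_report(sp, gts[[focal]])
message(sprintf("tanglegram for %s: %d crossings after rotation",
                focal, rep$crossings))
writeLines(c(paste("species:", paste(rep$species_order, collapse = " ")),
             paste("gene:   ", paste(rep$gene_order, collapse = " ")),
             paste("crossings:", rep$crossings)),
           "results/tanglegram_focal.txt")
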