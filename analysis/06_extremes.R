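#!/usr/bin/env Rscript
# Stage 6: per-strain top/bottom-10 genes by gene %A among COG-annotated
# genes, pooled with orthogroup-level deduplication, and the COG category
# distribution of the pooled low-%A and high-%A sets.

suppressMessages(library(endoreg))

prof <- read.delim("results/composition.tsv")
cog <- read.delim("results/data/cog_map.tsv")
og <- read.delim("results/data/orthogroups.tsv")

ex <- select_extremes(prof, cog, k = 10, orthogroups = og)
write.table(ex$per_strain, "results/extreme_sets_per_strain.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ex$pooled, "results/extreme_sets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
fr <- cog_frequency(ex, cog)
write.table(fr, "results/cog_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (pol in unique(fr$polarity)) {
  d <- fr[fr$polarity == pol, ]
  top <- d[which.max(d$count), ]
  message(sprintf("%s: %d pooled genes; most frequent COG category %s with %d/%d (%.0f%%)",
                  pol, top$total, top$category, top$count, top$total,
                  100 * top$fraction))
}
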