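#!/usr/bin/env Rscript
# Stage 2: per-gene composition profiles (gene-convention %A/%T/%G/%C,
# length, CBI, Nc) and the per-strain co-correlation among parameters.

suppressMessages(library(endoreg))

datadir <- "results/data"
orfs <- read_orf_fasta(file.path(datadir, "orfs.fasta"))
prof <- composition_profiles(orfs)
og <- read.delim(file.path(datadir, "orthogroups.tsv"))

write.table(prof, "results/composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
prof_og <- prof
prof_og$gene_id <- og$orthogroup_id[match(prof$gene_id, og$gene_id)]
write.table(prof_og, "results/composition_og.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cc <- do.call(rbind, lapply(split(prof, prof$genome_id), function(d) {
  m <- co_correlation(d)
  data.frame(genome_id = d$genome_id[1],
             param1 = rep(rownames(m), ncol(m)),
             param2 = rep(colnames(m), each = nrow(m)),
             rho = as.vector(m))
}))
write.table(cc, "results/co_correlation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ac <- cc[cc$param1 == "pctA" & cc$param2 == "pctC", ]
message("per-strain Spearman rho between gene %A and %C:")
message(paste(sprintf("  %s: %.2f", ac$genome_id, ac$rho), collapse = "\n"))
message(sprintf("Nc range: %.1f-%.1f; CBI range: %.2f-%.2f",
                min(prof$nc, na.rm = TRUE), max(prof$nc, na.rm = TRUE),
                min(prof$cbi, na.rm = TRUE), max(prof$cbi, na.rm = TRUE)))
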