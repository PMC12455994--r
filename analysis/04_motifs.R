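#!/usr/bin/env Rscript
# Stage 4: scan 100 bp upstream regions for the five regulatory motifs
# (CtrA in [-30, 0], TATA in [-70, -20], others unwindowed), and compute
# orthogroup-level cross-genome conservation. With the synthetic truth
# registry available, report planted-motif recall.

suppressMessages(library(endoreg))

genomes <- read_genomes_fasta("results/data/genomes.fasta")
ann <- read_annotation_gff("results/data/annotations.gff3")
og <- read.delim("results/data/orthogroups.tsv")

scan <- scan_genomes(genomes, ann)
write.table(scan$hits, "results/motif_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scan$presence, "results/motif_presence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(hits_to_bed(scan$hits, ann), "results/motif_hits.bed",
            sep = "\t", quote = FALSE, row.names = FALSE)

cons <- conservation_scan(scan$presence, og)
write.table(cons, "results/conservation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tot <- table(scan$hits$motif)
message("in-window motif hits per motif:")
message(paste(sprintf("  %s: %d", names(tot), as.integer(tot)),
              collapse = "\n"))
message(sprintf("conserved (>=100/112-scaled presence, >80%% carriage): %d orthogroup x motif pairs",
                sum(cons$conserved)))

truth <- read.delim("results/data/truth_planted.tsv")
if (nrow(truth) > 0) {
  key <- paste(scan$presence$motif, scan$presence$gene_id)
  hit <- scan$presence$present_perfect[
    match(paste(truth$motif, truth$gene_id), key)]
  hit <- hit[!truth$mismatched]
  message(sprintf("planted-motif recall (perfect copies): %.1f%%",
                  100 * mean(hit)))
}
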