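#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — four AT-rich genomes (~1,000
# genes each), planted CtrA and TATA boxes, a 55-sample expression matrix
# (strains 2/5/22/26) whose log expression depends on %C, gene length and a
# midA-tied per-sample %A coefficient, and a 200-gene tree set.
# Writes the bundle under results/data/.

suppressMessages(library(endoreg))

seed <- 1L
outdir <- "results/data"

cfg <- synthetic_config(seed = seed)
bundle <- generate_genomes(cfg)
bundle <- plant_motif(bundle, motif_specs()$CtrA, window = c(-30, -15))
bundle <- plant_motif(bundle, motif_specs()$TATA, window = c(-70, -28))
bundle <- simulate_expression(bundle)
trees <- generate_tree_set(n_taxa = 20, n_genes = 200,
                           hgt_rate = cfg$hgt_rate, seed = seed + 3L)
files <- write_bundle(bundle, outdir, trees = trees)

at <- vapply(bundle$genomes, function(g)
  mean(strsplit(g, "")[[1]] %in% c("A", "T")), numeric(1))
message(sprintf("wrote %d files to %s", length(files), outdir))
message(sprintf("realized genome AT: %s (target %.2f)",
                paste(sprintf("%.3f", at), collapse = ", "),
                cfg$at_fraction))
message(sprintf("planted motifs: %d (%s); midA orthogroup: %s",
                nrow(bundle$truth$planted),
                paste(unique(bundle$truth$planted$motif), collapse = ", "),
                bundle$truth$mida_og))
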