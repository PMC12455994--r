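# endoreg

Nucleotide composition, regulatory motifs and gene expression in
endosymbiont genomes.

## The problem

Endosymbiotic bacteria such as *Wolbachia* have lost most promoters and
intact operons during genome reduction, yet their gene expression is
coordinated with host physiology. One proposed mechanism is composition-
keyed global regulation: a host-inducible methyltransferase (*midA*, a
SAM-dependent arginine methyltransferase with DNA methylation activity)
modifies the genome or the transcription machinery, so that genes are up-
or down-regulated according to their base content — %A-rich genes
repressed when *midA* is highly expressed. `endoreg` implements the full
in-silico analysis chain for this hypothesis, for researchers analysing
endosymbiont RNA-seq compendia:

* **Composition metrics** — per-gene %A/%T/%G/%C under the gene-strand
  convention (gene %A = ORF %T, etc.), length, Codon Bias Index
  (Bennetzen–Hall), and Wright's effective number of codons
  `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`.
* **Cross-study normalization** — per condition,
  `Log2expr_i = mean_s log2((1 + expr_si) / Σ_j (1 + expr_sj))`,
  converted to average-rank quantiles `rank/(N+1)`.
* **Correlation scan** — per-sample Spearman ρ of each composition
  parameter against expression, Bonferroni-adjusted per strain.
* **Motif scan & conservation** — IUPAC scanning (≤1 mismatch) of the
  CtrA-binding site `TTAA-N7-TTAA`, Pribnow `TATAAT`, CAAT, GC and TATA
  boxes in 100 bp upstream regions (TATA windowed to [−70, −20], CtrA to
  [−30, 0]); orthogroup-level conservation across genomes (present in
  ≥ 100/112-scaled genomes and motif-bearing in > 80%).
* **midA modulation** — GAMM `ρ ~ s(midA expression) + (1 | strain)` per
  parameter, Benjamini–Hochberg adjusted; co-expression and PCA checks of
  midA's uniqueness.
* **%A extremes** — per-strain top/bottom-10 %A genes among COG-annotated
  genes, pooled with orthogroup dedup, COG category summaries.
* **Tree concordance** — symmetric-difference (Penny–Hendy /
  Robinson–Foulds) topology distance of each gene tree to the species
  tree, its trend against gene length, and tanglegram reports.

A seeded synthetic-data module generates AT-rich genomes with planted
motifs, expression matrices with planted composition effects tied to a
midA gradient, and gene trees with controlled discordance, so every stage
is testable offline with known ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on a seeded
synthetic bundle (4 strains, 1,000 genes each, 55 samples split
2/5/22/26) and write their tables under `results/`. Running them in order
prints, among other things:

```
$ Rscript analysis/01_simulate.R
realized genome AT: 0.691, 0.691, 0.691, 0.690 (target 0.70)
planted motifs: 800 (CtrA, TATA); midA orthogroup: OG0500

$ Rscript analysis/03_normalize_correlate.R
55 samples x 7 parameters tested
  log10_length significant in 55/55 samples, rho 0.29..0.43
  pctA         significant in 28/55 samples, rho -0.37..0.15
  pctC         significant in 55/55 samples, rho 0.25..0.44
  pctT         significant in 30/55 samples, rho -0.28..0.06

$ Rscript analysis/05_modulation.R
  pctA         increasing p_bh = 0
  pctC         decreasing p_bh = 0
midA pairwise co-correlation: max 0.48, min -0.51, median -0.00

$ Rscript analysis/07_treedist.R
distance vs gene length: Spearman rho = -0.38 (p = 3.1e-08) over 200 genes
```

Reading: %C and gene length correlate positively with expression in every
sample, while %A flips sign across samples — and the GAMM attributes that
flip to the midA expression gradient (`pctA increasing`, i.e. the %A–
expression correlation rises with midA expression, exactly the planted
mechanism). The motif stage recovers 100% of planted regulatory sites and
flags exactly the planted orthogroups as conserved; gene-tree discordance
decreases with gene length as constructed.

The same machinery consumes real data directly: ORF FASTA
(`gene_id|genome_id` headers) or genome FASTA + GFF3, expression TSV with
`strain|condition|replicate` column headers, orthogroup and COG TSVs, and
Newick trees. `run_pipeline(pipeline_config(...))` orchestrates all
stages file-to-file with an idempotent manifest.

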