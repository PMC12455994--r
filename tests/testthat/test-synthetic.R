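# Synthetic data generator: composition targets, determinism, planted-motif
# round trips, expression regression structure, tree sets.

test_that("realized genome AT tracks the configured fraction", {
  b <- generate_genomes(tiny_config(seed = 1, n_genomes = 1, n_genes = 10))
  expect_equal(length(b$genomes), 1)
  expect_equal(nrow(b$annotations), 10)
  at <- at_fraction_of(b$genomes[[1]])
  expect_true(at >= 0.67 && at <= 0.73)
  b50 <- generate_genomes(tiny_config(seed = 2, n_genomes = 1,
                                      n_genes = 10, at_fraction = 0.50))
  at50 <- at_fraction_of(b50$genomes[[1]])
  expect_true(at50 >= 0.47 && at50 <= 0.53)
})

test_that("the same seed reproduces byte-identical outputs", {
  cfg <- tiny_config(seed = 9, n_genes = 12)
  b1 <- simulate_expression(generate_genomes(cfg))
  b2 <- simulate_expression(generate_genomes(cfg))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  t1 <- generate_tree_set(6, 5, seed = 3)
  t2 <- generate_tree_set(6, 5, seed = 3)
  write_bundle(b1, d1, trees = t1)
  write_bundle(b2, d2, trees = t2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("gene placement honours lengths, frames and upstream gaps", {
  cfg <- tiny_config(seed = 3, n_genes = 20)
  b <- generate_genomes(cfg)
  ann <- b$annotations
  expect_true(all((ann$end - ann$start + 1) %% 3 == 0))
  expect_true(all(ann$end - ann$start + 1 >= cfg$gene_length_range[1]))
  # non-overlapping and with full upstream room on both strands
  for (g in unique(ann$genome_id)) {
    a <- ann[ann$genome_id == g, ]
    a <- a[order(a$start), ]
    expect_true(all(diff(a$start) > 0))
    gaps <- a$start[-1] - a$end[-nrow(a)] - 1
    expect_true(all(gaps >= 2 * cfg$upstream_len))
  }
  # ORF sequences are in coding orientation: every gene starts with ATG
  expect_true(all(substr(b$orfs$sequence, 1, 3) == "ATG"))
  # annotated minus-strand genes carry the reverse complement in the genome
  mi <- which(ann$strand == "-")[1]
  a <- ann[mi, ]
  genome_seg <- substr(b$genomes[[a$contig]], a$start, a$end)
  orf <- b$orfs$sequence[b$orfs$gene_id == a$gene_id]
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome_seg))), orf)
})

test_that("the edge gene has a truncated upstream region", {
  cfg <- tiny_config(seed = 4, n_genes = 8, edge_gene = TRUE)
  b <- generate_genomes(cfg)
  first <- b$annotations[1, ]
  expect_lt(first$start - 1, cfg$upstream_len)
  up <- extract_upstream(b$genomes[[first$contig]], first$start,
                         first$end, first$strand, cfg$upstream_len)
  if (first$strand == "+") expect_true(up$truncated)
})

test_that("infeasible packing raises a sizing error", {
  cfg <- tiny_config(seed = 1, n_genomes = 1, n_genes = 10,
                     genome_size = 2000)
  expect_error(generate_genomes(cfg), "genome_size")
})

test_that("planted motifs are re-discoverable exactly at their offsets", {
  cfg <- tiny_config(seed = 6, n_genes = 25)
  b <- generate_genomes(cfg)
  b <- plant_motif(b, motif_specs()$CtrA, window = c(-30, -15),
                   fraction = 1.0, mismatch_fraction = 0)
  reg <- b$truth$planted
  expect_gt(nrow(reg), 0)
  scan <- scan_genomes(b$genomes, b$annotations,
                       motifs = motif_specs()["CtrA"])
  # recall 1.0: every planted gene has a perfect in-window hit
  planted_genes <- unique(reg$gene_id)
  pres <- scan$presence
  expect_true(all(pres$present_perfect[pres$gene_id %in% planted_genes]))
  # exact string at the recorded offset
  for (i in seq_len(nrow(reg))) {
    a <- b$annotations[b$annotations$gene_id == reg$gene_id[i], ]
    up <- extract_upstream(b$genomes[[a$contig]], a$start, a$end,
                           a$strand, cfg$upstream_len)
    got <- substr(up$sequence, reg$start_offset[i] + cfg$upstream_len + 1,
                  reg$start_offset[i] + cfg$upstream_len +
                    nchar(reg$sequence[i]))
    expect_equal(got, reg$sequence[i])
  }
})

test_that("fraction 0 plants nothing; broken copies never match perfectly", {
  cfg <- tiny_config(seed = 7, n_genes = 20)
  b <- generate_genomes(cfg)
  b0 <- plant_motif(b, motif_specs()$TATA, window = c(-70, -20),
                    fraction = 0)
  expect_equal(nrow(b0$truth$planted), 0)
  bm <- plant_motif(b, motif_specs()$Pribnow, window = c(-90, -10),
                    fraction = 1.0, mismatch_fraction = 1.0)
  reg <- bm$truth$planted
  expect_true(all(reg$mismatched))
  for (i in seq_len(nrow(reg))) {
    a <- bm$annotations[bm$annotations$gene_id == reg$gene_id[i], ]
    up <- extract_upstream(bm$genomes[[a$contig]], a$start, a$end,
                           a$strand, cfg$upstream_len)
    h0 <- iupac_scan(up$sequence, "TATAAT", max_mismatch = 0)
    expect_false(reg$start_offset[i] %in% h0$start_offset)
    h1 <- iupac_scan(up$sequence, "TATAAT", max_mismatch = 1)
    expect_true(reg$start_offset[i] %in% h1$start_offset)
  }
})

test_that("motifs planted into the same upstream never clobber each other", {
  cfg <- tiny_config(seed = 15, n_genes = 40)
  b <- generate_genomes(cfg)
  b <- plant_motif(b, motif_specs()$CtrA, window = c(-30, -15),
                   fraction = 1)
  b <- plant_motif(b, motif_specs()$TATA, window = c(-70, -28),
                   fraction = 1)
  reg <- b$truth$planted
  expect_setequal(unique(reg$motif), c("CtrA", "TATA"))
  for (i in seq_len(nrow(reg))) {
    a <- b$annotations[b$annotations$gene_id == reg$gene_id[i], ]
    up <- extract_upstream(b$genomes[[a$contig]], a$start, a$end,
                           a$strand, cfg$upstream_len)
    got <- substr(up$sequence, reg$start_offset[i] + cfg$upstream_len + 1,
                  reg$start_offset[i] + cfg$upstream_len +
                    nchar(reg$sequence[i]))
    expect_equal(got, reg$sequence[i],
                 info = paste(reg$motif[i], reg$gene_id[i]))
  }
})

test_that("a window that does not fit the upstream region errors", {
  b <- generate_genomes(tiny_config(seed = 8, n_genes = 5))
  expect_error(plant_motif(b, motif_specs()$TATA, window = c(-150, -120)),
               "window")
})

test_that("noiseless expression recovers the generating coefficients", {
  cfg <- tiny_config(seed = 10, n_genomes = 1, n_genes = 200,
                     samples = 6,
                     effect_sizes = list(beta_C = 0.35, beta_len = 2.5,
                                         gamma_A_slope = 0.4),
                     noise_sd = 0, replicate_sd = 0, n_replicates = 1,
                     count_scale = 1e8)
  b <- simulate_expression(generate_genomes(cfg))
  prof <- bundle_profiles(b, ids = "orthogroup", full = FALSE)
  truth <- b$truth$mida_gradient
  counts <- b$expression$counts
  mida_row <- which(rownames(counts) == b$truth$mida_og)
  for (s in seq_len(ncol(counts))) {
    y <- log(counts[-mida_row, s])
    d <- prof[match(rownames(counts)[-mida_row], prof$gene_id), ]
    fit <- stats::lm(y ~ d$pctC + d$log10_length + d$pctA)
    expect_equal(unname(coef(fit)[2]), 0.35, tolerance = 1e-6)
    expect_equal(unname(coef(fit)[3]), 2.5, tolerance = 1e-6)
    expect_lt(abs(unname(coef(fit)[4]) - truth$gamma[s]), 1e-6)
  }
})

test_that("midA expression tracks the planted gradient", {
  cfg <- tiny_config(seed = 11, n_genomes = 2, n_genes = 80,
                     samples = c(5, 5))
  b <- simulate_expression(generate_genomes(cfg))
  norm <- normalize_expression(b$expression)
  mida <- mida_expression(norm, b$truth$mida_og)
  truth <- b$truth$mida_gradient
  m <- merge(mida, truth, by = c("strain", "condition"))
  expect_equal(cor(m$quantile, m$mida_level, method = "spearman"), 1)
})

test_that("noiseless monotone limit gives per-sample rho of 1 in %C", {
  cfg <- tiny_config(seed = 12, n_genomes = 1, n_genes = 60, samples = 3,
                     effect_sizes = list(beta_C = 1, beta_len = 0,
                                         gamma_A_slope = 0),
                     noise_sd = 0, replicate_sd = 0, n_replicates = 1,
                     count_scale = 1e8)
  b <- simulate_expression(generate_genomes(cfg))
  norm <- normalize_expression(b$expression)
  prof <- bundle_profiles(b, ids = "orthogroup", full = FALSE)
  mida_og <- b$truth$mida_og
  for (cd in unique(norm$condition)) {
    nr <- norm[norm$condition == cd & norm$gene_id != mida_og, ]
    res <- suppressWarnings(
      correlate_sample(prof, nr, "s", cd,
                       params = c("pctC", "pctA")))
    expect_equal(res$rho[res$parameter == "pctC"], 1, tolerance = 1e-12)
  }
})

test_that("tree sets respect discordance controls and determinism", {
  # no moves at all: every gene tree matches the species tree
  ts0 <- generate_tree_set(8, 6, hgt_rate = 0, perturb_short = FALSE,
                           seed = 2)
  expect_true(all(ts0$records$true_moves == 0))
  d0 <- tree_distances(ts0$species_tree, ts0$gene_trees)
  expect_true(all(d0$distance == 0))
  # one SPR on 6 taxa: positive distance
  set.seed(5)
  sp <- ape::rtree(6)
  moved <- phangorn::rSPR(sp, moves = 1)
  expect_gt(topo_distance(sp, moved), 0)
  # determinism of the newick output
  t1 <- generate_tree_set(10, 8, seed = 4)
  t2 <- generate_tree_set(10, 8, seed = 4)
  expect_identical(ape::write.tree(t1$gene_trees),
                   ape::write.tree(t2$gene_trees))
})

test_that("bundle IO round-trips through the standard formats", {
  cfg <- tiny_config(seed = 13, n_genes = 10)
  b <- simulate_expression(generate_genomes(cfg))
  dir <- tempfile()
  write_bundle(b, dir)
  genomes <- read_genomes_fasta(file.path(dir, "genomes.fasta"))
  expect_equal(genomes, b$genomes)
  orfs <- read_orf_fasta(file.path(dir, "orfs.fasta"))
  expect_equal(orfs$sequence, b$orfs$sequence)
  expect_equal(orfs$gene_id, b$orfs$gene_id)
  ann <- read_annotation_gff(file.path(dir, "annotations.gff3"))
  ann <- ann[match(b$annotations$gene_id, ann$gene_id), ]
  expect_equal(ann$start, b$annotations$start)
  expect_equal(ann$end, b$annotations$end)
  expect_equal(ann$strand, b$annotations$strand)
  em <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(unname(em$counts), unname(b$expression$counts))
  expect_equal(em$design$strain, b$expression$design$strain)
})
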