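# Upstream extraction, IUPAC scanning with mismatch budget, conservation.

test_that("upstream extraction follows the coordinate conventions", {
  contig <- random_seq(300, at = 0.5)
  # + strand gene at 101..110, 100 bp upstream = contig[1..100]
  up <- extract_upstream(contig, 101, 110, "+", 100)
  expect_equal(up$sequence, substr(contig, 1, 100))
  expect_false(up$truncated)
  # gene starting at 50: truncated 49 bp region
  up <- extract_upstream(contig, 50, 60, "+", 100)
  expect_equal(up$length, 49)
  expect_true(up$truncated)
  expect_equal(up$sequence, substr(contig, 1, 49))
  # - strand: reverse complement of the 3' flank
  up <- extract_upstream(contig, 101, 110, "-", 50)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 111, 160))))
  expect_equal(up$sequence, rc)
  # flush against the edge: zero-length region
  up <- extract_upstream(contig, 1, 10, "+", 100)
  expect_equal(up$length, 0)
  expect_true(up$truncated)
})

test_that("worked motif instances match as specified", {
  # CtrA: TTAA-N7-TTAA
  hits <- iupac_scan(paste0(strrep("C", 30), "TTAAGGGGGGGTTAA"),
                     motif_specs()$CtrA$pattern)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$start_offset, -15)
  # TATA box TATAWAWR matches TATATAAA perfectly
  hits <- iupac_scan("TATATAAA", motif_specs()$TATA$pattern)
  expect_equal(hits$start_offset, -8)
  expect_equal(hits$mismatches, 0)
  # Pribnow TATAAT vs TACAAT: one mismatch
  expect_equal(nrow(iupac_scan("TACAAT", "TATAAT", max_mismatch = 0)), 0)
  h1 <- iupac_scan("TACAAT", "TATAAT", max_mismatch = 1)
  expect_equal(h1$mismatches, 1)
})

test_that("scanner agrees with a regex oracle across motifs and budgets", {
  set.seed(31)
  for (i in 1:30) {
    region <- random_seq(200, at = 0.7)
    for (spec in motif_specs()) {
      for (mm in 0:1) {
        got <- iupac_scan(region, spec$pattern, max_mismatch = mm)
        want <- oracle_iupac_scan(region, spec$pattern, max_mm = mm)
        expect_equal(got$start_offset, want$start_offset,
                     info = paste(spec$name, "mm", mm, "seed rep", i))
        expect_equal(got$mismatches, want$mismatches,
                     info = paste(spec$name, "mm", mm))
      }
    }
  }
})

test_that("perfect hits are a subset of one-mismatch hits", {
  set.seed(32)
  for (i in 1:10) {
    region <- random_seq(150)
    for (spec in motif_specs()) {
      h0 <- iupac_scan(region, spec$pattern, max_mismatch = 0)
      h1 <- iupac_scan(region, spec$pattern, max_mismatch = 1)
      expect_true(all(h0$start_offset %in% h1$start_offset))
    }
  }
})

test_that("window filtering restricts by start offset or containment", {
  region <- paste0(strrep("G", 60), "TATAAT", strrep("G", 34))
  # Pribnow start at offset -40
  h <- iupac_scan(region, "TATAAT")
  expect_equal(h$start_offset, -40)
  expect_equal(nrow(iupac_scan(region, "TATAAT", window = c(-45, -35))), 1)
  expect_equal(nrow(iupac_scan(region, "TATAAT", window = c(-30, -1))), 0)
  # containment: [-40, -35] spans the motif exactly
  expect_equal(nrow(iupac_scan(region, "TATAAT", window = c(-40, -35),
                               window_mode = "containment")), 1)
  expect_equal(nrow(iupac_scan(region, "TATAAT", window = c(-40, -36),
                               window_mode = "containment")), 0)
  # pattern longer than region: empty, no error
  expect_equal(nrow(iupac_scan("ACGT", "TTAANNNNNNNTTAA")), 0)
})

test_that("scan_genomes is deterministic and respects annotations", {
  cfg <- tiny_config(seed = 5, n_genes = 15)
  b <- generate_genomes(cfg)
  s1 <- scan_genomes(b$genomes, b$annotations)
  s2 <- scan_genomes(b$genomes, b$annotations)
  expect_identical(s1$hits, s2$hits)
  expect_equal(nrow(s1$regions), nrow(b$annotations))
  expect_setequal(unique(s1$presence$motif), names(motif_specs()))
  # annotation pointing at a missing contig is skipped with a warning
  bad <- b$annotations[1, ]
  bad$contig <- "nope"; bad$gene_id <- "ghost"
  expect_warning(s3 <- scan_genomes(b$genomes, rbind(b$annotations, bad)),
                 "ghost")
  expect_false("ghost" %in% s3$regions$gene_id)
  # empty motif list: empty tables
  s4 <- scan_genomes(b$genomes, b$annotations, motifs = list())
  expect_equal(nrow(s4$hits), 0)
})

test_that("conservation thresholds follow the >80% and >=100/112 rules", {
  genomes <- sprintf("G%03d", 1:112)
  og <- data.frame(orthogroup_id = "OG1", genome_id = genomes,
                   gene_id = paste0(genomes, "_g1"))
  presence <- data.frame(motif = "CtrA", genome_id = genomes,
                         gene_id = paste0(genomes, "_g1"),
                         present_perfect = TRUE, present_1mm = TRUE)
  # present and motif-bearing in all genomes -> conserved
  rec <- conservation_scan(presence, og)
  expect_true(rec$conserved)
  expect_equal(rec$n_present, 112)
  # exactly 80% is not enough (strict > 0.80): 8 of 10 genomes
  og10 <- og[1:10, ]
  p10 <- presence[1:10, ]
  p10$present_perfect <- rep(c(TRUE, FALSE), c(8, 2))
  rec <- conservation_scan(p10, og10, min_presence = 5)
  expect_equal(rec$fraction, 0.8)
  expect_false(rec$conserved)
  p10$present_perfect <- rep(c(TRUE, FALSE), c(9, 1))
  expect_true(conservation_scan(p10, og10, min_presence = 5)$conserved)
  # orthogroup in fewer than min_presence genomes: never conserved
  rec <- conservation_scan(presence[1:50, ], og[1:50, ], min_presence = 100)
  expect_false(rec$conserved)
  # one-mismatch presence definition reported side by side
  p10$present_perfect <- rep(FALSE, 10)
  p10$present_1mm <- rep(TRUE, 10)
  expect_false(conservation_scan(p10, og10, min_presence = 5)$conserved)
  expect_true(conservation_scan(p10, og10, min_presence = 5,
                                definition = "one_mismatch")$conserved)
})
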