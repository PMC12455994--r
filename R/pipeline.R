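# File-based orchestration of the full analysis: each stage reads the
# previous stages' outputs from disk and writes its own, so re-runs can
# skip stages whose outputs are newer than their inputs.

#' Pipeline configuration
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed Integer seed propagated to the synthetic generators.
#' @param synthetic [synthetic_config()]; its seed is overridden by `seed`.
#' @param alpha Significance threshold for correlation summaries.
#' @param min_presence,min_fraction Conservation thresholds
#'   ([conservation_scan()]).
#' @param k Extreme-set size per polarity per strain.
#' @param variant Normalization pseudo-count placement.
#' @param n_taxa,n_tree_genes Tree-set size for the concordance stage.
#' @param force Re-run stages even when outputs are up to date.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            alpha = 0.05, min_presence = NULL,
                            min_fraction = 0.80, k = 10L,
                            variant = "inside",
                            n_taxa = 20L, n_tree_genes = 200L,
                            force = FALSE) {
  synthetic$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, alpha = alpha,
                 min_presence = min_presence,
                 min_fraction = min_fraction, k = as.integer(k),
                 variant = variant, n_taxa = as.integer(n_taxa),
                 n_tree_genes = as.integer(n_tree_genes),
                 force = isTRUE(force)),
            class = "pipeline_config")
}

stage_fresh <- function(outputs, inputs, force) {
  if (force) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  if (length(inputs) == 0L) return(TRUE)
  min(file.mtime(outputs)) >= max(file.mtime(inputs))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate -> composition -> normalize ->
#' correlate -> motifs/conservation -> modulate -> extremes -> treedist.
#' A stage is skipped when its outputs already exist and are newer than its
#' inputs (unless `force`). A failing stage stops the run with the stage
#' name in the error; the manifest written so far is preserved.
#'
#' @param config [pipeline_config()].
#' @return Manifest `data.frame` (stage, outputs, skipped, seconds), also
#'   written to `manifest.tsv` in `outdir` together with input checksums.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out, ...)
  manifest <- list()
  note <- function(stage, outputs, skipped, secs) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, outputs = paste(basename(outputs), collapse = ","),
      skipped = skipped, seconds = round(secs, 2),
      stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, inputs, outputs, fun) {
    if (stage_fresh(outputs, inputs, config$force)) {
      note(stage, outputs, TRUE, 0)
      return(invisible())
    }
    t0 <- proc.time()[3]
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     stopf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e))
                   })
    note(stage, outputs, FALSE, proc.time()[3] - t0)
    invisible(ok)
  }

  # 1. simulate
  sim_out <- p(c("genomes.fasta", "orfs.fasta", "annotations.gff3",
                 "expression.tsv", "orthogroups.tsv", "cog_map.tsv",
                 "truth_planted.tsv", "truth_mida.tsv",
                 "species_tree.nwk", "gene_trees.nwk",
                 "gene_tree_records.tsv"))
  run_stage("simulate", character(0), sim_out, function() {
    bundle <- generate_genomes(config$synthetic)
    specs <- motif_specs()
    bundle <- plant_motif(bundle, specs$CtrA, window = c(-30L, -15L))
    bundle <- plant_motif(bundle, specs$TATA, window = c(-70L, -20L))
    bundle <- simulate_expression(bundle)
    trees <- generate_tree_set(config$n_taxa, config$n_tree_genes,
                               hgt_rate = config$synthetic$hgt_rate,
                               seed = config$seed + 3L)
    write_bundle(bundle, out, trees = trees)
  })

  # 2. composition
  run_stage("composition", p("orfs.fasta"),
            p(c("composition.tsv", "composition_og.tsv",
                "co_correlation.tsv")),
            function() {
    orfs <- read_orf_fasta(p("orfs.fasta"))
    prof <- composition_profiles(orfs)
    write_tsv(prof, p("composition.tsv"))
    og <- read_tsv(p("orthogroups.tsv"))
    prof_og <- prof
    prof_og$gene_id <- og$orthogroup_id[match(prof$gene_id, og$gene_id)]
    write_tsv(prof_og, p("composition_og.tsv"))
    cc <- do.call(rbind, lapply(split(prof, prof$genome_id), function(d) {
      m <- co_correlation(d)
      data.frame(genome_id = d$genome_id[1],
                 param1 = rep(rownames(m), ncol(m)),
                 param2 = rep(colnames(m), each = nrow(m)),
                 rho = as.vector(m), stringsAsFactors = FALSE)
    }))
    write_tsv(cc, p("co_correlation.tsv"))
  })

  # 3. normalize
  run_stage("normalize", p("expression.tsv"), p("normalized.tsv"),
            function() {
    em <- read_expression_tsv(p("expression.tsv"))
    write_tsv(normalize_expression(em, variant = config$variant),
              p("normalized.tsv"))
  })

  # 4. correlate
  run_stage("correlate", p(c("composition_og.tsv", "normalized.tsv")),
            p(c("correlations.tsv", "correlation_summary.tsv")),
            function() {
    prof <- read_tsv(p("composition_og.tsv"))
    norm <- read_tsv(p("normalized.tsv"))
    strains <- unique(norm$strain)
    res <- correlate_samples(prof, norm,
                             strain_genome = stats::setNames(strains,
                                                             strains))
    write_tsv(res, p("correlations.tsv"))
    write_tsv(summarize_significance(res, alpha = config$alpha),
              p("correlation_summary.tsv"))
  })

  # 5. motifs + conservation
  run_stage("motifs",
            p(c("genomes.fasta", "annotations.gff3", "orthogroups.tsv")),
            p(c("motif_hits.tsv", "motif_presence.tsv",
                "conservation.tsv", "motif_hits.bed")),
            function() {
    genomes <- read_genomes_fasta(p("genomes.fasta"))
    ann <- read_annotation_gff(p("annotations.gff3"))
    scan <- scan_genomes(genomes, ann,
                         upstream_len = config$synthetic$upstream_len)
    write_tsv(scan$hits, p("motif_hits.tsv"))
    write_tsv(scan$presence, p("motif_presence.tsv"))
    og <- read_tsv(p("orthogroups.tsv"))
    write_tsv(conservation_scan(scan$presence, og,
                                min_presence = config$min_presence,
                                min_fraction = config$min_fraction),
              p("conservation.tsv"))
    write_tsv(hits_to_bed(scan$hits, ann), p("motif_hits.bed"))
  })

  # 6. modulate
  run_stage("modulate",
            p(c("correlations.tsv", "normalized.tsv", "truth_mida.tsv")),
            p("modulation.tsv"),
            function() {
    res <- read_tsv(p("correlations.tsv"))
    norm <- read_tsv(p("normalized.tsv"))
    mida_tab <- read_tsv(p("truth_mida.tsv"))
    mida_og <- mida_tab$value[mida_tab$key == "mida_og"]
    pts <- build_sample_points(res, mida_expression(norm, mida_og))
    write_tsv(fit_modulation_all(pts), p("modulation.tsv"))
  })

  # 7. extremes
  run_stage("extremes",
            p(c("composition.tsv", "cog_map.tsv", "orthogroups.tsv")),
            p(c("extreme_sets.tsv", "cog_summary.tsv")),
            function() {
    prof <- read_tsv(p("composition.tsv"))
    cog <- read_tsv(p("cog_map.tsv"))
    og <- read_tsv(p("orthogroups.tsv"))
    ex <- select_extremes(prof, cog, k = config$k, orthogroups = og)
    write_tsv(ex$pooled, p("extreme_sets.tsv"))
    write_tsv(cog_frequency(ex, cog), p("cog_summary.tsv"))
  })

  # 8. treedist
  run_stage("treedist",
            p(c("species_tree.nwk", "gene_trees.nwk",
                "gene_tree_records.tsv")),
            p(c("tree_distances.tsv", "tree_trend.tsv")),
            function() {
    sp <- ape::read.tree(p("species_tree.nwk"))
    gts <- ape::read.tree(p("gene_trees.nwk"))
    recs <- read_tsv(p("gene_tree_records.tsv"))
    names(gts) <- recs$gene_id
    td <- tree_distances(sp, gts, lengths = recs)
    trend <- distance_vs_length(td)
    write_tsv(trend$records, p("tree_distances.tsv"))
    write_tsv(data.frame(rho = trend$rho, p = trend$p),
              p("tree_trend.tsv"))
  })

  manifest <- do.call(rbind, manifest)
  inputs <- p(c("genomes.fasta", "orfs.fasta", "expression.tsv"))
  checks <- data.frame(stage = "checksums",
                       outputs = paste(basename(inputs),
                                       substr(tools::md5sum(inputs), 1, 8),
                                       sep = ":", collapse = ","),
                       skipped = NA, seconds = NA)
  manifest <- rbind(manifest, checks)
  write_tsv(manifest, p("manifest.tsv"))
  manifest
}
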