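# Synthetic study generator: AT-rich genomes with annotated ORFs and
# intergenic upstream regions, planted regulatory motifs, and expression
# matrices whose log-expression depends on gene composition with a
# per-sample %A coefficient tied to a designated midA gene. Everything is
# deterministic under the config seed.

#' Synthetic study configuration
#'
#' Parameters of the synthetic data generator. Defaults emulate the
#' motivating study design: four AT-rich (~70\% AT) genomes of ~1,000 genes,
#' 55 samples split 2/5/22/26 across four strains, expression driven
#' positively by gene \%C and length with a per-sample \%A coefficient
#' proportional to the centred midA expression gradient.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_genomes,n_genes_per_genome Genome count and genes per genome.
#' @param at_fraction Target genome AT fraction in (0, 1) (default 0.70).
#' @param gene_length_range `c(min, max)` gene length in bp; sampled lengths
#'   are multiples of 3.
#' @param motif_plant_rate Fraction of orthogroups receiving a planted motif
#'   in [plant_motif()] when no fraction is given.
#' @param upstream_len Guaranteed intergenic upstream length per gene (bp).
#' @param n_strains Number of strains (strain g uses genome g; must be
#'   <= `n_genomes`).
#' @param samples_per_strain Integer vector (length `n_strains`) of
#'   conditions per strain; default `c(2, 5, 22, 26)` (55 samples).
#' @param n_replicates Replicates per condition.
#' @param effect_sizes List with `beta_C`, `beta_len`, `gamma_A_slope`:
#'   coefficients of \%C, log10 length, and the midA-tied per-sample \%A
#'   slope on latent log expression.
#' @param noise_sd Gene x sample latent noise SD (log scale).
#' @param replicate_sd Replicate-level noise SD (log scale).
#' @param count_scale Median expected count after exponentiation.
#' @param hgt_rate Expected random SPR moves per gene tree
#'   ([generate_tree_set()]).
#' @param edge_gene Place the first gene of genome 1 near the contig start
#'   with only half an upstream region (exercises truncation handling).
#' @param genome_size Optional fixed genome size (bp); an error is raised
#'   when the genes plus upstream gaps do not fit. NULL (default) sizes the
#'   genome to fit.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genomes = 4L,
                             n_genes_per_genome = 1000L,
                             at_fraction = 0.70,
                             gene_length_range = c(300L, 1500L),
                             motif_plant_rate = 0.10,
                             upstream_len = 100L,
                             n_strains = 4L,
                             samples_per_strain = c(2L, 5L, 22L, 26L),
                             n_replicates = 2L,
                             effect_sizes = list(beta_C = 0.35,
                                                 beta_len = 2.5,
                                                 gamma_A_slope = 0.4),
                             noise_sd = 1.0,
                             replicate_sd = 0.2,
                             count_scale = 50,
                             hgt_rate = 0.2,
                             edge_gene = FALSE,
                             genome_size = NULL) {
  if (!(at_fraction > 0 && at_fraction < 1))
    stopf("synthetic_config(): at_fraction must be in (0, 1)")
  if (n_strains > n_genomes)
    stopf("synthetic_config(): n_strains (%d) > n_genomes (%d)",
          n_strains, n_genomes)
  samples_per_strain <- rep_len(samples_per_strain, n_strains)
  if (noise_sd < 0 || replicate_sd < 0)
    stopf("synthetic_config(): noise SDs must be nonnegative")
  stopifnot(gene_length_range[1] >= 9, diff(gene_length_range) >= 0)
  structure(list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    n_genes_per_genome = as.integer(n_genes_per_genome),
    at_fraction = at_fraction,
    gene_length_range = as.integer(gene_length_range),
    motif_plant_rate = motif_plant_rate,
    upstream_len = as.integer(upstream_len),
    n_strains = as.integer(n_strains),
    samples_per_strain = as.integer(samples_per_strain),
    n_replicates = as.integer(n_replicates),
    effect_sizes = effect_sizes,
    noise_sd = noise_sd, replicate_sd = replicate_sd,
    count_scale = count_scale, hgt_rate = hgt_rate,
    edge_gene = isTRUE(edge_gene), genome_size = genome_size
  ), class = "synthetic_config")
}

# Base probabilities (A, C, G, T) implied by the AT target: i.i.d. with
# P(A) = P(T) = at/2, P(C) = P(G) = (1 - at)/2.
background_probs <- function(at_fraction) {
  c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
    G = (1 - at_fraction) / 2, T = at_fraction / 2)
}

# Random ORF: ATG + random sense codons + a stop, codon probabilities
# proportional to the product of background base probabilities.
random_orfs <- function(n, lengths, probs) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  cp <- apply(expand.grid(bases, bases, bases)[, c(1, 2, 3)], 1, function(b)
    prod(probs[b]))
  cp <- stats::setNames(as.numeric(cp), paste0(
    expand.grid(bases, bases, bases)[, 1],
    expand.grid(bases, bases, bases)[, 2],
    expand.grid(bases, bases, bases)[, 3]))
  gc <- genetic_code()
  stops <- names(gc)[gc == "*"]
  sense <- setdiff(names(cp), stops)
  p_sense <- cp[sense] / sum(cp[sense])
  p_stop <- cp[stops] / sum(cp[stops])
  vapply(lengths, function(L) {
    n_cod <- L / 3L
    body <- sample(sense, n_cod - 2L, replace = TRUE, prob = p_sense)
    paste0("ATG", paste(body, collapse = ""),
           sample(stops, 1L, prob = p_stop))
  }, character(1))
}

#' Generate synthetic genomes with annotated ORFs
#'
#' Builds one circular contig per genome: i.i.d. background sequence at the
#' configured AT fraction with non-overlapping genes on both strands, each
#' flanked by enough intergenic sequence that every gene has at least
#' `upstream_len` bp of upstream region (except the optional edge gene).
#' Gene `i` of every genome belongs to orthogroup `i`; a COG category map
#' and a designated midA orthogroup are generated alongside.
#'
#' @param config [synthetic_config()].
#' @return Object of class `synthetic_bundle`: `config`, `genomes` (named
#'   character vector of contig sequences), `annotations`, `orfs`,
#'   `orthogroups`, `cog_map`, `truth` (planted-motif registry, midA ids,
#'   expression coefficients once simulated).
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    probs <- background_probs(config$at_fraction)
    up <- config$upstream_len
    gap <- 2L * up + 20L  # upstream regions of adjacent genes never overlap
    n <- config$n_genes_per_genome
    lr <- config$gene_length_range
    len_pool <- seq(3L * ceiling(lr[1] / 3), 3L * floor(lr[2] / 3), by = 3L)
    cog_letters <- c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O",
                    "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
    genomes <- character(0)
    ann <- list(); orfs <- list(); ogs <- list()
    for (g in seq_len(config$n_genomes)) {
      gid <- sprintf("genome%d", g)
      lengths <- sample(len_pool, n, replace = TRUE)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      first_gap <- if (config$edge_gene && g == 1L) up %/% 2L else gap
      starts <- integer(n); ends <- integer(n)
      pos <- first_gap
      for (i in seq_len(n)) {
        starts[i] <- pos + 1L
        ends[i] <- pos + lengths[i]
        pos <- ends[i] + gap
      }
      total <- pos
      if (!is.null(config$genome_size)) {
        if (total > config$genome_size)
          stopf("generate_genomes(): %d genes plus upstream gaps need %d bp but genome_size is %d",
                n, total, config$genome_size)
        total <- config$genome_size
      }
      seq_bg <- paste(sample(names(probs), total, replace = TRUE,
                             prob = probs), collapse = "")
      gene_seqs <- random_orfs(n, lengths, probs)
      for (i in seq_len(n)) {
        placed <- if (strands[i] == "+") gene_seqs[i] else
          reverse_complement(gene_seqs[i])
        substr(seq_bg, starts[i], ends[i]) <- placed
      }
      gene_ids <- sprintf("%s_g%04d", gid, seq_len(n))
      genomes[[gid]] <- seq_bg
      ann[[g]] <- data.frame(genome_id = gid, contig = gid,
                             gene_id = gene_ids, start = starts,
                             end = ends, strand = strands,
                             stringsAsFactors = FALSE)
      orfs[[g]] <- data.frame(gene_id = gene_ids, genome_id = gid,
                              sequence = gene_seqs,
                              stringsAsFactors = FALSE)
      ogs[[g]] <- data.frame(orthogroup_id = sprintf("OG%04d", seq_len(n)),
                             genome_id = gid, gene_id = gene_ids,
                             stringsAsFactors = FALSE)
    }
    og_cat <- sample(cog_letters, n, replace = TRUE)
    multi <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.1, 0.9))
    og_cat[multi] <- paste0(og_cat[multi],
                            sample(cog_letters, sum(multi), replace = TRUE))
    orthogroups <- do.call(rbind, ogs)
    cog_map <- data.frame(
      gene_id = orthogroups$gene_id,
      category = og_cat[as.integer(sub("OG", "", orthogroups$orthogroup_id))],
      stringsAsFactors = FALSE)
    mida_idx <- max(1L, n %/% 2L)
    mida_og <- sprintf("OG%04d", mida_idx)
    annotations <- do.call(rbind, ann)
    structure(list(
      config = config, genomes = genomes, annotations = annotations,
      orfs = do.call(rbind, orfs), orthogroups = orthogroups,
      cog_map = cog_map,
      truth = list(
        mida_og = mida_og,
        mida_genes = stats::setNames(
          orthogroups$gene_id[orthogroups$orthogroup_id == mida_og],
          orthogroups$genome_id[orthogroups$orthogroup_id == mida_og]),
        planted = data.frame(motif = character(0), genome_id = character(0),
                             gene_id = character(0),
                             orthogroup_id = character(0),
                             start_offset = integer(0),
                             sequence = character(0),
                             mismatched = logical(0),
                             stringsAsFactors = FALSE),
        mida_gradient = NULL, gamma = NULL)
    ), class = "synthetic_bundle")
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("synthetic_bundle: %d genome(s) x %d genes, AT target %.2f, %d planted motif(s)\n",
              x$config$n_genomes, x$config$n_genes_per_genome,
              x$config$at_fraction, nrow(x$truth$planted)))
  invisible(x)
}

#' Composition profiles of a synthetic bundle
#'
#' @param bundle `synthetic_bundle`.
#' @param ids `"gene"` (default) keys rows by gene id; `"orthogroup"` keys
#'   them by orthogroup id (the gene id space of the simulated expression
#'   matrix).
#' @param full Compute CBI and Nc as well (default TRUE).
#' @return Composition profile `data.frame`.
#' @export
bundle_profiles <- function(bundle, ids = c("gene", "orthogroup"),
                            full = TRUE) {
  ids <- match.arg(ids)
  orfs <- bundle$orfs
  out <- if (full) {
    composition_profiles(orfs)
  } else {
    composition_table(orfs$sequence, orfs$gene_id, orfs$genome_id)
  }
  if (ids == "orthogroup") {
    out$gene_id <- bundle$orthogroups$orthogroup_id[
      match(out$gene_id, bundle$orthogroups$gene_id)]
  }
  rownames(out) <- NULL
  out
}

# Draw a concrete instance of an IUPAC pattern: degenerate positions
# uniform over their class, N positions from the background distribution.
instantiate_motif <- function(pattern, probs) {
  classes <- iupac_classes()
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(pat, function(p) {
    if (p == "N") sample(names(probs), 1L, prob = probs)
    else sample(classes[[p]], 1L)
  }, character(1)), collapse = "")
}

#' Plant a motif into upstream regions
#'
#' Instantiates the IUPAC pattern and writes it into the upstream region of
#' the genes of a random fraction of orthogroups (planting per orthogroup,
#' so conservation is a recoverable ground truth), at a uniform random start
#' offset within `window`. A `mismatch_fraction` of planted copies carry
#' exactly one substitution at a non-N position (a base outside the
#' position's IUPAC class). The truth registry records every planted copy.
#'
#' @param bundle `synthetic_bundle`.
#' @param motif One element of [motif_specs()] (or a compatible list).
#' @param window `c(lo, hi)` start-offset window for planting; must fit the
#'   upstream region together with the motif length.
#' @param fraction Fraction of orthogroups planted (default: the config's
#'   `motif_plant_rate`).
#' @param mismatch_fraction Fraction of planted copies broken by one
#'   substitution (default 0).
#' @param seed Seed (default derived from the config seed and registry
#'   state, so successive calls are deterministic).
#' @return The bundle with modified genomes and an extended truth registry.
#' @export
plant_motif <- function(bundle, motif, window, fraction = NULL,
                        mismatch_fraction = 0, seed = NULL) {
  config <- bundle$config
  fraction <- fraction %||% config$motif_plant_rate
  m <- nchar(motif$pattern)
  up <- config$upstream_len
  lo <- window[1]; hi <- min(window[2], -m)
  if (lo < -up || hi < lo)
    stopf("plant_motif(): window [%d, %d] does not fit motif of length %d in %d bp upstream",
          window[1], window[2], m, up)
  seed <- seed %||% (config$seed + 1000L + nrow(bundle$truth$planted) +
                       m)
  with_seed(seed, {
    probs <- background_probs(config$at_fraction)
    classes <- iupac_classes()
    pat <- strsplit(toupper(motif$pattern), "", fixed = TRUE)[[1]]
    ogs <- unique(bundle$orthogroups$orthogroup_id)
    chosen <- ogs[sample.int(length(ogs)) <= round(fraction * length(ogs))]
    if (length(chosen) == 0L) return(bundle)
    members <- bundle$orthogroups[
      bundle$orthogroups$orthogroup_id %in% chosen, , drop = FALSE]
    ann <- bundle$annotations
    reg <- list()
    for (i in seq_len(nrow(members))) {
      a <- ann[ann$gene_id == members$gene_id[i], ]
      # skip genes without a full upstream region (edge gene)
      avail <- if (a$strand == "+") a$start - 1L else
        nchar(bundle$genomes[[a$contig]]) - a$end
      if (avail < up) next
      # never overwrite a motif already planted in this gene's upstream
      prev <- bundle$truth$planted[
        bundle$truth$planted$gene_id == a$gene_id, , drop = FALSE]
      candidates <- seq(lo, hi)
      if (nrow(prev) > 0L) {
        for (q in seq_len(nrow(prev))) {
          p_lo <- prev$start_offset[q]
          p_hi <- p_lo + nchar(prev$sequence[q]) - 1L
          candidates <- candidates[candidates + m - 1L < p_lo |
                                     candidates > p_hi]
        }
      }
      if (length(candidates) == 0L) next
      off <- if (length(candidates) == 1L) candidates else
        sample(candidates, 1L)
      inst <- instantiate_motif(motif$pattern, probs)
      mismatched <- stats::runif(1) < mismatch_fraction
      if (mismatched) {
        cand <- which(pat != "N")
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        alt <- setdiff(c("A", "C", "G", "T"), classes[[pat[j]]])
        substr(inst, j, j) <- sample(alt, 1L)
      }
      gseq <- bundle$genomes[[a$contig]]
      if (a$strand == "+") {
        p1 <- a$start + off
        substr(gseq, p1, p1 + m - 1L) <- inst
      } else {
        p2 <- a$end - off           # genome position of motif 5' base
        p1 <- p2 - m + 1L
        substr(gseq, p1, p2) <- reverse_complement(inst)
      }
      bundle$genomes[[a$contig]] <- gseq
      reg[[length(reg) + 1L]] <- data.frame(
        motif = motif$name, genome_id = a$genome_id, gene_id = a$gene_id,
        orthogroup_id = members$orthogroup_id[i],
        start_offset = off, sequence = inst, mismatched = mismatched,
        stringsAsFactors = FALSE)
    }
    if (length(reg))
      bundle$truth$planted <- rbind(bundle$truth$planted,
                                    do.call(rbind, reg))
    bundle
  })
}

#' Simulate an expression matrix over the bundle's orthogroups
#'
#' Latent log expression of gene *i* in sample *s* is
#' `beta_C * pctC_i + beta_len * log10(len_i) + gamma_s * pctA_i + eps`,
#' `eps ~ N(0, noise_sd)`, with `gamma_s = gamma_A_slope * (midA_s -
#' mean(midA))` where `midA_s` follows a fixed per-sample gradient. The
#' designated midA gene's latent value is set to the corresponding quantile
#' of the sample's latent distribution, so its normalized expression tracks
#' the gradient. Counts are emitted per replicate as rounded exp-scale
#' values (zeros possible). Rows are keyed by orthogroup id; each strain's
#' values use its own genome's composition.
#'
#' @param bundle `synthetic_bundle` (from [generate_genomes()]).
#' @param config Configuration (default: the bundle's).
#' @return The bundle with `$expression` ([expression_matrix()]) and truth
#'   entries `mida_gradient` (per-condition midA level) and `gamma`
#'   (per-condition \%A coefficient).
#' @export
simulate_expression <- function(bundle, config = bundle$config) {
  es <- config$effect_sizes
  with_seed(config$seed + 2L, {
    prof <- bundle_profiles(bundle, ids = "orthogroup", full = FALSE)
    strains <- sprintf("genome%d", seq_len(config$n_strains))
    n_cond <- sum(config$samples_per_strain)
    cond_strain <- rep(strains, config$samples_per_strain)
    cond_id <- unlist(lapply(seq_along(strains), function(g)
      sprintf("%s_s%02d", strains[g],
              seq_len(config$samples_per_strain[g]))))
    mida_q <- sample(seq(0.05, 0.95, length.out = n_cond))
    gamma <- es$gamma_A_slope * (mida_q - mean(mida_q))
    og_ids <- unique(bundle$orthogroups$orthogroup_id)
    counts <- NULL; design <- NULL
    for (s in seq_len(n_cond)) {
      p <- prof[prof$genome_id == cond_strain[s], , drop = FALSE]
      p <- p[match(og_ids, p$gene_id), , drop = FALSE]
      mu <- es$beta_C * p$pctC + es$beta_len * p$log10_length +
        gamma[s] * p$pctA +
        stats::rnorm(length(og_ids), 0, config$noise_sd)
      mida_row <- which(og_ids == bundle$truth$mida_og)
      mu[mida_row] <- stats::quantile(mu[-mida_row], probs = mida_q[s],
                                      names = FALSE)
      mu <- mu - stats::median(mu) + log(config$count_scale)
      for (r in seq_len(config$n_replicates)) {
        cnt <- round(exp(mu + stats::rnorm(length(mu), 0,
                                           config$replicate_sd)))
        counts <- cbind(counts, pmax(cnt, 0))
        design <- rbind(design, data.frame(
          replicate = sprintf("%s_r%d", cond_id[s], r),
          strain = cond_strain[s], condition = cond_id[s],
          stringsAsFactors = FALSE))
      }
    }
    rownames(counts) <- og_ids
    bundle$expression <- expression_matrix(counts, design)
    bundle$truth$mida_gradient <- data.frame(
      strain = cond_strain, condition = cond_id, mida_level = mida_q,
      gamma = gamma, stringsAsFactors = FALSE)
    bundle$truth$gamma <- gamma
    bundle
  })
}

#' Generate a species tree and discordant gene trees
#'
#' The species tree comes from a random branching process
#' (`ape::rtree`). Each gene tree applies a Poisson(`hgt_rate`) number of
#' random subtree-prune-regraft moves, and short genes receive one extra
#' move with probability `exp(-(len - min_len) / length_scale)`, emulating
#' the weaker phylogenetic signal of short genes (topological distance
#' decreasing with gene length). True move counts are recorded.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param n_genes Number of gene trees.
#' @param hgt_rate Poisson mean of SPR moves per gene tree.
#' @param length_range Gene length range (bp, uniform).
#' @param length_scale Decay scale of the short-gene perturbation (bp).
#' @param perturb_short Apply the extra short-gene move (default TRUE);
#'   FALSE leaves discordance entirely to `hgt_rate`.
#' @param seed Integer seed.
#' @return List with `species_tree` (phylo), `gene_trees` (multiPhylo,
#'   named), and `records` (`gene_id`, `mean_gene_length`, `true_moves`).
#' @export
generate_tree_set <- function(n_taxa, n_genes, hgt_rate = 0.2,
                              length_range = c(300, 1500),
                              length_scale = 300, perturb_short = TRUE,
                              seed = 1L) {
  if (n_taxa < 4L) stopf("generate_tree_set(): need n_taxa >= 4")
  with_seed(seed, {
    species <- ape::rtree(n_taxa, tip.label = sprintf("genome%d",
                                                      seq_len(n_taxa)))
    lens <- round(stats::runif(n_genes, length_range[1], length_range[2]))
    moves <- stats::rpois(n_genes, hgt_rate)
    if (perturb_short)
      moves <- moves + stats::rbinom(n_genes, 1L,
                                     exp(-(lens - length_range[1]) /
                                           length_scale))
    base <- ape::unroot(species)   # SPR moves operate on the unrooted tree
    gene_trees <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      gene_trees[[i]] <- if (moves[i] > 0L)
        phangorn::rSPR(base, moves = moves[i]) else base
    }
    names(gene_trees) <- sprintf("gene%04d", seq_len(n_genes))
    class(gene_trees) <- "multiPhylo"
    list(species_tree = species, gene_trees = gene_trees,
         records = data.frame(gene_id = names(gene_trees),
                              mean_gene_length = lens,
                              true_moves = moves,
                              stringsAsFactors = FALSE))
  })
}
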