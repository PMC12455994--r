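# Independent oracle implementations used to cross-check the package's
# codon indices, motif scanner and split distance. They deliberately share
# no code with R/: translation comes from seqinr, motif matching from
# regular expressions, and splits from graph component enumeration.

# --- genetic code via seqinr ------------------------------------------------

translate_codon <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

codon_table <- local({
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases,
                                  stringsAsFactors = FALSE), 1, paste,
                      collapse = "")
  aa <- vapply(all_codons, translate_codon, character(1))
  data.frame(codon = all_codons, aa = aa, stringsAsFactors = FALSE)
})

split_into_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return(character(0))
  substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
}

# Brute-force CBI: per-codon tally with expected optimal counts under
# uniform synonymous usage.
oracle_cbi <- function(seq, optimal = ecoli_optimal_codons()) {
  codons <- split_into_codons(seq)
  codons <- codons[!grepl("[^ACGT]", codons)]
  aa <- codon_table$aa[match(codons, codon_table$codon)]
  keep <- aa != "*"
  codons <- codons[keep]; aa <- aa[keep]
  opt_aa <- unique(codon_table$aa[match(optimal, codon_table$codon)])
  syn_counts <- table(codon_table$aa[codon_table$aa != "*"])
  n_opt <- 0; n_tot <- 0; n_ran <- 0
  for (i in seq_along(codons)) {
    if (!aa[i] %in% opt_aa) next
    n_tot <- n_tot + 1
    if (codons[i] %in% optimal) n_opt <- n_opt + 1
    k_opt <- sum(optimal %in%
                   codon_table$codon[codon_table$aa == aa[i]])
    n_ran <- n_ran + k_opt / as.numeric(syn_counts[aa[i]])
  }
  if (n_tot == 0 || abs(n_tot - n_ran) < 1e-12) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

# Brute-force Nc: independent tally of usage fractions and Wright's formula.
oracle_nc <- function(seq) {
  codons <- split_into_codons(seq)
  codons <- codons[!grepl("[^ACGT]", codons)]
  aa <- codon_table$aa[match(codons, codon_table$codon)]
  keep <- aa != "*"
  codons <- codons[keep]; aa <- aa[keep]
  if (length(codons) == 0) return(NA_real_)
  syn_counts <- table(codon_table$aa[codon_table$aa != "*"])
  per_aa <- split(codons, aa)
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (a in names(per_aa)) {
    k <- as.numeric(syn_counts[a])
    if (k == 1) next
    cnt <- table(per_aa[[a]])
    n <- sum(cnt)
    if (n < 2) next
    p <- as.numeric(cnt) / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], f)
  }
  fm <- vapply(f_by_class, function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))
  if (is.na(fm["2"]) || is.na(fm["4"]) || is.na(fm["6"])) return(NA_real_)
  if (is.na(fm["3"])) fm["3"] <- 1 / ((1 / fm["2"] + 1 / fm["4"]) / 2)
  if (any(fm <= 0)) return(NA_real_)
  min(2 + 9 / fm["2"] + 1 / fm["3"] + 5 / fm["4"] + 3 / fm["6"], 61)
}

# Random ORF of n_codons sense codons (no stops), uniform over sense codons
# unless probabilities are supplied.
random_toy_orf <- function(n_codons, prob = NULL) {
  sense <- codon_table$codon[codon_table$aa != "*"]
  paste(sample(sense, n_codons, replace = TRUE, prob = prob),
        collapse = "")
}

# --- regex-based IUPAC oracle ----------------------------------------------

iupac_regex_class <- c(A = "A", C = "C", G = "G", T = "T",
                       R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                       K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                       H = "[ACT]", V = "[ACG]", N = ".")

pattern_to_regex <- function(pattern, relax_at = NULL) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  re <- iupac_regex_class[pat]
  if (!is.null(relax_at)) re[relax_at] <- "."
  paste0("(?=(", paste(re, collapse = ""), "))")
}

regex_starts <- function(region, regex) {
  m <- gregexpr(regex, region, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# All start offsets (negative convention) with <= max_mm mismatches at
# non-N positions, via unions of single-position relaxations.
oracle_iupac_scan <- function(region, pattern, max_mm = 0) {
  U <- nchar(region)
  pat <- strsplit(toupper(pattern), "")[[1]]
  exact <- regex_starts(region, pattern_to_regex(pattern))
  hits <- data.frame(start = exact, mism = integer(length(exact)))
  if (max_mm >= 1) {
    for (j in which(pat != "N")) {
      st <- regex_starts(region, pattern_to_regex(pattern, relax_at = j))
      st <- setdiff(st, hits$start[hits$mism == 0])
      if (length(st))
        hits <- rbind(hits, data.frame(start = st, mism = 1L))
    }
    # a position found by several relaxations is still one mismatch
    hits <- hits[!duplicated(hits$start), ]
  }
  hits <- hits[order(hits$start), ]
  data.frame(start_offset = hits$start - U - 1L,
             mismatches = hits$mism)
}

random_seq <- function(n, at = 0.7) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

# --- graph-based split oracle ----------------------------------------------

# Non-trivial splits of a tree by deleting each edge of its (unrooted)
# graph and reading the leaf content of the components.
oracle_splits <- function(tree, taxa = sort(tree$tip.label)) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  keys <- character(0)
  for (e in seq_len(igraph::ecount(g))) {
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    leaf_nodes <- as.character(seq_len(n))
    side_labels <- tree$tip.label[comp[leaf_nodes] == 1]
    side <- taxa %in% side_labels
    if (sum(side) < 2 || sum(side) > n - 2) next
    if (side[1]) side <- !side
    keys <- c(keys, paste(as.integer(side), collapse = ""))
  }
  unique(keys)
}

oracle_topo_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  taxa <- sort(shared)
  s1 <- oracle_splits(ape::keep.tip(t1, shared), taxa)
  s2 <- oracle_splits(ape::keep.tip(t2, shared), taxa)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# --- misc -------------------------------------------------------------------

tiny_config <- function(seed = 1, n_genomes = 2, n_genes = 30,
                        samples = c(3, 4), ...) {
  synthetic_config(seed = seed, n_genomes = n_genomes,
                   n_genes_per_genome = n_genes,
                   n_strains = n_genomes, samples_per_strain = samples,
                   ...)
}

at_fraction_of <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  mean(v %in% c("A", "T"))
}
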