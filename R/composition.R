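#' Per-gene nucleotide composition under the gene-strand convention
#'
#' ORF sequences follow the mRNA (coding) strand. The analyses in this
#' package are framed on the *gene* (template-complement) composition, which
#' is obtained by complementing the ORF composition: gene \%A = ORF \%T,
#' gene \%T = ORF \%A, gene \%G = ORF \%C, gene \%C = ORF \%G. Percentages
#' are computed over unambiguous bases only.
#'
#' @param sequence Character scalar, ORF nucleotide sequence (coding
#'   orientation, alphabet A/C/G/T plus ambiguity codes).
#' @param gene_id,genome_id Identifiers carried into the output row.
#' @return One-row `data.frame` with `gene_id`, `genome_id`, `pctA`, `pctT`,
#'   `pctG`, `pctC` (gene convention, percentages in \[0, 100\]),
#'   `length_bp`, `log10_length`, and `unreliable` (TRUE when more than 10\%
#'   of bases are ambiguous).
#' @examples
#' gene_composition("AAAT")  # ORF 75% A -> gene pctA = 25, pctT = 75
#' @export
gene_composition <- function(sequence, gene_id = NA_character_,
                             genome_id = NA_character_) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stopf("gene_composition(): empty sequence for gene '%s'", gene_id)
  composition_table(sequence, gene_id, genome_id)
}

# Vectorized composition over many ORFs; shared by gene_composition() and
# composition_profiles().
composition_table <- function(seqs, gene_ids, genome_ids) {
  if (any(!nzchar(seqs) | is.na(seqs)))
    stopf("composition: empty sequence among inputs")
  chars <- strsplit(toupper(seqs), "", fixed = TRUE)
  base_counts <- function(b)
    vapply(chars, function(v) sum(v == b), numeric(1))
  nA <- base_counts("A"); nC <- base_counts("C")
  nG <- base_counts("G"); nT <- base_counts("T")
  n_total <- nchar(seqs)
  n_unamb <- nA + nC + nG + nT
  if (any(n_unamb == 0))
    stopf("composition: sequence with no unambiguous bases")
  data.frame(
    gene_id = gene_ids, genome_id = genome_ids,
    # gene convention: complement of the ORF composition
    pctA = 100 * nT / n_unamb, pctT = 100 * nA / n_unamb,
    pctG = 100 * nC / n_unamb, pctC = 100 * nG / n_unamb,
    length_bp = n_total, log10_length = log10(n_total),
    unreliable = (n_total - n_unamb) / n_total > 0.10,
    stringsAsFactors = FALSE
  )
}

#' Composition profiles for a set of ORFs
#'
#' Computes the full per-gene profile used downstream: base percentages
#' (gene convention), length, log10 length, Codon Bias Index and effective
#' number of codons.
#'
#' @param orfs Named character vector of ORF sequences (names are gene ids),
#'   or a `data.frame` with columns `gene_id`, `genome_id`, `sequence`.
#' @param genome_id Genome id recycled over `orfs` when `orfs` is a vector.
#' @param optimal_codons Codon set passed to [codon_bias_index()].
#' @return `data.frame` with one row per gene: composition columns plus
#'   `cbi` and `nc` (NA where undefined).
#' @export
composition_profiles <- function(orfs, genome_id = NA_character_,
                                 optimal_codons = ecoli_optimal_codons()) {
  if (is.data.frame(orfs)) {
    seqs <- orfs$sequence
    ids <- orfs$gene_id
    gids <- orfs$genome_id
  } else {
    seqs <- unname(orfs)
    ids <- names(orfs) %||% paste0("gene", seq_along(orfs))
    gids <- rep_len(genome_id, length(orfs))
  }
  out <- composition_table(seqs, ids, gids)
  out$cbi <- vapply(seqs, codon_bias_index, numeric(1),
                    optimal_codons = optimal_codons, USE.NAMES = FALSE)
  out$nc <- vapply(seqs, effective_number_of_codons, numeric(1),
                   USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Spearman co-correlation among composition parameters
#'
#' Pairwise Spearman correlation among the composition parameters, computed
#' separately per strain in the published design; here over whatever profile
#' set is supplied.
#'
#' @param profiles `data.frame` from [composition_profiles()].
#' @param params Character vector of profile columns to correlate.
#' @return Symmetric numeric matrix of Spearman rho with unit diagonal;
#'   rows/columns of constant parameters are NA.
#' @export
co_correlation <- function(profiles,
                           params = c("pctA", "pctT", "pctG", "pctC",
                                      "log10_length", "cbi", "nc")) {
  if (nrow(profiles) < 3L)
    stopf("co_correlation(): need at least 3 genes, got %d", nrow(profiles))
  x <- as.matrix(profiles[, params, drop = FALSE])
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  constant <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) <= 1L
  })
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- ifelse(constant, NA_real_, 1)
  rho
}
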