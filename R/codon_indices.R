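# Codon-level composition indices: Codon Bias Index (Bennetzen-Hall, as
# popularised by CodonW) and Wright's effective number of codons (Nc).

# Standard genetic code, DNA alphabet, from Biostrings. Stops are "*".
genetic_code <- function() Biostrings::GENETIC_CODE

# Degeneracy (number of sense codons) per amino acid under the standard code.
aa_degeneracy <- function() {
  gc <- genetic_code()
  gc <- gc[gc != "*"]
  table(factor(gc))
}

#' Classic E. coli optimal codon set
#'
#' The default optimal-codon set for [codon_bias_index()]: the translationally
#' optimal codons of *E. coli* (Sharp & Li), the default reference organism of
#' codon-usage tools. Override with an organism-specific set when one is
#' available.
#'
#' @return Character vector of codons (DNA alphabet).
#' @export
ecoli_optimal_codons <- function() {
  c("TTC",               # Phe
    "CTG",               # Leu
    "ATC",               # Ile
    "GTT", "GTA",        # Val
    "TAC",               # Tyr
    "CAC",               # His
    "CAG",               # Gln
    "AAC",               # Asn
    "AAA",               # Lys
    "GAC",               # Asp
    "GAA",               # Glu
    "TGC",               # Cys
    "CGT", "CGC",        # Arg
    "TCT", "TCC",        # Ser
    "ACT", "ACC",        # Thr
    "CCG",               # Pro
    "GCT", "GCA",        # Ala
    "GGT", "GGC")        # Gly
}

# Split an ORF into clean sense codons: trailing partial codon dropped (with
# a warning), stop codons and codons containing ambiguous bases excluded.
sense_codons <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n %% 3L != 0L) {
    warnf("sequence length %d not a multiple of 3; trailing partial codon dropped", n)
    n <- n - n %% 3L
    s <- substr(s, 1L, n)
  }
  if (n < 3L) return(character(0))
  codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  codons <- codons[!grepl("[^ACGT]", codons)]
  gc <- genetic_code()
  codons[gc[codons] != "*"]
}

#' Codon Bias Index
#'
#' Bennetzen-Hall CBI: how strongly a gene restricts itself to a set of
#' "optimal" codons. `CBI = (N_opt - N_ran) / (N_tot - N_ran)` where `N_opt`
#' is the number of optimal codons observed, `N_tot` the number of codons at
#' amino acids that have at least one optimal codon, and `N_ran` the expected
#' number of optimal codons under uniform synonymous usage. 0 indicates
#' random usage, 1 exclusive use of optimal codons; values can be negative
#' when optimal codons are avoided.
#'
#' @param orf ORF nucleotide sequence (coding orientation).
#' @param optimal_codons Character vector of optimal codons; defaults to the
#'   classic *E. coli* set ([ecoli_optimal_codons()]).
#' @return CBI value (<= 1), or NA when no informative codons are present.
#' @export
codon_bias_index <- function(orf, optimal_codons = ecoli_optimal_codons()) {
  codons <- sense_codons(orf)
  if (length(codons) == 0L) return(NA_real_)
  gc <- genetic_code()
  optimal_codons <- toupper(optimal_codons)
  opt_aa <- unique(gc[optimal_codons])
  deg <- aa_degeneracy()
  aa <- gc[codons]
  informative <- aa %in% opt_aa
  n_tot <- sum(informative)
  if (n_tot == 0L) return(NA_real_)
  n_opt <- sum(informative & codons %in% optimal_codons)
  # expected optimal count under uniform synonymous usage
  k_opt <- table(factor(gc[optimal_codons], levels = opt_aa))
  n_aa <- table(factor(aa[informative], levels = opt_aa))
  n_ran <- sum(as.numeric(n_aa) * as.numeric(k_opt) /
                 as.numeric(deg[opt_aa]))
  if (abs(n_tot - n_ran) < .Machine$double.eps * n_tot) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Effective number of codons (Wright's Nc)
#'
#' Wright's codon-usage evenness statistic. For each amino acid with `n`
#' observed codons and synonymous usage fractions `p_i`, the usage
#' homozygosity is `F = (n * sum(p_i^2) - 1) / (n - 1)`. Nc combines the mean
#' F per degeneracy class of the standard genetic code:
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` (Met and Trp contribute the leading
#' 2). Nc is 20 at maximal bias (one codon per amino acid) and approaches 61
#' under uniform synonymous usage; finite-sample estimates above 61 are
#' clamped.
#'
#' When no 3-fold amino acid (Ile) is observed, F3 is imputed from the 2- and
#' 4-fold classes as `1 / ((1/F2 + 1/F4) / 2)` following Wright; a missing
#' 2-, 4- or 6-fold class makes the statistic undefined (NA).
#'
#' @param orf ORF nucleotide sequence (coding orientation).
#' @return Nc in \[20, 61\], or NA when undefined.
#' @export
effective_number_of_codons <- function(orf) {
  codons <- sense_codons(orf)
  if (length(codons) == 0L) return(NA_real_)
  gc <- genetic_code()
  deg <- aa_degeneracy()
  aa <- gc[codons]
  f_hat <- vapply(unique(aa), function(a) {
    if (deg[a] == 1L) return(NA_real_)  # Met, Trp: constant term
    cnt <- table(codons[aa == a])
    n <- sum(cnt)
    if (n < 2L) return(NA_real_)
    p <- as.numeric(cnt) / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  cls <- as.numeric(deg[unique(aa)])
  class_mean <- function(k) {
    v <- f_hat[cls == k & !is.na(f_hat)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  f2 <- class_mean(2); f3 <- class_mean(3)
  f4 <- class_mean(4); f6 <- class_mean(6)
  if (is.na(f2) || is.na(f4) || is.na(f6)) return(NA_real_)
  if (is.na(f3)) f3 <- 1 / ((1 / f2 + 1 / f4) / 2)
  if (any(c(f2, f3, f4, f6) <= 0)) return(NA_real_)
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(nc, 61)
}
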