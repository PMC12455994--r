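# IUPAC degenerate motif scanning of upstream regions, and cross-genome
# conservation of motif presence per orthogroup.

# IUPAC nucleotide classes.
iupac_classes <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

#' Built-in regulatory motif set
#'
#' The five candidate regulatory elements scanned upstream of genes:
#' CtrA-binding site (`TTAA-N7-TTAA`), Pribnow box (`TATAAT`), CAAT box
#' (`HYYRRCCAWWSR`), GC box (`WRDRGGHRKDKYYK`) and TATA box (`TATAWAWR`).
#' Default scan windows (5' start offset of the motif, relative to the
#' translation start at 0) restrict the genome-wide scans: TATA boxes in
#' \[-70, -20\] and CtrA-binding sites in \[-30, 0\]; the other motifs scan
#' the full upstream region, as does the focal-gene (midA) upstream survey.
#'
#' @return Named list of motif specs: `name`, `pattern` (IUPAC string),
#'   `window` (c(lo, hi) start-offset window, or NULL for the full region).
#' @export
motif_specs <- function() {
  list(
    CtrA    = list(name = "CtrA",    pattern = "TTAANNNNNNNTTAA",
                   window = c(-30L, 0L)),
    Pribnow = list(name = "Pribnow", pattern = "TATAAT",  window = NULL),
    CAAT    = list(name = "CAAT",    pattern = "HYYRRCCAWWSR", window = NULL),
    GC      = list(name = "GC",      pattern = "WRDRGGHRKDKYYK", window = NULL),
    TATA    = list(name = "TATA",    pattern = "TATAWAWR",
                   window = c(-70L, -20L))
  )
}

reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Extract the upstream region of a gene
#'
#' Returns the `length` bases immediately 5' of the translation start, in
#' coding-strand orientation: for a + strand gene the bases ending at
#' `start - 1`; for a - strand gene the reverse complement of the bases
#' beginning at `end + 1`. Offset convention downstream: position -1 is the
#' base immediately 5' of the start codon.
#'
#' @param contig_seq Character scalar, the contig sequence.
#' @param start,end 1-based inclusive gene coordinates on the contig.
#' @param strand `"+"` or `"-"`.
#' @param length Requested upstream length in bp (default 100).
#' @return List with `sequence`, `length` (realized), `truncated` (TRUE when
#'   the contig edge shortened the region; a zero-length region is returned
#'   for a gene flush against the edge and is excluded from conservation
#'   denominators downstream).
#' @export
extract_upstream <- function(contig_seq, start, end, strand, length = 100L) {
  L <- nchar(contig_seq)
  if (start < 1L || end > L || end < start)
    stopf("extract_upstream(): gene [%d, %d] outside contig of length %d",
          start, end, L)
  if (strand == "+") {
    lo <- max(1L, start - length)
    hi <- start - 1L
    seq <- if (hi >= lo) substr(contig_seq, lo, hi) else ""
  } else {
    lo <- end + 1L
    hi <- min(L, end + length)
    seq <- if (hi >= lo) reverse_complement(substr(contig_seq, lo, hi)) else ""
  }
  list(sequence = seq, length = nchar(seq),
       truncated = nchar(seq) < length)
}

#' Scan a region for an IUPAC motif with a mismatch budget
#'
#' Slides the pattern over the region (coding strand only) and reports every
#' start offset at which the number of violated non-N pattern positions is
#' at most `max_mismatch`. N positions always match and never count as
#' mismatches. Offsets are negative: the region's rightmost base is position
#' -1 (immediately 5' of the translation start).
#'
#' @param region Character scalar (upstream sequence, coding orientation),
#'   or the list returned by [extract_upstream()].
#' @param pattern IUPAC pattern string.
#' @param max_mismatch 0 or 1 allowed mismatches.
#' @param window Optional `c(lo, hi)` restricting hits by offset; see
#'   `window_mode`.
#' @param window_mode `"start"` (default): the hit's 5' start offset must lie
#'   in \[lo, hi\]; `"containment"`: the whole motif must lie in \[lo, hi\].
#' @return `data.frame` with `start_offset` and `mismatches`, ordered 5'->3';
#'   empty when the pattern is longer than the region.
#' @export
iupac_scan <- function(region, pattern, max_mismatch = 0L, window = NULL,
                       window_mode = c("start", "containment")) {
  window_mode <- match.arg(window_mode)
  if (is.list(region)) region <- region$sequence
  stopifnot(max_mismatch %in% c(0L, 1L))
  empty <- data.frame(start_offset = integer(0), mismatches = integer(0))
  U <- nchar(region)
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  m <- length(pat)
  if (m > U || U == 0L) return(empty)
  classes <- iupac_classes()
  if (any(!pat %in% names(classes)))
    stopf("iupac_scan(): non-IUPAC symbol in pattern '%s'", pattern)
  bases <- c("A", "C", "G", "T")
  codes <- match(strsplit(toupper(region), "", fixed = TRUE)[[1]], bases)
  codes[is.na(codes)] <- 5L  # ambiguous sequence base: matches only N
  # allowed[j, b]: does base code b satisfy pattern position j?
  allowed <- t(vapply(pat, function(p) {
    c(bases %in% classes[[p]], identical(p, "N"))
  }, logical(5)))
  n_off <- U - m + 1L
  mism <- integer(n_off)
  for (j in seq_len(m)) {
    mism <- mism + !allowed[j, codes[j:(n_off + j - 1L)]]
  }
  off <- seq_len(n_off) - U - 1L
  keep <- mism <= max_mismatch
  if (!is.null(window)) {
    keep <- keep & if (window_mode == "start") {
      off >= window[1] & off <= window[2]
    } else {
      off >= window[1] & (off + m - 1L) <= window[2]
    }
  }
  data.frame(start_offset = off[keep], mismatches = as.integer(mism[keep]))
}

#' Scan all genes of a genome set for a motif panel
#'
#' Extracts each gene's upstream region and scans every motif within its
#' window. Genes whose upstream region is empty (flush against a contig
#' edge) are recorded as excluded and enter no denominator.
#'
#' @param genomes Named character vector of contig sequences (names are
#'   contig ids).
#' @param annotations `data.frame` with columns `genome_id`, `contig`,
#'   `gene_id`, `start`, `end`, `strand`.
#' @param motifs Motif spec list as from [motif_specs()].
#' @param upstream_len Upstream length to extract (default 100).
#' @param max_mismatch Mismatch budget for the scan (default 1; presence is
#'   reported both for perfect and one-mismatch definitions).
#' @param window_mode Passed to [iupac_scan()].
#' @return List with `hits` (`motif`, `genome_id`, `gene_id`, `start_offset`,
#'   `mismatches`), `presence` (per gene x motif: `present_perfect`,
#'   `present_1mm`), and `regions` (per gene: realized length, `truncated`,
#'   `excluded`).
#' @export
scan_genomes <- function(genomes, annotations, motifs = motif_specs(),
                         upstream_len = 100L, max_mismatch = 1L,
                         window_mode = "start") {
  hit_rows <- list()
  pres_rows <- list()
  reg_rows <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (!a$contig %in% names(genomes)) {
      warnf("gene '%s': contig '%s' absent from genome set; skipped",
            a$gene_id, a$contig)
      next
    }
    up <- extract_upstream(genomes[[a$contig]], a$start, a$end, a$strand,
                           upstream_len)
    excluded <- up$length == 0L
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      genome_id = a$genome_id, gene_id = a$gene_id, length = up$length,
      truncated = up$truncated, excluded = excluded,
      stringsAsFactors = FALSE)
    if (excluded) next
    for (mt in motifs) {
      h <- iupac_scan(up$sequence, mt$pattern, max_mismatch = max_mismatch,
                      window = mt$window, window_mode = window_mode)
      if (nrow(h) > 0L)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          motif = mt$name, genome_id = a$genome_id, gene_id = a$gene_id,
          start_offset = h$start_offset, mismatches = h$mismatches,
          stringsAsFactors = FALSE)
      pres_rows[[length(pres_rows) + 1L]] <- data.frame(
        motif = mt$name, genome_id = a$genome_id, gene_id = a$gene_id,
        present_perfect = any(h$mismatches == 0L),
        present_1mm = nrow(h) > 0L,
        stringsAsFactors = FALSE)
    }
  }
  list(hits = if (length(hit_rows)) do.call(rbind, hit_rows) else
         data.frame(motif = character(0), genome_id = character(0),
                    gene_id = character(0), start_offset = integer(0),
                    mismatches = integer(0)),
       presence = if (length(pres_rows)) do.call(rbind, pres_rows) else
         data.frame(motif = character(0), genome_id = character(0),
                    gene_id = character(0), present_perfect = logical(0),
                    present_1mm = logical(0)),
       regions = do.call(rbind, reg_rows))
}

#' Cross-genome conservation of motif presence per orthogroup
#'
#' For each (orthogroup, motif), counts the genomes carrying the gene and
#' the genomes with at least one in-window hit, and flags the orthogroup as
#' conserved when it is present in at least `min_presence` genomes and
#' carries the motif in strictly more than `min_fraction` of them. The
#' published thresholds are 100 of 112 genomes and > 0.80; `min_presence`
#' defaults to the proportional equivalent for the genome count at hand.
#'
#' @param presence Presence table from [scan_genomes()].
#' @param orthogroups `data.frame` with `orthogroup_id`, `genome_id`,
#'   `gene_id`.
#' @param min_presence Minimum genomes carrying the gene (default
#'   `round(n_genomes * 100 / 112)`).
#' @param min_fraction Motif-carrying fraction must exceed this (default
#'   0.80, strict).
#' @param definition `"perfect"` (default) or `"one_mismatch"` presence.
#' @return `data.frame` of `ConservationRecord` rows: `orthogroup_id`,
#'   `motif`, `n_present`, `n_with_motif`, `fraction`, `conserved`.
#' @export
conservation_scan <- function(presence, orthogroups, min_presence = NULL,
                              min_fraction = 0.80,
                              definition = c("perfect", "one_mismatch")) {
  definition <- match.arg(definition)
  pcol <- if (definition == "perfect") "present_perfect" else "present_1mm"
  n_genomes <- length(unique(orthogroups$genome_id))
  if (is.null(min_presence))
    min_presence <- round(n_genomes * 100 / 112)
  og <- merge(orthogroups, presence,
              by = c("genome_id", "gene_id"))
  if (nrow(og) == 0L)
    return(data.frame(orthogroup_id = character(0), motif = character(0),
                      n_present = integer(0), n_with_motif = integer(0),
                      fraction = numeric(0), conserved = logical(0)))
  keys <- unique(og[, c("orthogroup_id", "motif")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    d <- og[og$orthogroup_id == keys$orthogroup_id[k] &
              og$motif == keys$motif[k], , drop = FALSE]
    n_present <- length(unique(d$genome_id))
    n_with <- length(unique(d$genome_id[d[[pcol]]]))
    frac <- n_with / n_present
    data.frame(orthogroup_id = keys$orthogroup_id[k],
               motif = keys$motif[k],
               n_present = n_present, n_with_motif = n_with,
               fraction = frac,
               conserved = n_present >= min_presence & frac > min_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Analytic per-offset perfect-match probability of an IUPAC pattern on
# i.i.d. sequence with the given base probabilities (A, C, G, T order).
# Used for background hit-rate checks.
iupac_match_probability <- function(pattern, base_probs) {
  stopifnot(length(base_probs) == 4, abs(sum(base_probs) - 1) < 1e-9)
  names(base_probs) <- c("A", "C", "G", "T")
  classes <- iupac_classes()
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  prod(vapply(pat, function(p) sum(base_probs[classes[[p]]]), numeric(1)))
}
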