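# Readers and writers for the standard interchange formats: FASTA
# (Biostrings), GFF3 (rtracklayer), Newick (ape), and the package's TSV
# tables.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a synthetic bundle to standard files
#'
#' Emits genomes and ORFs as FASTA (ORF headers `gene_id|genome_id`), the
#' annotation as GFF3 (1-based inclusive, strand column), the expression
#' matrix as TSV with `strain|condition|replicate` column headers, the
#' orthogroup/COG/truth tables as TSV, and any tree set as Newick.
#'
#' @param bundle `synthetic_bundle`.
#' @param dir Output directory (created if missing).
#' @param trees Optional output of [generate_tree_set()].
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir, trees = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$genomes),
                              p("genomes.fasta"))
  files <- c(files, p("genomes.fasta"))
  orf_set <- Biostrings::DNAStringSet(bundle$orfs$sequence)
  names(orf_set) <- paste(bundle$orfs$gene_id, bundle$orfs$genome_id,
                          sep = "|")
  Biostrings::writeXStringSet(orf_set, p("orfs.fasta"))
  files <- c(files, p("orfs.fasta"))
  ann <- bundle$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand, type = "CDS", ID = ann$gene_id,
    genome_id = ann$genome_id, phase = 0L)
  rtracklayer::export(gr, p("annotations.gff3"), format = "gff3")
  files <- c(files, p("annotations.gff3"))
  if (!is.null(bundle$expression)) {
    em <- bundle$expression
    hdr <- with(em$design, paste(strain, condition, replicate, sep = "|"))
    tab <- data.frame(gene_id = rownames(em$counts), em$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(tab) <- c("gene_id", hdr)
    write_tsv(tab, p("expression.tsv"))
    files <- c(files, p("expression.tsv"))
  }
  write_tsv(bundle$orthogroups, p("orthogroups.tsv"))
  write_tsv(bundle$cog_map, p("cog_map.tsv"))
  write_tsv(bundle$truth$planted, p("truth_planted.tsv"))
  mida <- data.frame(key = c("mida_og", names(bundle$truth$mida_genes)),
                     value = c(bundle$truth$mida_og,
                               unname(bundle$truth$mida_genes)),
                     stringsAsFactors = FALSE)
  write_tsv(mida, p("truth_mida.tsv"))
  files <- c(files, p("orthogroups.tsv"), p("cog_map.tsv"),
             p("truth_planted.tsv"), p("truth_mida.tsv"))
  if (!is.null(bundle$truth$mida_gradient)) {
    write_tsv(bundle$truth$mida_gradient, p("truth_mida_gradient.tsv"))
    files <- c(files, p("truth_mida_gradient.tsv"))
  }
  if (!is.null(trees)) {
    ape::write.tree(trees$species_tree, p("species_tree.nwk"))
    ape::write.tree(trees$gene_trees, p("gene_trees.nwk"))
    write_tsv(trees$records, p("gene_tree_records.tsv"))
    files <- c(files, p("species_tree.nwk"), p("gene_trees.nwk"),
               p("gene_tree_records.tsv"))
  }
  invisible(files)
}

#' Read an ORF FASTA with `gene_id|genome_id` headers
#'
#' @param path FASTA file.
#' @return `data.frame` with `gene_id`, `genome_id`, `sequence`.
#' @export
read_orf_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, character(1), 1),
             genome_id = vapply(parts, function(p)
               if (length(p) > 1) p[2] else NA_character_, character(1)),
             sequence = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read genome contigs from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_genomes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a gene annotation from GFF3
#'
#' Keeps CDS/gene features and returns the coordinate table used by the
#' scanning functions.
#'
#' @param path GFF3 file.
#' @return `data.frame` with `genome_id`, `contig`, `gene_id`, `start`,
#'   `end`, `strand`.
#' @export
read_annotation_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  md <- S4Vectors::mcols(gr)
  data.frame(
    genome_id = if ("genome_id" %in% names(md)) md$genome_id
                else as.character(GenomicRanges::seqnames(gr)),
    contig = as.character(GenomicRanges::seqnames(gr)),
    gene_id = md$ID,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Read an expression TSV with `strain|condition|replicate` headers
#'
#' @param path TSV written by [write_bundle()] (first column `gene_id`).
#' @return [expression_matrix()] object.
#' @export
read_expression_tsv <- function(path) {
  tab <- read_tsv(path)
  hdr <- names(tab)[-1]
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad))
    stopf("read_expression_tsv(): malformed column header '%s'",
          hdr[bad][1])
  design <- data.frame(
    replicate = vapply(parts, `[`, character(1), 3),
    strain = vapply(parts, `[`, character(1), 1),
    condition = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$gene_id
  expression_matrix(counts, design)
}

#' Export motif hits as BED-like genome intervals
#'
#' Converts upstream-offset hits to 0-based half-open genome coordinates on
#' the annotated strand.
#'
#' @param hits Hits table from [scan_genomes()].
#' @param annotations Annotation table (as in [scan_genomes()]).
#' @return `data.frame` with `contig`, `start`, `end`, `name`, `score`
#'   (mismatches), `strand`.
#' @export
hits_to_bed <- function(hits, annotations) {
  if (nrow(hits) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  idx <- match(hits$gene_id, annotations$gene_id)
  a <- annotations[idx, ]
  m <- nchar(vapply(motif_specs()[hits$motif], `[[`, character(1),
                    "pattern"))
  g_start <- ifelse(a$strand == "+", a$start + hits$start_offset,
                    a$end - hits$start_offset - m + 1L)
  data.frame(contig = a$contig, start = as.integer(g_start - 1L),
             end = as.integer(g_start - 1L + m),
             name = paste(hits$motif, hits$gene_id, sep = ":"),
             score = hits$mismatches, strand = a$strand,
             stringsAsFactors = FALSE)
}
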