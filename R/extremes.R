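# Genes with extreme adenine content: per-strain top/bottom-k selection by
# gene %A among COG-annotated genes, pooled across strains, and COG
# category summaries of the pooled sets.

#' Select per-strain low/high %A gene sets
#'
#' Among COG-annotated genes of each strain (genome), selects the `k` genes
#' with the lowest and the `k` with the highest gene-convention \%A. Ties
#' are broken deterministically by (\%A, gene id). Pooling across strains
#' deduplicates at the orthogroup level when an orthogroup table is
#' supplied, else by gene id.
#'
#' @param profiles Composition profiles with `genome_id` (one genome per
#'   strain).
#' @param cog_map `data.frame` with `gene_id` and `category` (COG letters;
#'   first letter used for multi-category genes). Genes absent from the map
#'   are not eligible for selection.
#' @param k Selection size per polarity per strain (default 10).
#' @param orthogroups Optional `data.frame` (`orthogroup_id`, `genome_id`,
#'   `gene_id`) for pooled deduplication.
#' @return List with `per_strain` (`data.frame`: `genome_id`, `polarity`,
#'   `gene_id`, `pctA`) and `pooled` (`polarity`, `member_id`, `gene_id`,
#'   `pctA` of the representative), where `member_id` is the orthogroup id
#'   when deduplicating by orthogroup.
#' @export
select_extremes <- function(profiles, cog_map, k = 10L,
                            orthogroups = NULL) {
  annotated <- profiles[profiles$gene_id %in% cog_map$gene_id, ,
                        drop = FALSE]
  if (nrow(annotated) == 0L) {
    warnf("select_extremes(): no COG-annotated genes")
    empty <- data.frame(genome_id = character(0), polarity = character(0),
                        gene_id = character(0), pctA = numeric(0))
    return(list(per_strain = empty,
                pooled = data.frame(polarity = character(0),
                                    member_id = character(0),
                                    gene_id = character(0),
                                    pctA = numeric(0))))
  }
  per_strain <- do.call(rbind, lapply(split(annotated, annotated$genome_id),
                                      function(d) {
    if (nrow(d) < 2L * k)
      warnf("select_extremes(): genome '%s' has %d annotated genes (< 2k); taking all",
            d$genome_id[1], nrow(d))
    ord <- d[order(d$pctA, d$gene_id), , drop = FALSE]
    kk <- min(k, nrow(ord))
    low <- ord[seq_len(kk), , drop = FALSE]
    high <- ord[seq(nrow(ord) - kk + 1L, nrow(ord)), , drop = FALSE]
    high <- high[order(-high$pctA, high$gene_id), , drop = FALSE]
    rbind(
      data.frame(genome_id = low$genome_id, polarity = "low_A",
                 gene_id = low$gene_id, pctA = low$pctA,
                 stringsAsFactors = FALSE),
      data.frame(genome_id = high$genome_id, polarity = "high_A",
                 gene_id = high$gene_id, pctA = high$pctA,
                 stringsAsFactors = FALSE))
  }))
  rownames(per_strain) <- NULL
  # pooled union with dedup
  if (!is.null(orthogroups)) {
    per_strain$member_id <- orthogroups$orthogroup_id[
      match(per_strain$gene_id, orthogroups$gene_id)]
    per_strain$member_id[is.na(per_strain$member_id)] <-
      per_strain$gene_id[is.na(per_strain$member_id)]
  } else {
    per_strain$member_id <- per_strain$gene_id
  }
  pooled <- do.call(rbind, lapply(split(per_strain, per_strain$polarity),
                                  function(d) {
    d <- d[order(d$member_id, d$pctA, d$gene_id), , drop = FALSE]
    d[!duplicated(d$member_id),
      c("polarity", "member_id", "gene_id", "pctA"), drop = FALSE]
  }))
  rownames(pooled) <- NULL
  per_strain$member_id <- NULL
  list(per_strain = per_strain, pooled = pooled)
}

#' COG category frequencies of the pooled extreme sets
#'
#' Counts COG functional categories within each polarity's pooled gene set.
#' Multi-letter annotations contribute their first-listed category only, so
#' counts sum to the set size and fractions to 1.
#'
#' @param extremes Output of [select_extremes()].
#' @param cog_map `data.frame` with `gene_id`, `category`.
#' @return `data.frame` per (polarity, category): `count`, `fraction`,
#'   `total`; unannotated members are tallied under category `"-"`.
#' @export
cog_frequency <- function(extremes, cog_map) {
  pooled <- extremes$pooled
  if (nrow(pooled) == 0L)
    return(data.frame(polarity = character(0), category = character(0),
                      count = integer(0), fraction = numeric(0),
                      total = integer(0)))
  cat_of <- function(ids) {
    full <- cog_map$category[match(ids, cog_map$gene_id)]
    ifelse(is.na(full) | !nzchar(full), "-", substr(full, 1L, 1L))
  }
  out <- do.call(rbind, lapply(split(pooled, pooled$polarity), function(d) {
    cats <- cat_of(d$gene_id)
    tab <- table(cats)
    data.frame(polarity = d$polarity[1], category = names(tab),
               count = as.integer(tab),
               fraction = as.numeric(tab) / nrow(d),
               total = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$polarity, -out$count, out$category), ]
}
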