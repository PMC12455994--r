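# Gene-tree vs species-tree topological concordance: symmetric-difference
# (Robinson-Foulds family / Penny-Hendy) distance over unrooted splits,
# its relation to gene length, and a tanglegram-style paired report.

# Non-trivial splits of a tree as canonical membership keys over `taxa`.
# Each internal edge of the unrooted tree defines a bipartition; the key is
# the membership vector normalized so its first element is 0.
tree_splits <- function(tree, taxa = sort(tree$tip.label)) {
  if (anyDuplicated(tree$tip.label))
    stopf("tree_splits(): duplicate leaf labels")
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  if (n < 4L) return(character(0))
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  nnode <- max(edge)
  below <- vector("list", nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (k in seq_len(nrow(edge))) {
    ch <- edge[k, 2]
    if (ch <= n) next                      # trivial split (single leaf)
    side <- taxa %in% tree$tip.label[below[[ch]]]
    sz <- sum(side)
    if (sz < 2L || sz > n - 2L) next
    if (side[1]) side <- !side
    keys <- c(keys, paste(as.integer(side), collapse = ""))
  }
  unique(keys)
}

#' Topological distance between two trees
#'
#' Number of non-trivial bipartitions (splits) present in exactly one of
#' the two unrooted trees after restriction to their shared leaf set — the
#' symmetric-difference (Penny-Hendy / Robinson-Foulds) topological
#' distance. Some tools report half or twice this count; `scaling` selects
#' the convention.
#'
#' @param t1,t2 `phylo` trees (rooting is ignored; polytomies allowed).
#' @param scaling `"count"` (default, symmetric-difference cardinality),
#'   `"half"` or `"double"`.
#' @return Nonnegative number; NA (with a warning) when fewer than 4 leaves
#'   are shared.
#' @export
topo_distance <- function(t1, t2, scaling = c("count", "half", "double")) {
  scaling <- match.arg(scaling)
  if (anyDuplicated(t1$tip.label) || anyDuplicated(t2$tip.label))
    stopf("topo_distance(): duplicate leaf labels")
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) {
    warnf("topo_distance(): only %d shared leaves; distance undefined",
          length(shared))
    return(NA_real_)
  }
  t1 <- ape::keep.tip(t1, shared)
  t2 <- ape::keep.tip(t2, shared)
  taxa <- sort(shared)
  s1 <- tree_splits(t1, taxa)
  s2 <- tree_splits(t2, taxa)
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  switch(scaling, count = d, half = d / 2, double = 2 * d)
}

#' Distance of every gene tree to the species tree
#'
#' @param species_tree `phylo`.
#' @param gene_trees Named list / `multiPhylo` of gene trees.
#' @param lengths Optional `data.frame` with `gene_id` and
#'   `mean_gene_length` to merge in.
#' @return `data.frame`: `gene_id`, `distance`, `n_shared_leaves`, plus
#'   `mean_gene_length` when supplied.
#' @export
tree_distances <- function(species_tree, gene_trees, lengths = NULL) {
  ids <- names(gene_trees) %||% sprintf("gene%04d", seq_along(gene_trees))
  rows <- lapply(seq_along(gene_trees), function(i) {
    gt <- gene_trees[[i]]
    data.frame(gene_id = ids[i],
               distance = topo_distance(species_tree, gt),
               n_shared_leaves = length(intersect(species_tree$tip.label,
                                                  gt$tip.label)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(lengths))
    out <- merge(out, lengths[, c("gene_id", "mean_gene_length")],
                 by = "gene_id", sort = TRUE)
  out
}

#' Trend of topological distance versus gene length
#'
#' Spearman correlation between gene-tree/species-tree distance and mean
#' gene length, plus a per-gene outlier flag: within each gene's +/-20\%
#' length band, a gene whose distance is the band maximum (and above the
#' band median, with at least 3 genes in the band) is flagged as a
#' horizontal-transfer candidate.
#'
#' @param records `data.frame` with `gene_id`, `mean_gene_length`,
#'   `distance` (>= 5 rows).
#' @return List with `rho`, `p`, and `records` (input plus `band_size`,
#'   `band_rank`, `outlier`).
#' @export
distance_vs_length <- function(records) {
  if (nrow(records) < 5L)
    stopf("distance_vs_length(): need >= 5 records")
  d <- records$distance; len <- records$mean_gene_length
  if (length(unique(d[!is.na(d)])) <= 1L) {
    warnf("distance_vs_length(): distances constant; trend undefined")
    rho <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(len, d, method = "spearman",
                                           exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  band_size <- integer(nrow(records))
  band_rank <- numeric(nrow(records))
  outlier <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    band <- which(len >= 0.8 * len[i] & len <= 1.2 * len[i])
    band_size[i] <- length(band)
    band_rank[i] <- rank(d[band], ties.method = "average")[
      which(band == i)] / length(band)
    outlier[i] <- length(band) >= 3L && !is.na(d[i]) &&
      d[i] == max(d[band], na.rm = TRUE) &&
      d[i] > stats::median(d[band], na.rm = TRUE)
  }
  records$band_size <- band_size
  records$band_rank <- band_rank
  records$outlier <- outlier
  list(rho = rho, p = p, records = records)
}

# Leaf order of a tree under the current child ordering stored in `kids`.
leaf_order_from <- function(kids, node, n) {
  if (node <= n) return(node)
  unlist(lapply(kids[[node]], leaf_order_from, kids = kids, n = n))
}

# Inversions between a leaf order and reference positions.
count_crossings <- function(order_labels, ref_positions) {
  p <- ref_positions[order_labels]
  sum(vapply(seq_along(p), function(i) sum(p[seq_len(i - 1)] > p[i]),
             numeric(1)))
}

#' Paired-tree (tanglegram) report
#'
#' Restricts both trees to their shared leaves, fixes the species-tree leaf
#' order, and heuristically rotates the gene tree's internal nodes to
#' minimize the number of crossing connector lines: children are first
#' ordered by the mean species-order position of their descendant leaves,
#' then single-node flips are applied while they reduce the crossing count.
#'
#' @param species_tree,gene_tree `phylo` trees sharing >= 4 leaves.
#' @return List with `species_order`, `gene_order` (leaf label orderings)
#'   and `crossings` (achieved crossing count).
#' @export
paired_tree_report <- function(species_tree, gene_tree) {
  shared <- intersect(species_tree$tip.label, gene_tree$tip.label)
  if (length(shared) < 4L)
    stopf("paired_tree_report(): only %d shared leaves", length(shared))
  sp <- ape::keep.tip(species_tree, shared)
  gt <- ape::keep.tip(gene_tree, shared)
  sp <- stats::reorder(sp, "cladewise")
  n_sp <- length(sp$tip.label)
  sp_order <- sp$tip.label[sp$edge[sp$edge[, 2] <= n_sp, 2]]
  ref <- stats::setNames(seq_along(sp_order), sp_order)
  n <- length(gt$tip.label)
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  kids <- lapply(stats::setNames(kids, names(kids)), as.integer)
  kids_vec <- vector("list", max(gt$edge))
  kids_vec[as.integer(names(kids))] <- kids
  root <- setdiff(gt$edge[, 1], gt$edge[, 2])[1]
  # mean reference position of leaves below each node
  mean_pos <- function(node) {
    lv <- leaf_order_from(kids_vec, node, n)
    mean(ref[gt$tip.label[lv]])
  }
  internal <- sort(unique(gt$edge[, 1]))
  for (nd in rev(internal)) {
    kids_vec[[nd]] <- kids_vec[[nd]][order(vapply(kids_vec[[nd]], mean_pos,
                                                  numeric(1)))]
  }
  current <- function() {
    lv <- leaf_order_from(kids_vec, root, n)
    count_crossings(gt$tip.label[lv], ref)
  }
  best <- current()
  improved <- TRUE
  while (improved && best > 0) {
    improved <- FALSE
    for (nd in internal) {
      old <- kids_vec[[nd]]
      kids_vec[[nd]] <- rev(old)
      cr <- current()
      if (cr < best) {
        best <- cr
        improved <- TRUE
      } else {
        kids_vec[[nd]] <- old
      }
    }
  }
  lv <- leaf_order_from(kids_vec, root, n)
  list(species_order = sp_order, gene_order = gt$tip.label[lv],
       crossings = best)
}
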