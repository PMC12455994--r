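# Cross-study expression normalization: per-replicate log2 relative
# abundance with a pseudo-count, averaged over replicates of a condition,
# then converted to quantiles within each condition.

#' Construct an expression matrix object
#'
#' Container for raw per-replicate gene expression quantifications with the
#' replicate design (strain and condition labels).
#'
#' @param counts Numeric matrix, genes x replicates, nonnegative; rownames
#'   are gene ids.
#' @param design `data.frame` with one row per replicate: columns
#'   `replicate`, `strain`, `condition` (a condition is a host-strain
#'   sample; replicates nest within conditions).
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE))
    stopf("expression_matrix(): negative values not allowed")
  need <- c("replicate", "strain", "condition")
  if (!all(need %in% names(design)))
    stopf("expression_matrix(): design must have columns %s",
          paste(need, collapse = ", "))
  if (ncol(counts) != nrow(design))
    stopf("expression_matrix(): %d count columns vs %d design rows",
          ncol(counts), nrow(design))
  if (anyDuplicated(design$replicate))
    stopf("expression_matrix(): duplicated replicate ids")
  colnames(counts) <- design$replicate
  structure(list(counts = counts, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d replicates (%d conditions, %d strains)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$design$condition)),
              length(unique(x$design$strain))))
  invisible(x)
}

#' Per-condition log2 relative expression
#'
#' For each replicate `s` of a condition, each gene's quantification is
#' converted to a pseudo-counted relative abundance and log2-transformed;
#' the per-gene values are then averaged over the condition's replicates:
#' `Log2expr_i = mean_s log2( (1 + expr_si) / sum_j (1 + expr_sj) )`.
#' This is the within-condition half of a log2 fold-change and makes values
#' comparable across studies. The `"outside"` variant places the pseudo-count
#' on the ratio instead: `log2(1 + expr_si / sum_j expr_sj)`.
#'
#' @param counts Genes x replicates numeric matrix for one condition.
#' @param variant `"inside"` (default) or `"outside"` pseudo-count placement.
#' @return Named numeric vector of per-gene log2 expression.
#' @export
log2_relative_expression <- function(counts, variant = c("inside", "outside")) {
  variant <- match.arg(variant)
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stopf("log2_relative_expression(): no replicates")
  per_rep <- apply(counts, 2, function(v) {
    if (all(is.na(v))) return(rep(NA_real_, length(v)))
    if (variant == "inside") {
      log2((1 + v) / sum(1 + v, na.rm = TRUE))
    } else {
      log2(1 + v / sum(v, na.rm = TRUE))
    }
  })
  per_rep <- matrix(per_rep, nrow = nrow(counts),
                    dimnames = dimnames(counts))
  all_na <- apply(per_rep, 2, function(v) all(is.na(v)))
  if (any(all_na)) {
    warnf("dropping %d all-missing replicate(s)", sum(all_na))
    per_rep <- per_rep[, !all_na, drop = FALSE]
  }
  if (ncol(per_rep) == 0L) stopf("log2_relative_expression(): empty condition")
  rowMeans(per_rep, na.rm = TRUE)
}

#' Convert values to average-rank quantiles
#'
#' `quantile_i = rank_i / (N + 1)` with average ranks for ties; strictly
#' monotone in the input up to ties and bounded away from 0 and 1.
#'
#' @param x Numeric vector (NAs propagate).
#' @return Numeric vector of quantiles in (0, 1).
#' @export
to_quantiles <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) stopf("to_quantiles(): need at least 2 values")
  rank(x, ties.method = "average", na.last = "keep") / (n + 1)
}

#' Normalize an expression matrix across conditions
#'
#' Applies [log2_relative_expression()] per condition and converts the
#' per-condition values to quantiles. Replicates whose fraction of zero
#' quantifications exceeds `max_zero_frac` are dropped beforehand (the
#' published analysis excluded a study with only 8\% nonzero
#' quantifications).
#'
#' @param em [expression_matrix()] object.
#' @param variant Pseudo-count placement, see [log2_relative_expression()].
#' @param max_zero_frac Replicates with a zero fraction above this are
#'   dropped with a warning (default 0.9).
#' @return `data.frame` with columns `gene_id`, `strain`, `condition`,
#'   `log2expr`, `quantile`.
#' @export
normalize_expression <- function(em, variant = c("inside", "outside"),
                                 max_zero_frac = 0.9) {
  variant <- match.arg(variant)
  stopifnot(inherits(em, "expression_matrix"))
  zero_frac <- colMeans(em$counts == 0, na.rm = TRUE)
  drop <- zero_frac > max_zero_frac
  if (any(drop)) {
    warnf("dropping %d replicate(s) with > %d%% zero quantifications: %s",
          sum(drop), round(100 * max_zero_frac),
          paste(em$design$replicate[drop], collapse = ", "))
    em <- expression_matrix(em$counts[, !drop, drop = FALSE],
                            em$design[!drop, , drop = FALSE])
  }
  conds <- unique(em$design[, c("strain", "condition")])
  out <- lapply(seq_len(nrow(conds)), function(k) {
    sel <- em$design$strain == conds$strain[k] &
      em$design$condition == conds$condition[k]
    if (!any(sel)) return(NULL)
    le <- log2_relative_expression(em$counts[, sel, drop = FALSE], variant)
    data.frame(gene_id = rownames(em$counts),
               strain = conds$strain[k],
               condition = conds$condition[k],
               log2expr = unname(le),
               quantile = unname(to_quantiles(le)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract the focal gene's normalized expression per condition
#'
#' Returns the per-condition quantile-normalized log2 expression of a named
#' gene (in the motivating study, the *midA* methyltransferase); the
#' modulation analysis uses these values as its predictor.
#'
#' @param normalized Output of [normalize_expression()].
#' @param mida_id Gene id of the focal gene.
#' @return `data.frame` with `strain`, `condition`, `log2expr`, `quantile`,
#'   plus attribute `"constant"` flagging zero variance across conditions.
#' @export
mida_expression <- function(normalized, mida_id) {
  rows <- normalized[normalized$gene_id == mida_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stopf("mida_expression(): gene '%s' absent from normalized table", mida_id)
  out <- rows[, c("strain", "condition", "log2expr", "quantile")]
  rownames(out) <- NULL
  constant <- stats::var(out$quantile) < .Machine$double.eps
  if (isTRUE(constant))
    warnf("midA expression constant across conditions; modulation analysis unidentifiable")
  attr(out, "constant") <- isTRUE(constant)
  out
}
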