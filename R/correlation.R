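# Per-sample Spearman correlation between composition parameters and
# normalized expression, with per-strain Bonferroni correction.

comp_params <- function() c("pctA", "pctT", "pctG", "pctC",
                            "log10_length", "cbi", "nc")

#' Spearman correlation of composition parameters with expression, one sample
#'
#' For a single host-strain condition (sample), correlates each composition
#' parameter against the normalized expression of the same genes, using
#' rank-based Spearman correlation with average-rank ties and a two-sided
#' asymptotic p-value.
#'
#' @param profiles Composition profiles ([composition_profiles()]).
#' @param norm_sample `data.frame` with `gene_id` and `quantile` (or
#'   `log2expr`) for one condition.
#' @param strain,condition Labels carried into the output.
#' @param params Parameters to test (default: the seven composition
#'   parameters).
#' @param value_col Expression column to correlate against
#'   (default `"quantile"`; Spearman is invariant to this monotone choice).
#' @return `data.frame` of `CorrelationResult` rows: `strain`, `condition`,
#'   `parameter`, `rho`, `p`, `n_genes`. Constant inputs yield NA rho/p.
#' @export
correlate_sample <- function(profiles, norm_sample, strain, condition,
                             params = comp_params(),
                             value_col = "quantile") {
  merged <- merge(profiles, norm_sample[, c("gene_id", value_col)],
                  by = "gene_id")
  if (nrow(merged) < 10L)
    stopf("correlate_sample(): only %d genes with both profile and expression",
          nrow(merged))
  expr <- merged[[value_col]]
  rows <- lapply(params, function(p) {
    x <- merged[[p]]
    keep <- !is.na(x) & !is.na(expr)
    res <- if (sum(keep) < 3L ||
               length(unique(x[keep])) <= 1L ||
               length(unique(expr[keep])) <= 1L) {
      list(estimate = NA_real_, p.value = NA_real_)
    } else {
      suppressWarnings(stats::cor.test(x[keep], expr[keep],
                                       method = "spearman", exact = FALSE))
    }
    data.frame(strain = strain, condition = condition, parameter = p,
               rho = unname(res$estimate), p = res$p.value,
               n_genes = sum(keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate all samples of a normalized expression table
#'
#' Convenience wrapper running [correlate_sample()] over every
#' (strain, condition) present in the normalized table, then applying the
#' per-strain Bonferroni adjustment.
#'
#' @param profiles Composition profiles; when profiles carry a `genome_id`
#'   column and `strain_genome` is supplied, each strain is matched to its
#'   own genome's profiles.
#' @param normalized Output of [normalize_expression()].
#' @param strain_genome Optional named character vector strain -> genome_id.
#' @inheritParams correlate_sample
#' @return `data.frame` of correlation results with `p_adj`.
#' @export
correlate_samples <- function(profiles, normalized, strain_genome = NULL,
                              params = comp_params(),
                              value_col = "quantile") {
  conds <- unique(normalized[, c("strain", "condition")])
  rows <- lapply(seq_len(nrow(conds)), function(k) {
    st <- conds$strain[k]; cd <- conds$condition[k]
    prof <- profiles
    if (!is.null(strain_genome) && "genome_id" %in% names(profiles))
      prof <- profiles[profiles$genome_id == strain_genome[[st]], , drop = FALSE]
    sel <- normalized$strain == st & normalized$condition == cd
    correlate_sample(prof, normalized[sel, , drop = FALSE], st, cd,
                     params = params, value_col = value_col)
  })
  adjust_per_strain(do.call(rbind, rows))
}

#' Per-strain Bonferroni adjustment
#'
#' Within each strain, `p_adj = min(1, p * m)` where `m` is the number of
#' tests performed for that strain (parameters x samples), matching a
#' family defined per strain.
#'
#' @param results Correlation results with columns `strain` and `p`.
#' @return `results` with a `p_adj` column.
#' @export
adjust_per_strain <- function(results) {
  results$p_adj <- NA_real_
  for (st in unique(results$strain)) {
    sel <- results$strain == st
    # p.adjust() drops NAs from its n; the family size here is the number
    # of tests attempted in the strain, so scale explicitly.
    m <- sum(sel)
    results$p_adj[sel] <- pmin(1, results$p[sel] * m)
  }
  results
}

#' Significance summary per parameter
#'
#' Counts, for each composition parameter, in how many samples the
#' correlation was significant at `alpha`, and summarizes the rho
#' distribution (the tabular basis of the per-strain boxplot figures).
#'
#' @param results Correlation results (with `p_adj` if `use_adjusted`).
#' @param alpha Significance threshold (default 0.05).
#' @param use_adjusted Use the per-strain Bonferroni-adjusted p (default
#'   TRUE) or the raw p.
#' @return `data.frame` per parameter: `n_samples`, `n_significant`,
#'   `prop_significant`, `rho_min`, `rho_median`, `rho_max`.
#' @export
summarize_significance <- function(results, alpha = 0.05,
                                   use_adjusted = TRUE) {
  if (is.null(results) || nrow(results) == 0L)
    return(data.frame(parameter = character(0), n_samples = integer(0),
                      n_significant = integer(0),
                      prop_significant = numeric(0), rho_min = numeric(0),
                      rho_median = numeric(0), rho_max = numeric(0)))
  pcol <- if (use_adjusted) "p_adj" else "p"
  out <- lapply(split(results, results$parameter), function(d) {
    sig <- !is.na(d[[pcol]]) & d[[pcol]] < alpha
    data.frame(parameter = d$parameter[1],
               n_samples = nrow(d),
               n_significant = sum(sig),
               prop_significant = mean(sig),
               rho_min = suppressWarnings(min(d$rho, na.rm = TRUE)),
               rho_median = stats::median(d$rho, na.rm = TRUE),
               rho_max = suppressWarnings(max(d$rho, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
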