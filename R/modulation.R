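# Does midA expression modulate the composition-expression correlations?
# GAMM of per-sample Spearman rho on midA expression with a strain random
# intercept, BH correction over the parameter family, and the
# co-expression/PCA characterization of midA's expression pattern.

#' Join per-sample correlations with midA expression
#'
#' Builds one point per (strain, condition): the sample's Spearman rho for
#' each composition parameter together with the sample's quantile-normalized
#' log2 midA expression.
#'
#' @param results Correlation results ([correlate_samples()]).
#' @param mida Per-condition midA expression ([mida_expression()]).
#' @return `data.frame` with `strain`, `condition`, `mida_expr`, `parameter`,
#'   `rho`; samples missing either side are dropped with a warning.
#' @export
build_sample_points <- function(results, mida) {
  pts <- merge(results[, c("strain", "condition", "parameter", "rho")],
               mida[, c("strain", "condition", "quantile")],
               by = c("strain", "condition"))
  names(pts)[names(pts) == "quantile"] <- "mida_expr"
  n_samples_in <- nrow(unique(results[, c("strain", "condition")]))
  n_samples_out <- nrow(unique(pts[, c("strain", "condition")]))
  if (n_samples_out < n_samples_in)
    warnf("%d sample(s) missing midA expression; dropped",
          n_samples_in - n_samples_out)
  pts[order(pts$parameter, pts$strain, pts$condition), ]
}

#' GAMM test of midA modulation for one parameter
#'
#' Fits `rho ~ s(mida_expr) + s(strain, bs = "re")` by REML (penalized
#' spline smooth, random strain intercept) and reports the smooth-term
#' p-value and the direction of the fitted trend over the observed midA
#' range. With a single strain the random intercept is dropped (logged
#' downgrade to a fixed-intercept additive model).
#'
#' @param points Output of [build_sample_points()].
#' @param parameter Composition parameter to test.
#' @param k Smooth basis dimension (default 5).
#' @return One-row `data.frame` (`ModulationResult`): `parameter`,
#'   `p_smooth`, `edf`, `direction` (increasing/decreasing/flat from the
#'   fitted difference between the max and min observed `mida_expr`,
#'   |difference| < 1e-3 counts as flat).
#' @export
fit_modulation <- function(points, parameter, k = 5) {
  d <- points[points$parameter == parameter & !is.na(points$rho), ,
              drop = FALSE]
  if (nrow(d) < 8L)
    stopf("fit_modulation(%s): only %d points (need >= 8)", parameter,
          nrow(d))
  d$strain <- factor(d$strain)
  if (stats::var(d$rho) < .Machine$double.eps) {
    return(data.frame(parameter = parameter, p_smooth = NA_real_,
                      edf = 0, direction = "flat",
                      stringsAsFactors = FALSE))
  }
  single_strain <- nlevels(d$strain) < 2L
  fit <- if (single_strain) {
    warnf("fit_modulation(%s): single strain; random intercept dropped",
          parameter)
    mgcv::gam(rho ~ s(mida_expr, k = k), data = d, method = "REML")
  } else {
    mgcv::gam(rho ~ s(mida_expr, k = k) + s(strain, bs = "re"),
              data = d, method = "REML")
  }
  st <- summary(fit)$s.table
  p_smooth <- st["s(mida_expr)", "p-value"]
  edf <- st["s(mida_expr)", "edf"]
  nd <- data.frame(mida_expr = range(d$mida_expr),
                   strain = d$strain[1])
  pred <- if (single_strain) {
    stats::predict(fit, newdata = nd)
  } else {
    stats::predict(fit, newdata = nd, exclude = "s(strain)")
  }
  delta <- pred[2] - pred[1]
  direction <- if (abs(delta) < 1e-3) "flat" else
    if (delta > 0) "increasing" else "decreasing"
  data.frame(parameter = parameter, p_smooth = unname(p_smooth),
             edf = unname(edf), direction = direction,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment over the parameter family
#'
#' @param results Rows from [fit_modulation()] (one per parameter).
#' @return `results` with a `p_bh` column (standard step-up BH).
#' @export
adjust_bh <- function(results) {
  if (nrow(results) == 0L) stopf("adjust_bh(): no results")
  results$p_bh <- stats::p.adjust(results$p_smooth, method = "BH")
  results
}

#' Fit the modulation model for every parameter
#'
#' @param points Output of [build_sample_points()].
#' @param params Parameters to test (default: all present).
#' @param k Smooth basis dimension.
#' @return `data.frame` of modulation results with `p_bh`.
#' @export
fit_modulation_all <- function(points, params = unique(points$parameter),
                               k = 5) {
  res <- do.call(rbind, lapply(params, function(p)
    fit_modulation(points, p, k = k)))
  adjust_bh(res)
}

#' Co-expression profile and PCA of core genes
#'
#' Pairwise Spearman co-correlation among gene expression patterns across
#' samples, PCA of the sample x gene matrix (centered, unscaled), and a
#' summary of the focal gene's pairwise correlations (used to ask whether
#' any other gene shares midA's expression pattern).
#'
#' @param normalized Output of [normalize_expression()].
#' @param genes Core gene ids to include (default: all).
#' @param mida_id Focal gene id for the summary (optional).
#' @param value_col Expression column (default `"quantile"`).
#' @return List with `cor_matrix` (genes x genes Spearman), `pca`
#'   (`prcomp` object on samples x genes), and `mida_summary`
#'   (max/min/median pairwise rho with the focal gene, and its nearest
#'   neighbour), or NULL when `mida_id` is not given.
#' @export
coexpression_profile <- function(normalized, genes = NULL, mida_id = NULL,
                                 value_col = "quantile") {
  wide <- stats::reshape(
    normalized[, c("gene_id", "strain", "condition", value_col)],
    idvar = c("strain", "condition"), timevar = "gene_id",
    direction = "wide")
  mat <- as.matrix(wide[, -(1:2), drop = FALSE])
  colnames(mat) <- sub(paste0("^", value_col, "\\."), "", colnames(mat))
  if (!is.null(genes)) mat <- mat[, colnames(mat) %in% genes, drop = FALSE]
  if (ncol(mat) < 3L || nrow(mat) < 3L)
    stopf("coexpression_profile(): need >= 3 genes and >= 3 samples")
  constant <- apply(mat, 2, function(v) stats::var(v, na.rm = TRUE)) <
    .Machine$double.eps
  if (any(constant)) {
    warnf("dropping %d constant gene(s) before PCA", sum(constant))
    mat <- mat[, !constant, drop = FALSE]
  }
  cm <- suppressWarnings(
    stats::cor(mat, method = "spearman", use = "pairwise.complete.obs"))
  pca <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  mida_summary <- NULL
  if (!is.null(mida_id)) {
    if (!mida_id %in% colnames(cm))
      stopf("coexpression_profile(): focal gene '%s' not in matrix", mida_id)
    v <- cm[mida_id, colnames(cm) != mida_id]
    mida_summary <- data.frame(
      rho_max = max(v), rho_min = min(v), rho_median = stats::median(v),
      nearest_gene = names(v)[which.max(abs(v))],
      stringsAsFactors = FALSE)
  }
  list(cor_matrix = cm, pca = pca, mida_summary = mida_summary)
}
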