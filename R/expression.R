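## Expression analysis: median-of-ratios normalization, pairwise
## differential expression under the fold-change/FDR contract, PCA variance
## shares, relative expression fractions and rank-based pathway enrichment.

#' Median-of-ratios normalization
#'
#' Estimates one size factor per sample as the median across features of the
#' ratio of the sample's count to the feature's geometric mean over all
#' samples (features with a zero in any sample are excluded from the
#' median). Falls back to total-count factors, with a warning, when no
#' feature is nonzero in every sample.
#'
#' @param mat Non-negative count matrix, features x samples.
#' @return List with `size_factors` (positive, named by sample) and
#'   `normalized` (counts divided by their size factor).
#' @export
normalize_counts <- function(mat) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  log_geo <- rowMeans(log(mat))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    warning("no feature with nonzero counts in all samples; ",
            "falling back to total-count size factors")
    totals <- colSums(mat)
    sf <- totals / exp(mean(log(totals)))
  } else {
    sf <- apply(mat[usable, , drop = FALSE], 2, function(col) {
      exp(median(log(col) - log_geo[usable]))
    })
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("normalize_counts: non-positive size factor")
  }
  list(size_factors = sf,
       normalized = sweep(mat, 2, sf, "/"))
}

## Row-wise Welch t-test on a matrix, comparing column groups a and b.
## Returns two-sided p-values; features with zero variance in both groups
## get p = 1.
welch_rowwise <- function(x, a, b) {
  na <- length(a); nb <- length(b)
  ma <- rowMeans(x[, a, drop = FALSE])
  mb <- rowMeans(x[, b, drop = FALSE])
  va <- apply(x[, a, drop = FALSE], 1, var)
  vb <- apply(x[, b, drop = FALSE], 1, var)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tt), df)
  p[va == 0 & vb == 0] <- 1
  p[is.na(p)] <- 1
  p
}

#' Pairwise differential expression between two stages
#'
#' Tests each feature two-sided on `log2(normalized count + 1)` between the
#' two stage groups, corrects p-values by Benjamini-Hochberg within the
#' contrast, and computes the fold change from stage means of normalized
#' counts with a pseudocount of 1. A feature is significant when its fold
#' change is strictly greater than 2 in either direction and its FDR is
#' strictly below 0.05.
#'
#' The default test is the variance-moderated (empirical Bayes) t-test with
#' a mean-variance trend, which pools variance information across features;
#' with 2-3 replicates per stage a per-feature variance estimate is too
#' noisy to be useful, and moderation restores power while keeping the null
#' calibrated. A plain Welch t-test is available via `method = "welch"`.
#'
#' @param mat Count matrix, features x samples.
#' @param design Data frame with `sample_id` and `stage` covering the
#'   columns of `mat`.
#' @param stage_a,stage_b Stage labels to contrast; positive log2 fold
#'   changes mean higher expression in `stage_b`.
#' @param fc_cutoff,fdr_cutoff Significance contract (strict inequalities).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return Data frame with `feature_id`, `log2_fc`, `p_value`, `fdr`,
#'   `significant`.
#' @export
differential_expression <- function(mat, design, stage_a, stage_b,
                                    fc_cutoff = 2, fdr_cutoff = 0.05,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(all(design$sample_id %in% colnames(mat)))
  a <- design$sample_id[design$stage == stage_a]
  b <- design$sample_id[design$stage == stage_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("differential_expression: need >= 2 samples per stage")
  }
  norm <- normalize_counts(mat)$normalized
  x <- log2(norm + 1)
  if (method == "moderated") {
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))),
                  levels = c("a", "b"))
    fit <- limma::lmFit(x[, c(a, b), drop = FALSE],
                        stats::model.matrix(~grp))
    ## zero-variance features are handled by the contract below (p = 1), so
    ## limma's offset notice about them is redundant here
    fit <- withCallingHandlers(
      limma::eBayes(fit, trend = nrow(x) >= 10),
      warning = function(w) {
        if (grepl("Zero sample variances", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    p <- fit$p.value[, 2]
    zero_var <- apply(x[, c(a, b), drop = FALSE], 1, var) == 0
    p[zero_var] <- 1
  } else {
    p <- welch_rowwise(x, match(a, colnames(mat)), match(b, colnames(mat)))
  }
  mean_a <- rowMeans(norm[, a, drop = FALSE])
  mean_b <- rowMeans(norm[, b, drop = FALSE])
  log2_fc <- log2(mean_b + 1) - log2(mean_a + 1)
  fdr <- p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(mat), log2_fc = log2_fc, p_value = p,
             fdr = fdr,
             significant = abs(log2_fc) > log2(fc_cutoff) & fdr < fdr_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal component analysis of samples
#'
#' PCA on `log2(normalized count + 1)` with samples as observations
#' (features as variables, mean-centered). Variance fractions are
#' non-increasing and sum to 1 over all components.
#'
#' @param mat Count matrix, features x samples.
#' @param design Optional design data frame (`sample_id`, `stage`) used to
#'   annotate the coordinates.
#' @return List with `coordinates` (samples x components) and
#'   `variance_fraction`.
#' @export
pca_variance <- function(mat, design = NULL) {
  if (ncol(mat) < 3) stop("pca_variance: need >= 3 samples")
  x <- t(log2(normalize_counts(mat)$normalized + 1))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- pc$x
  if (!is.null(design)) {
    stopifnot(all(rownames(coords) %in% design$sample_id))
  }
  list(coordinates = coords, variance_fraction = frac)
}

#' Relative expression fraction per stage
#'
#' For each stage, each feature's fraction of the stage's total normalized
#' expression (fractions sum to 1 within a stage). Stages with zero total
#' are flagged and returned as `NA`.
#'
#' @param mat Count matrix, features x samples.
#' @param design Data frame with `sample_id` and `stage`.
#' @return Matrix, features x stages, of expression fractions; attribute
#'   `flagged_stages` lists all-zero stages.
#' @export
relative_expression_fraction <- function(mat, design) {
  norm <- normalize_counts(mat)$normalized
  stages <- unique(design$stage)
  out <- vapply(stages, function(s) {
    cols <- design$sample_id[design$stage == s]
    tot <- rowSums(norm[, cols, drop = FALSE])
    if (sum(tot) == 0) return(rep(NA_real_, nrow(mat)))
    tot / sum(tot)
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), stages))
  attr(out, "flagged_stages") <- stages[colSums(is.na(out)) > 0]
  out
}

#' Cumulative expression share of the top features
#'
#' Ranks features by their mean fraction across stages and reports the
#' cumulative share of the top `k` within each stage.
#'
#' @param fractions Output of [relative_expression_fraction()].
#' @param k Number of top features.
#' @return Named numeric vector of per-stage cumulative shares of the top
#'   `k` features, with the selected feature ids as attribute `features`.
#' @export
top_expression_share <- function(fractions, k) {
  ord <- order(rowMeans(fractions, na.rm = TRUE), decreasing = TRUE)
  top <- rownames(fractions)[ord[seq_len(min(k, nrow(fractions)))]]
  share <- colSums(fractions[top, , drop = FALSE])
  attr(share, "features") <- top
  share
}

#' Rank-based pathway enrichment
#'
#' For each pathway, compares the member features' p-values against all
#' non-member p-values with a two-sample Wilcoxon rank-sum test
#' (one-sided: members shifted toward smaller p-values). Pathways without
#' at least one member and one non-member are skipped with a warning.
#'
#' @param feature_pvalues Named numeric vector of per-feature p-values.
#' @param pathway_membership Data frame with `pathway_id`, `feature_id`.
#' @return Data frame with `pathway_id`, `n_members`, `p_value`.
#' @export
pathway_rank_enrichment <- function(feature_pvalues, pathway_membership) {
  ids <- names(feature_pvalues)
  pathways <- unique(pathway_membership$pathway_id)
  rows <- lapply(pathways, function(pw) {
    members <- intersect(
      pathway_membership$feature_id[pathway_membership$pathway_id == pw], ids)
    rest <- setdiff(ids, members)
    if (length(members) == 0 || length(rest) == 0) {
      warning("pathway ", pw, " skipped: needs >= 1 member and >= 1 non-member")
      return(NULL)
    }
    xm <- feature_pvalues[members]
    xr <- feature_pvalues[rest]
    ## exact null distribution when feasible and untied, else the normal
    ## approximation with continuity correction
    use_exact <- length(xm) * length(xr) <= 20000 &&
      !anyDuplicated(c(xm, xr))
    p <- suppressWarnings(
      wilcox.test(xm, xr, alternative = "less", exact = use_exact))$p.value
    data.frame(pathway_id = pw, n_members = length(members), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway_id = character(0), n_members = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  }
  out
}
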