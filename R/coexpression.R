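## Co-expression analysis: correlation-based module detection with
## type-specific minimum module sizes, module eigengenes, and module-trait
## (stage) correlation.

#' Minimum module size by feature kind
#'
#' The analysis uses kind-specific minimum module sizes: 300 loci for
#' hc-siRNA, 10 for microRNA, 30 for lncRNA.
#'
#' @param kind One of `"hc-siRNA"`, `"miRNA"`, `"lncRNA"`.
#' @return Integer minimum module size.
#' @export
min_module_size <- function(kind = c("hc-siRNA", "miRNA", "lncRNA")) {
  kind <- match.arg(kind)
  c(`hc-siRNA` = 300L, miRNA = 10L, lncRNA = 30L)[[kind]]
}

#' Detect co-expression modules
#'
#' Clusters features by signed Pearson correlation distance (`1 - r`) with
#' average-linkage hierarchical clustering and a static tree cut at
#' `cut_height`. Clusters smaller than `min_size` are merged into the
#' unassigned pool, module 0; surviving modules are renumbered by size,
#' largest first. Constant-expression features go to module 0 with a
#' warning. The procedure is deterministic.
#'
#' @param x Numeric expression matrix (e.g. log2 normalized counts),
#'   features x samples.
#' @param min_size Minimum module size (see [min_module_size()]).
#' @param cut_height Static tree cut height on the `1 - r` dendrogram.
#' @return Named integer vector: module id per feature (0 = unassigned).
#' @export
detect_modules <- function(x, min_size, cut_height = 0.25) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2 * min_size) {
    stop("detect_modules: need at least 2 * min_size features")
  }
  sds <- apply(x, 1, sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warning(sum(constant), " constant-expression feature(s) assigned to module 0")
  }
  module <- setNames(rep(0L, nrow(x)), rownames(x))
  active <- which(!constant)
  if (length(active) >= 2) {
    r <- cor(t(x[active, , drop = FALSE]))
    cl <- cutree(hclust(as.dist(1 - r), method = "average"), h = cut_height)
    sizes <- table(cl)
    keep <- names(sizes)[sizes >= min_size]
    if (length(keep) > 0) {
      keep <- keep[order(-sizes[keep], as.integer(keep))]
      for (k in seq_along(keep)) {
        module[active[cl == as.integer(keep[k])]] <- k
      }
    }
  }
  module
}

#' Compute a module eigengene
#'
#' The eigengene is the first principal component of the module's
#' feature-standardized expression submatrix across samples: a unit-norm
#' per-sample score vector, with its sign fixed so that it correlates
#' non-negatively with the module's mean standardized profile. The variance
#' share is the fraction of the submatrix variance the component explains.
#'
#' @param x Expression matrix, features x samples.
#' @param members Feature ids (or indices) of the module.
#' @return List with `score` (named per-sample vector, unit norm) and
#'   `variance_share`.
#' @export
compute_eigengene <- function(x, members) {
  sub <- x[members, , drop = FALSE]
  if (nrow(sub) == 0) stop("compute_eigengene: empty module")
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0) stop("compute_eigengene: all features constant")
    sds <- sds[sds > 0]
  }
  z <- (sub - rowMeans(sub)) / sds
  if (nrow(z) == 1) {
    score <- as.numeric(z) / sqrt(sum(z^2))
    names(score) <- colnames(x)
    return(list(score = score, variance_share = 1))
  }
  dec <- svd(z)
  score <- dec$v[, 1]
  mean_profile <- colMeans(z)
  if (cor(score, mean_profile) < 0) score <- -score
  names(score) <- colnames(x)
  list(score = score, variance_share = dec$d[1]^2 / sum(dec$d^2))
}

#' Correlate module eigengenes with stage indicators
#'
#' Pearson correlation of each eigengene with each stage's one-hot sample
#' indicator. High positive correlation means the module is expressed at
#' that stage.
#'
#' @param eigengenes Matrix (modules x samples) or a list of eigengene
#'   score vectors.
#' @param design Data frame with `sample_id` and `stage` covering all
#'   samples.
#' @return Matrix of correlations, modules x stages.
#' @export
module_trait_correlation <- function(eigengenes, design) {
  if (is.list(eigengenes) && !is.matrix(eigengenes)) {
    eigengenes <- do.call(rbind, eigengenes)
  }
  stages <- unique(design$stage)
  if (length(stages) < 2) {
    stop("module_trait_correlation: need >= 2 stages")
  }
  samples <- colnames(eigengenes)
  if (is.null(samples)) {
    stop("module_trait_correlation: eigengenes need sample column names")
  }
  stopifnot(all(samples %in% design$sample_id))
  stage_of <- design$stage[match(samples, design$sample_id)]
  indicators <- sapply(stages, function(s) as.numeric(stage_of == s))
  out <- cor(t(eigengenes), indicators)
  rownames(out) <- rownames(eigengenes)
  out
}
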