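test_that("median-of-ratios factors undo exact scaling", {
  set.seed(3)
  base <- matrix(rpois(200 * 2, 50), 200, 2)
  mat <- cbind(base[, 1], base[, 1] * 2L)
  colnames(mat) <- c("s1", "s2")
  out <- normalize_counts(mat)
  expect_equal(unname(out$size_factors[2] / out$size_factors[1]), 2)
  expect_equal(out$normalized[, 1], out$normalized[, 2],
               ignore_attr = TRUE)
  same <- cbind(base[, 1], base[, 1])
  colnames(same) <- c("s1", "s2")
  expect_equal(unname(normalize_counts(same)$size_factors), c(1, 1))
})

test_that("size factors recover known depths and match the DESeq2 estimator", {
  cfg <- synthetic_config(seed = 6, planted_de_fraction = 0, planted_fc = 1)
  depth <- rep(c(0.5, 1, 2), length.out = 14)
  cnt <- generate_counts(cfg, sprintf("f%04d", 1:2000), n_modules = 0,
                         depth_factors = depth)
  sf <- normalize_counts(cnt$counts)$size_factors
  rel <- sf / exp(mean(log(sf)))
  target <- depth / exp(mean(log(depth)))
  expect_true(all(abs(rel / target - 1) < 0.05))
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt$counts)
  expect_equal(unname(sf / exp(mean(log(sf)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-8)
})

test_that("all-zero-feature matrices fall back to total-count factors", {
  mat <- matrix(c(5L, 0L, 0L, 10L), 2, 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_warning(out <- normalize_counts(mat), "total-count")
  expect_true(all(out$size_factors > 0))
})

test_that("differential expression honours the strict fold-change contract", {
  ## stable features make all size factors 1; the contract feature has
  ## (mean_b + 1) exactly = 2 * (mean_a + 1), i.e. fold change exactly 2
  set.seed(9)
  filler <- matrix(rep(c(40L, 60L, 80L, 100L), each = 4), 4, 4, byrow = TRUE)
  mat <- rbind(filler, c(3L, 5L, 8L, 10L))
  dimnames(mat) <- list(paste0("f", 1:5),
                        c("A_R1", "A_R2", "B_R1", "B_R2"))
  design <- data.frame(sample_id = colnames(mat),
                       stage = c("A", "A", "B", "B"), replicate = c(1, 2, 1, 2))
  de <- differential_expression(mat, design, "A", "B")
  expect_equal(de$log2_fc[5], 1)
  expect_false(de$significant[5])
  ## zero variance in both groups gives p = 1
  expect_equal(de$p_value[1], 1)
})

test_that("swapping the contrast negates fold changes and keeps p-values", {
  cfg <- synthetic_config(seed = 14)
  cnt <- generate_counts(cfg, sprintf("f%03d", 1:500), n_modules = 0)
  d1 <- differential_expression(cnt$counts, cnt$design, "T1", "D3")
  d2 <- differential_expression(cnt$counts, cnt$design, "D3", "T1")
  expect_equal(d1$log2_fc, -d2$log2_fc)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
  expect_error(differential_expression(cnt$counts, cnt$design, "T1", "XX"),
               ">= 2 samples")
})

test_that("planted 4-fold effects are recovered with controlled FDP", {
  rec <- fdp <- numeric(5)
  for (i in 1:5) {
    cfg <- synthetic_config(seed = 100 + i)
    cnt <- generate_counts(cfg, sprintf("f%04d", 1:2000), n_modules = 0,
                           de_stages = "D3")
    de <- differential_expression(cnt$counts, cnt$design, "T1", "D3")
    sig <- de$feature_id[de$significant]
    planted <- cnt$truth$de$feature_id
    rec[i] <- mean(planted %in% sig)
    fdp[i] <- if (length(sig)) mean(!sig %in% planted) else 0
  }
  expect_gte(mean(rec), 0.9)
  expect_lte(mean(fdp), 0.1)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  set.seed(21)
  for (m in c(10, 500, 5000)) {
    p <- runif(m)^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("PCA variance fractions match a dense eigendecomposition", {
  cfg <- synthetic_config(seed = 25)
  cnt <- generate_counts(cfg, sprintf("f%03d", 1:300))
  pv <- pca_variance(cnt$counts, cnt$design)
  expect_equal(sum(pv$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(pv$variance_fraction) <= 1e-12))
  x <- t(log2(normalize_counts(cnt$counts)$normalized + 1))
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(xc %*% t(xc) / (nrow(x) - 1), symmetric = TRUE)$values
  ev <- ev[seq_along(pv$variance_fraction)]
  expect_equal(pv$variance_fraction, ev / sum(ev), tolerance = 1e-8)
  ## rank-1 log expression (feature-specific loadings on one profile)
  ## concentrates essentially all variance on PC1
  load <- seq(7, 9, length.out = 50)
  t_s <- seq(1, 1.5, length.out = 14)
  m2 <- round(2^outer(load, t_s))
  dimnames(m2) <- list(paste0("g", 1:50), colnames(cnt$counts))
  pv2 <- pca_variance(m2)
  expect_gt(pv2$variance_fraction[1], 0.99)
  expect_error(pca_variance(m2[, 1:2]), ">= 3 samples")
})

test_that("PCA is invariant to feature order and sample relabeling", {
  cfg <- synthetic_config(seed = 26)
  cnt <- generate_counts(cfg, sprintf("f%03d", 1:200))
  pv <- pca_variance(cnt$counts)
  shuf <- cnt$counts[sample(nrow(cnt$counts)), ]
  pv2 <- pca_variance(shuf)
  expect_equal(pv$variance_fraction, pv2$variance_fraction, tolerance = 1e-9)
})

test_that("relative expression fractions are column-normalized sums", {
  cfg <- synthetic_config(seed = 33)
  cnt <- generate_counts(cfg, sprintf("f%02d", 1:50), n_modules = 0)
  fr <- relative_expression_fraction(cnt$counts, cnt$design)
  expect_equal(unname(colSums(fr)), rep(1, 5), tolerance = 1e-12)
  norm <- normalize_counts(cnt$counts)$normalized
  for (s in unique(cnt$design$stage)) {
    cols <- cnt$design$sample_id[cnt$design$stage == s]
    manual <- rowSums(norm[, cols, drop = FALSE])
    manual <- manual / sum(manual)
    expect_equal(fr[, s], manual, tolerance = 1e-12)
  }
  ## single feature takes the whole share; top-k share is cumulative
  single <- cnt$counts[1, , drop = FALSE]
  fr1 <- relative_expression_fraction(single, cnt$design)
  expect_true(all(fr1 == 1))
  top <- top_expression_share(fr, 5)
  expect_true(all(top <= 1 & top >= 0))
  expect_length(attr(top, "features"), 5)
})

test_that("rank-sum pathway enrichment matches the exact extreme tail", {
  p <- c(sort(runif(10, 0, 1e-4)), runif(100, 0.2, 1))
  names(p) <- paste0("g", seq_along(p))
  member <- data.frame(pathway_id = "pw1", feature_id = paste0("g", 1:10))
  out <- pathway_rank_enrichment(p, member)
  expect_equal(out$p_value, 1 / choose(110, 10), tolerance = 1e-12)
  ## degenerate pathway covering every feature is skipped
  allpw <- data.frame(pathway_id = "all", feature_id = names(p))
  expect_warning(res <- pathway_rank_enrichment(p, allpw), "skipped")
  expect_identical(nrow(res), 0L)
})

test_that("enrichment p-values are calibrated for random member sets", {
  set.seed(55)
  p <- runif(200)
  names(p) <- paste0("g", 1:200)
  pvals <- replicate(300, {
    mem <- data.frame(pathway_id = "pw",
                      feature_id = sample(names(p), 15))
    suppressWarnings(pathway_rank_enrichment(p, mem)$p_value)
  })
  expect_gt(mean(pvals < 0.1), 0.05)
  expect_lt(mean(pvals < 0.1), 0.17)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})
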