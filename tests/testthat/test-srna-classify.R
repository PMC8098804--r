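test_that("read length filter keeps the inclusive 18-30 nt window", {
  expect_identical(filter_reads_by_length(c(17L, 18L, 24L, 30L, 31L)),
                   c(18L, 24L, 30L))
  expect_error(filter_reads_by_length(20L, min_len = 25, max_len = 20),
               "min_len")
  set.seed(4)
  lens <- sample(10:40, 1000, replace = TRUE)
  kept <- filter_reads_by_length(lens)
  brute <- lens[sapply(lens, function(l) l >= 18 && l <= 30)]
  expect_identical(kept, brute)
})

test_that("fuzzy reference matcher honours the mismatch/coverage contract", {
  set.seed(7)
  ref <- random_seq(150)
  q <- substr(ref, 40, 63)
  expect_true(matches_reference(q, ref))
  mm2 <- q
  substr(mm2, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(q, 3, 3))[1]
  substr(mm2, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(q, 10, 10))[1]
  expect_true(matches_reference(mm2, ref))
  mm3 <- mm2
  substr(mm3, 17, 17) <- setdiff(c("A", "C", "G", "T"), substr(q, 17, 17))[1]
  expect_false(matches_reference(mm3, ref))
  ## Edge trimming: 10% of the query may overhang the reference end.
  edge <- paste0(substr(ref, 1, 22), "GG")
  expect_true(matches_reference(edge, ref))
})

test_that("matcher agrees with an exhaustive subquery/offset oracle", {
  set.seed(19)
  oracle_match <- function(q, ref, max_mm = 2, min_cov = 0.9) {
    L <- nchar(q)
    minL <- ceiling(min_cov * L)
    for (len in minL:L) {
      for (qs in 1:(L - len + 1)) {
        sub <- substr(q, qs, qs + len - 1)
        if (nchar(ref) < len) next
        for (o in 1:(nchar(ref) - len + 1)) {
          w <- substr(ref, o, o + len - 1)
          mm <- sum(strsplit(sub, "")[[1]] != strsplit(w, "")[[1]])
          if (mm <= max_mm) return(TRUE)
        }
      }
    }
    FALSE
  }
  ref <- random_seq(60)
  hits <- 0
  for (i in 1:40) {
    q <- if (i %% 2 == 0) {
      random_seq(sample(18:24, 1))
    } else {
      ## near-copies with 0-4 random substitutions
      s <- sample.int(38, 1)
      qq <- substr(ref, s, s + 21)
      n_mut <- sample(0:4, 1)
      for (pos in sample(22, n_mut)) {
        substr(qq, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      }
      qq
    }
    got <- matches_reference(q, ref)
    expect_identical(got, oracle_match(q, ref), info = paste("case", i))
    hits <- hits + got
  }
  expect_gt(hits, 0)
})

test_that("classification cascade applies precedence, size rule and errors", {
  refs <- list(rRNA = c(r1 = random_seq(100)),
               tRNA = c(t1 = random_seq(80)),
               snRNA = c(s1 = random_seq(90)),
               miRNA = c(m1 = random_seq(90)),
               `ta-siRNA` = c(ta1 = random_seq(90)))
  shared <- substr(refs$rRNA[[1]], 10, 33)
  refs$tRNA <- c(t1 = paste0(shared, random_seq(40)))
  mk <- function(seqs) {
    data.frame(id = paste0("x", seq_along(seqs)), major_rna_seq = seqs,
               major_rna_len = nchar(seqs), stringsAsFactors = FALSE)
  }
  ## present in both rRNA and tRNA references: precedence gives rRNA
  out <- classify_loci(mk(shared), refs)
  expect_identical(out$class_label, "rRNA")
  ## no reference match
  set.seed(33)
  out <- classify_loci(mk(c(random_seq(24), random_seq(19))), refs)
  expect_identical(out$class_label, c("siRNA", "other"))
  expect_error(classify_loci(mk(""), refs), "empty major RNA")
})

test_that("genomic origin equals the quadratic overlap oracle", {
  set.seed(11)
  loci <- random_loci(500)
  genes <- random_loci(40)
  names(genes)[1] <- "gene_id"
  genes$gene_id <- sub("^L", "G", genes$gene_id)
  repeats <- random_loci(40)
  got <- assign_genomic_origin(loci, genes, repeats)$origin
  expect_identical(got, oracle_origin(loci, genes, repeats))
  fracs <- table(factor(got, c("repeat", "gene", "intergenic"))) / nrow(loci)
  expect_equal(sum(fracs), 1)
})

test_that("loci on unannotated chromosomes fall back to intergenic", {
  loci <- data.frame(id = "x", chrom = "ChrZ", start = 0L, end = 100L,
                     strand = "+")
  genes <- data.frame(gene_id = "g", chrom = "Chr1", start = 0L, end = 10L,
                      strand = "+")
  repeats <- genes[0, c("chrom", "start", "end")]
  expect_warning(out <- assign_genomic_origin(loci, genes, repeats),
                 "absent")
  expect_identical(out$origin, "intergenic")
})

test_that("hc-siRNA calling is the conjunction of the three criteria", {
  base <- data.frame(id = c("a", "b", "c", "d"),
                     class_label = c("siRNA", "siRNA", "miRNA", "siRNA"),
                     origin = c("repeat", "repeat", "repeat", "gene"),
                     major_rna_len = c(24L, 21L, 24L, 24L))
  out <- call_hc_sirna(base)
  expect_identical(out$is_hc_sirna, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("class-by-size summary equals a nested-loop tally", {
  set.seed(8)
  n <- 300L
  loci <- data.frame(
    id = paste0("l", 1:n),
    class_label = sample(c("rRNA", "tRNA", "snRNA", "miRNA", "ta-siRNA",
                           "siRNA", "other"), n, replace = TRUE),
    major_rna_len = sample(c(18:30), n, replace = TRUE))
  tab <- summarize_class_by_size(loci)
  expect_identical(tab$grand_total, n)
  for (cl in rownames(tab$counts)) {
    for (sz in colnames(tab$counts)) {
      manual <- 0L
      for (i in 1:n) {
        bin <- if (loci$major_rna_len[i] %in% 20:24)
          as.character(loci$major_rna_len[i]) else "other"
        if (loci$class_label[i] == cl && bin == sz) manual <- manual + 1L
      }
      expect_identical(tab$counts[cl, sz], manual)
    }
  }
  empty <- summarize_class_by_size(loci[0, ])
  expect_true(all(empty$counts == 0L))
})

test_that("novel microRNA post-filter applies all published rules strictly", {
  cand <- data.frame(
    id = c("keep", "score3", "known", "coding", "len20", "p05"),
    mature_len = c(21L, 21L, 22L, 21L, 20L, 22L),
    in_coding_region = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    randfold_p = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.05),
    mirdeep_score = c(5, 3, 5, 5, 5, 5),
    matches_known = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(novel_mirna_filter(cand)$id, "keep")
  expect_error(novel_mirna_filter(transform(cand, randfold_p = 2)),
               "randfold_p")
})

test_that("planted classes and hc-siRNAs are fully recovered on clean data", {
  cfg <- synthetic_config(seed = 23)
  ann <- generate_annotation(cfg)
  srna <- generate_srna_loci(cfg, ann)
  cls <- classify_srna_pipeline(srna$loci, ann$class_refs, ann$genes,
                                ann$repeats)
  expect_identical(setNames(cls$class_label, cls$id), srna$truth$class)
  expect_identical(setNames(cls$origin, cls$id), srna$truth$origin)
  expect_setequal(cls$id[cls$is_hc_sirna], srna$truth$hc_sirna_ids)
  ## hc-siRNAs are a subset of repeat-origin siRNA loci
  hc <- cls[cls$is_hc_sirna, ]
  expect_true(all(hc$class_label == "siRNA" & hc$origin == "repeat"))
})
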