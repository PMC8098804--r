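make_gene <- function(id, chrom, start, end, strand,
                      exon_bounds = list(c(start, end))) {
  genes <- data.frame(gene_id = id, chrom = chrom, start = start, end = end,
                      strand = strand, stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_along(exon_bounds), function(i) {
    data.frame(gene_id = id, exon_id = sprintf("%s.e%d", id, i),
               chrom = chrom, start = exon_bounds[[i]][1],
               end = exon_bounds[[i]][2], strand = strand,
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, exons = exons)
}

test_that("longest ORF length is computed per frame in codons", {
  ## ATG + 5 codons + stop in frame 1
  seq <- paste0("CC", "ATG", "AAACCCGGGTTTAAA", "TAA", "GG")
  expect_identical(longest_orf_codons(seq), 6L)
  expect_identical(longest_orf_codons("CCCCCCCCCC"), 0L)
  ## ORF without a stop runs to the last complete codon
  expect_identical(longest_orf_codons("ATGAAAAAA"), 3L)
  expect_error(longest_orf_codons(""), "missing")
})

test_that("lncRNA candidate filter applies length, ORF and sense-exon rules", {
  g <- make_gene("gA", "Chr1", 5000L, 8000L, "+")
  mk <- function(id, start, width, strand) {
    data.frame(id = id, chrom = "Chr1", start = start,
               end = start + width, strand = strand,
               stringsAsFactors = FALSE)
  }
  set.seed(5)
  tx <- rbind(mk("short", 100L, 150L, "+"),
              mk("ok", 1000L, 500L, "+"),
              mk("sense_ex", 5100L, 500L, "+"),
              mk("anti_ex", 5100L, 500L, "-"),
              mk("orfy", 2000L, 400L, "+"))
  seqs <- sapply(tx$end - tx$start, random_seq)
  names(seqs) <- tx$id
  ## guarantee the declared cases
  seqs[["ok"]] <- paste(rep("C", 500), collapse = "")
  seqs[["orfy"]] <- paste0("ATG", strrep("AAA", 120), "TAA",
                           random_seq(400 - 3 - 360 - 3))
  kept <- filter_lncrna_candidates(tx, seqs, g$exons)
  expect_true("ok" %in% kept$id)
  expect_true("anti_ex" %in% kept$id)
  expect_false("short" %in% kept$id)
  expect_false("sense_ex" %in% kept$id)
  expect_false("orfy" %in% kept$id)
  ## strict length bound: exactly 200 nt is rejected
  t200 <- mk("t200", 100L, 200L, "+")
  expect_identical(
    nrow(filter_lncrna_candidates(t200, c(t200 = strrep("C", 200)), g$exons)),
    0L)
  expect_error(filter_lncrna_candidates(mk("x", 1L, 300L, "+"),
                                        c(y = "AAA"), g$exons), "missing")
})

test_that("retained set equals a brute-force ORF + overlap oracle", {
  set.seed(15)
  g <- make_gene("gA", "Chr1", 2000L, 6000L, "+",
                 list(c(2000L, 3000L), c(5000L, 6000L)))
  tx <- random_loci(60, chroms = "Chr1", max_pos = 10000)
  tx$end <- tx$start + sample(150:400, 60, replace = TRUE)
  seqs <- sapply(tx$end - tx$start, random_seq)
  names(seqs) <- tx$id
  kept <- filter_lncrna_candidates(tx, seqs, g$exons, max_orf_codons = 20)
  oracle_orf <- function(s) {
    best <- 0
    for (f in 0:2) {
      run <- 0
      open <- FALSE
      i <- 1 + f
      while (i + 2 <= nchar(s)) {
        cod <- substr(s, i, i + 2)
        if (!open && cod == "ATG") {
          open <- TRUE
          run <- 0
        }
        if (open) {
          if (cod %in% c("TAA", "TAG", "TGA")) {
            best <- max(best, run)
            open <- FALSE
          } else {
            run <- run + 1
          }
        }
        i <- i + 3
      }
      if (open) best <- max(best, run)
    }
    best
  }
  manual <- tx$id[sapply(seq_len(nrow(tx)), function(i) {
    len_ok <- (tx$end[i] - tx$start[i]) > 200
    orf_ok <- oracle_orf(seqs[[tx$id[i]]]) < 20
    sense_ex <- any(g$exons$strand == tx$strand[i] &
                      g$exons$chrom == tx$chrom[i] &
                      g$exons$start < tx$end[i] & g$exons$end > tx$start[i])
    len_ok && orf_ok && !sense_ex
  })]
  expect_setequal(kept$id, manual)
})

test_that("positional taxonomy follows the declared conventions", {
  g <- make_gene("gA", "Chr1", 80000L, 90000L, "+",
                 list(c(80000L, 82000L), c(88000L, 90000L)))
  lnc <- data.frame(
    id = c("intr_s", "exon_a", "up_a"),
    chrom = "Chr1",
    start = c(83000L, 81000L, 80000L - 50000L - 300L),
    end = c(83400L, 81400L, 80000L - 50000L),
    strand = c("+", "-", "-"), stringsAsFactors = FALSE)
  out <- classify_lncrna_position(lnc, g$genes, g$exons)
  expect_identical(out$direction, c("sense", "antisense", "antisense"))
  expect_identical(out$zone, c("genic", "genic", "intergenic"))
  expect_identical(out$position, c("intronic", "exonic", "upstream"))
  expect_identical(out$closest_gene, rep("gA", 3))
  ## minus-strand gene flips up/downstream
  gm <- make_gene("gB", "Chr2", 50000L, 60000L, "-")
  lnc2 <- data.frame(id = "x", chrom = "Chr2", start = 45000L, end = 45400L,
                     strand = "+", stringsAsFactors = FALSE)
  out2 <- classify_lncrna_position(lnc2, gm$genes, gm$exons)
  expect_identical(out2$position, "downstream")
  ## no genes on the chromosome: flagged intergenic record
  lnc3 <- data.frame(id = "y", chrom = "Chr9", start = 0L, end = 400L,
                     strand = "+", stringsAsFactors = FALSE)
  out3 <- classify_lncrna_position(lnc3, g$genes, g$exons)
  expect_true(out3$flagged)
  expect_identical(out3$zone, "intergenic")
  expect_true(is.na(out3$closest_gene))
})

test_that("partner gene assignment equals the quadratic distance oracle", {
  g1 <- make_gene("gA", "Chr1", 100000L, 105000L, "+")
  lnc <- data.frame(id = c("genic1", "near", "far"),
                    chrom = "Chr1",
                    start = c(101000L, 105000L + 99000L, 105000L + 101000L),
                    end = c(101500L, 105000L + 99400L, 105000L + 101400L),
                    strand = "+", stringsAsFactors = FALSE)
  cl <- classify_lncrna_position(lnc, g1$genes, g1$exons)
  partners <- assign_partner_genes(cl, g1$genes)
  expect_identical(partners$genic1, "gA")
  expect_identical(partners$near, "gA")
  expect_identical(partners$far, character(0))
  ## random layout vs oracle
  set.seed(27)
  genes <- random_loci(30, max_pos = 5e5)
  names(genes)[1] <- "gene_id"
  genes$gene_id <- sub("^L", "G", genes$gene_id)
  lncs <- random_loci(80, max_pos = 5e5)
  cls <- classify_lncrna_position(lncs, genes,
                                  transform(genes, exon_id = gene_id))
  got <- assign_partner_genes(cls, genes, window = 20000L)
  for (i in seq_len(nrow(cls))) {
    expect_identical(got[[cls$id[i]]],
                     oracle_partners(cls[i, ], genes, 20000L),
                     info = cls$id[i])
  }
})

test_that("taxonomy summary counts all eight cells and matches planted truth", {
  cfg <- synthetic_config(seed = 19)
  ann <- generate_annotation(cfg)
  ln <- generate_lncrna_candidates(cfg, ann)
  cls <- classify_lncrna_position(ln$transcripts, ann$genes, ann$exons)
  expect_identical(setNames(cls$position, cls$id),
                   setNames(ln$truth$position, ln$truth$id))
  expect_identical(setNames(cls$direction, cls$id),
                   setNames(ln$truth$direction, ln$truth$id))
  expect_identical(setNames(cls$closest_gene, cls$id),
                   setNames(ln$truth$closest_gene, ln$truth$id))
  tab <- summarize_taxonomy(cls)
  expect_identical(tab$total, nrow(cls))
  manual <- 0L
  for (i in seq_len(nrow(cls))) {
    if (cls$direction[i] == "antisense" && cls$position[i] == "exonic") {
      manual <- manual + 1L
    }
  }
  expect_identical(tab$counts["antisense", "exonic"], manual)
  ## retained lncRNAs are never sense-exonic
  kept <- filter_lncrna_candidates(ln$transcripts, ln$seqs, ann$exons)
  kept_cls <- cls[cls$id %in% kept$id, ]
  expect_identical(
    sum(kept_cls$direction == "sense" & kept_cls$position == "exonic"), 0L)
})
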