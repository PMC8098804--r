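## File IO. Standard formats go through rtracklayer (GFF3, BED) and
## Biostrings (FASTA); tabular artifacts are plain TSV.

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon rows (1-based inclusive coordinates, as GFF3
#' requires) from the package's 0-based half-open gene and exon tables.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param exons Data frame with `gene_id`, `exon_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, exons, path) {
  validate_intervals(genes, "genes")
  validate_intervals(exons, "exons")
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  mrna_id <- paste0(genes$gene_id, ".1")
  gr_gene <- as_granges0(genes)
  S4Vectors::mcols(gr_gene) <- S4Vectors::DataFrame(
    type = "gene", ID = genes$gene_id)
  gr_mrna <- as_granges0(genes)
  S4Vectors::mcols(gr_mrna) <- S4Vectors::DataFrame(
    type = "mRNA", ID = mrna_id, Parent = genes$gene_id)
  gr_exon <- as_granges0(exons)
  S4Vectors::mcols(gr_exon) <- S4Vectors::DataFrame(
    type = "exon", ID = exons$exon_id,
    Parent = paste0(exons$gene_id, ".1"))
  all <- c(gr_gene, gr_mrna, gr_exon)
  all <- all[order(as.character(GenomicRanges::seqnames(all)),
                   GenomicRanges::start(all),
                   match(all$type, c("gene", "mRNA", "exon")))]
  rtracklayer::export.gff3(all, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with gene and exon rows.
#' @return A list with data frames `genes` and `exons` in 0-based half-open
#'   coordinates.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  to_df <- function(g, id) {
    data.frame(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      stringsAsFactors = FALSE
    )
  }
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  gene_df <- to_df(genes, as.character(genes$ID))
  parent <- as.character(BiocGenerics::unlist(exons$Parent))
  exon_df <- to_df(exons, sub("\\.1$", "", parent))
  exon_df$exon_id <- as.character(exons$ID)
  list(genes = gene_df, exons = exon_df)
}

#' Write intervals to BED6
#'
#' @param x Data frame with `name`, `chrom`, `start`, `end` and optionally
#'   `strand` (0-based half-open, BED's native convention).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "BED intervals")
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  df <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                   name = x$name, score = 0L, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file path.
#' @return Data frame with `name`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(
    name = if (!is.null(gr$name)) gr$name else paste0("feature_", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a count matrix as TSV (feature ids in the first column)
#'
#' @param mat Integer matrix, features x samples.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path File path.
#' @return Integer matrix with feature ids as row names.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "integer"
  mat
}
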