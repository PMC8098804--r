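## Long non-coding RNA identification and positional taxonomy:
## rule-based coding filter, sense/antisense x genic/intergenic x
## intronic/exonic/upstream/downstream classification relative to the
## closest annotated gene, and partner gene assignment.

#' Longest open reading frame, in codons
#'
#' Scans the three reading frames of the given strand of a transcript
#' sequence for ATG-initiated open reading frames. The length of an ORF is
#' the number of codons from the start codon up to (not including) the stop
#' codon; an ORF without an in-frame stop runs to the last complete codon.
#'
#' @param seq A DNA sequence (character scalar).
#' @return Integer, the longest ORF length in codons (0 when no ATG).
#' @export
longest_orf_codons <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) stop("longest_orf_codons: missing sequence")
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0 || starts[1] > n - 2L) next
    codons <- substring(seq, starts, starts + 2L)
    open_at <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_at)) {
        if (codons[k] == "ATG") open_at <- k
      } else if (codons[k] %in% stops) {
        best <- max(best, k - open_at)
        open_at <- NA_integer_
      }
    }
    if (!is.na(open_at)) best <- max(best, length(codons) - open_at + 1L)
  }
  best
}

#' Filter candidate transcripts to putative lncRNAs
#'
#' Retains transcripts strictly longer than `min_len` nt whose longest ORF
#' (three frames of the transcript strand) is strictly shorter than
#' `max_orf_codons` codons, and which do not overlap an annotated exon on
#' the same strand (sense-exonic overlaps are treated as unannotated mRNA
#' isoforms, not lncRNAs).
#'
#' @param transcripts Data frame with `id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param seqs Named character vector of transcript sequences covering all
#'   transcript ids.
#' @param exons Data frame of annotated exons (`chrom`, `start`, `end`,
#'   `strand`).
#' @param min_len Minimum transcript length in nt (exclusive bound).
#' @param max_orf_codons ORF threshold in codons (exclusive bound).
#' @return The retained subset of `transcripts`, with a `length` column.
#' @export
filter_lncrna_candidates <- function(transcripts, seqs, exons,
                                     min_len = 200L, max_orf_codons = 100L) {
  validate_intervals(transcripts, "transcripts")
  if (!all(transcripts$id %in% names(seqs))) {
    stop("filter_lncrna_candidates: missing sequence for some transcripts")
  }
  tx_seq <- seqs[transcripts$id]
  transcripts$length <- nchar(tx_seq)
  long_enough <- transcripts$length > min_len
  orf_ok <- vapply(tx_seq, longest_orf_codons, integer(1)) < max_orf_codons
  sense_exonic <- rep(FALSE, nrow(transcripts))
  if (!is.null(exons) && nrow(exons) > 0) {
    for (s in c("+", "-")) {
      sel <- transcripts$strand == s
      if (any(sel)) {
        sense_exonic[sel] <- overlaps_any0(
          transcripts[sel, , drop = FALSE],
          exons[exons$strand == s, , drop = FALSE])
      }
    }
  }
  transcripts[long_enough & orf_ok & !sense_exonic, , drop = FALSE]
}

## Closest gene on the same chromosome by gap distance; ties broken by
## lexicographically smallest gene id. Returns NA when no gene shares the
## chromosome.
closest_gene_idx <- function(chrom, start, end, genes) {
  cand <- which(genes$chrom == chrom)
  if (length(cand) == 0) return(NA_integer_)
  gap <- interval_gap(start, end, genes$start[cand], genes$end[cand])
  overlap <- genes$start[cand] < end & genes$end[cand] > start
  ## Minimum gap wins; a true overlap beats a merely touching interval at
  ## gap 0; remaining ties go to the lexicographically smallest gene id.
  ord <- order(gap, !overlap, genes$gene_id[cand])
  cand[ord][1]
}

#' Classify lncRNA position relative to the closest gene
#'
#' Each lncRNA is `genic` when it overlaps a gene body by >= 1 bp (position
#' `exonic` if it also overlaps an exon, else `intronic`), otherwise
#' `intergenic` (position `upstream` when it lies 5' of the closest gene's
#' transcription start, `downstream` when 3' of its end, relative to that
#' gene's strand). Direction is `sense` when the lncRNA strand equals the
#' closest (or overlapped) gene's strand, else `antisense`. lncRNAs on
#' chromosomes without genes are flagged and left intergenic with an
#' undefined closest gene.
#'
#' @param lncs Data frame with `id`, `chrom`, `start`, `end`, `strand`.
#' @param genes Data frame of gene bodies with `gene_id` and `strand`.
#' @param exons Data frame of exons with `gene_id`.
#' @return `lncs` with columns `direction`, `zone`, `position`,
#'   `closest_gene`, `flagged` added.
#' @export
classify_lncrna_position <- function(lncs, genes, exons) {
  validate_intervals(lncs, "lncRNAs")
  n <- nrow(lncs)
  direction <- zone <- position <- closest <- rep(NA_character_, n)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    idx <- closest_gene_idx(lncs$chrom[i], lncs$start[i], lncs$end[i], genes)
    if (is.na(idx)) {
      zone[i] <- "intergenic"
      flagged[i] <- TRUE
      next
    }
    g <- genes[idx, ]
    closest[i] <- g$gene_id
    direction[i] <- if (lncs$strand[i] == g$strand) "sense" else "antisense"
    gap <- interval_gap(lncs$start[i], lncs$end[i], g$start, g$end)
    if (gap == 0 && lncs$start[i] < g$end && lncs$end[i] > g$start) {
      zone[i] <- "genic"
      gene_exons <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
      hit_exon <- overlaps_any0(lncs[i, , drop = FALSE], gene_exons)
      position[i] <- if (isTRUE(hit_exon)) "exonic" else "intronic"
    } else {
      zone[i] <- "intergenic"
      before_start <- lncs$end[i] <= g$start
      five_prime_side <- if (g$strand == "-") !before_start else before_start
      position[i] <- if (five_prime_side) "upstream" else "downstream"
    }
  }
  lncs$direction <- direction
  lncs$zone <- zone
  lncs$position <- position
  lncs$closest_gene <- closest
  lncs$flagged <- flagged
  lncs
}

#' Assign partner genes to lncRNAs
#'
#' Genic lncRNAs partner with every gene they overlap; intergenic lncRNAs
#' partner with every gene whose body lies within `window` bp gap distance.
#'
#' @param lncs Classified lncRNA data frame (output of
#'   [classify_lncrna_position()]).
#' @param genes Gene body data frame with `gene_id`.
#' @param window Gap distance window in bp for intergenic lncRNAs.
#' @return Named list (by lncRNA id) of partner gene id vectors.
#' @export
assign_partner_genes <- function(lncs, genes, window = 100000L) {
  stopifnot("zone" %in% names(lncs))
  out <- vector("list", nrow(lncs))
  names(out) <- lncs$id
  for (i in seq_len(nrow(lncs))) {
    cand <- which(genes$chrom == lncs$chrom[i])
    if (length(cand) == 0) {
      out[[i]] <- character(0)
      next
    }
    gap <- interval_gap(lncs$start[i], lncs$end[i],
                        genes$start[cand], genes$end[cand])
    keep <- if (lncs$zone[i] == "genic") gap == 0 &
      genes$start[cand] < lncs$end[i] & genes$end[cand] > lncs$start[i]
    else gap <= window
    out[[i]] <- sort(genes$gene_id[cand[keep]])
  }
  out
}

#' Summarize the lncRNA positional taxonomy
#'
#' Counts classified lncRNAs over the eight (direction x zone x position)
#' cells: sense/antisense crossed with genic (intronic, exonic) and
#' intergenic (upstream, downstream).
#'
#' @param lncs Classified lncRNA data frame.
#' @return List with `counts` (2 x 4 integer matrix, rows sense/antisense,
#'   columns intronic/exonic/upstream/downstream) and `total`.
#' @export
summarize_taxonomy <- function(lncs) {
  ok <- !lncs$flagged & !is.na(lncs$position)
  tab <- table(factor(lncs$direction[ok], levels = c("sense", "antisense")),
               factor(lncs$position[ok],
                      levels = c("intronic", "exonic", "upstream", "downstream")))
  counts <- matrix(as.integer(tab), nrow = 2,
                   dimnames = list(c("sense", "antisense"),
                                   c("intronic", "exonic", "upstream",
                                     "downstream")))
  list(counts = counts, total = sum(counts))
}
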