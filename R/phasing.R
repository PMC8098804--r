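## 24-nt phasing analysis: phase score over small RNA read stacks at a
## locus, and PHAS locus calling as the conjunction of a high phase score
## with a retained trigger microRNA target site.

#' Phase score of a small RNA locus
#'
#' Assigns each read a corrected 5' start (minus-strand 5' starts are
#' shifted by +2 nt, the 3' overhang convention of phased duplexes),
#' discards reads whose raw 5' start falls outside the locus, and searches
#' all `p` registers for the one maximizing the phased abundance `P`. With
#' `U` the remaining (unphased) abundance and `k` the number of `p`-nt
#' cycles containing at least one phased read, the score is
#' `(k - 2) * ln(1 + 10 * P / (1 + U))` when `k >= 3` and 0 otherwise.
#'
#' @param alignments Data frame of reads with `chrom`, `start`, `end`,
#'   `strand`, `count` (0-based half-open).
#' @param locus List or single-row data frame with `chrom`, `start`, `end`.
#' @param p Phase length in nt.
#' @return List with `register` (0-based best register), `phased` (P),
#'   `unphased` (U), `cycles` (k), `score`.
#' @export
phase_score <- function(alignments, locus, p = 24L) {
  stopifnot(p >= 2L)
  aln <- alignments[alignments$chrom == locus$chrom, , drop = FALSE]
  five_prime <- ifelse(aln$strand == "-", aln$end - 1L, aln$start)
  inside <- five_prime >= locus$start & five_prime < locus$end
  aln <- aln[inside, , drop = FALSE]
  five_prime <- five_prime[inside]
  if (nrow(aln) == 0) stop("phase_score: no aligned reads within the locus")
  corrected <- five_prime + ifelse(aln$strand == "-", 2L, 0L)
  offset <- corrected - locus$start
  register <- offset %% p
  cycle <- offset %/% p
  total <- sum(aln$count)
  per_register <- vapply(0:(p - 1L), function(r) {
    sum(aln$count[register == r])
  }, numeric(1))
  best <- which.max(per_register) - 1L
  P <- per_register[best + 1L]
  U <- total - P
  k <- length(unique(cycle[register == best]))
  score <- if (k >= 3L) (k - 2L) * log(1 + 10 * P / (1 + U)) else 0
  list(register = best, phased = P, unphased = U, cycles = k, score = score)
}

#' Detect trigger-dependent PHAS loci
#'
#' Restricts candidates to loci with a 24-nt major RNA, and calls a PHAS
#' locus when the locus sequence carries a retained trigger microRNA target
#' site (expectation < 2) and its phase score strictly exceeds
#' `min_score`. High-scoring loci without a trigger site are reported but
#' not called.
#'
#' @param loci Locus data frame (`id`, `chrom`, `start`, `end`,
#'   `major_rna_len`).
#' @param alignments Read alignments with a `locus_id` column.
#' @param trigger_seq Trigger microRNA sequence (e.g. miR2275).
#' @param locus_seqs Named character vector of locus sequences.
#' @param p Phase length in nt.
#' @param min_score Strict phase-score threshold.
#' @param max_expectation Strict target-site retention cutoff.
#' @return Data frame with one row per scored candidate: `locus_id`,
#'   `register`, `phased`, `unphased`, `cycles`, `score`,
#'   `has_trigger_site`, `is_phas`.
#' @export
detect_phas_loci <- function(loci, alignments, trigger_seq, locus_seqs,
                             p = 24L, min_score = 30, max_expectation = 2) {
  cand <- loci[loci$major_rna_len == 24L, , drop = FALSE]
  cand <- cand[cand$id %in% alignments$locus_id, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    lc <- cand[i, ]
    aln <- alignments[alignments$locus_id == lc$id, , drop = FALSE]
    ps <- phase_score(aln, lc, p)
    has_site <- FALSE
    if (lc$id %in% names(locus_seqs)) {
      sites <- score_target_site(trigger_seq, locus_seqs[[lc$id]],
                                 max_expectation)
      has_site <- nrow(sites) > 0
    }
    data.frame(locus_id = lc$id, register = ps$register, phased = ps$phased,
               unphased = ps$unphased, cycles = ps$cycles, score = ps$score,
               has_trigger_site = has_site,
               is_phas = has_site & ps$score > min_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(locus_id = character(0), register = integer(0),
                      phased = numeric(0), unphased = numeric(0),
                      cycles = integer(0), score = numeric(0),
                      has_trigger_site = logical(0), is_phas = logical(0),
                      stringsAsFactors = FALSE)
  }
  out
}
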