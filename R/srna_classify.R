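## Small RNA locus classification: reference class cascade, major RNA size
## rule, genomic origin, heterochromatic siRNA calling, novel microRNA
## post-filters and the class-by-size summary table.

#' Filter small RNA read lengths
#'
#' Retains read lengths within the inclusive `[min_len, max_len]` window
#' (18-30 nt by default, the standard small RNA size selection), preserving
#' order.
#'
#' @param read_lengths Vector of positive integer read lengths (nt).
#' @param min_len,max_len Inclusive bounds in nt.
#' @return The retained lengths, in input order.
#' @export
filter_reads_by_length <- function(read_lengths, min_len = 18L, max_len = 30L) {
  if (min_len > max_len) stop("filter_reads_by_length: min_len > max_len")
  if (any(read_lengths < 1)) stop("filter_reads_by_length: lengths must be positive")
  read_lengths[read_lengths >= min_len & read_lengths <= max_len]
}

## Fuzzy matcher contract (stand-in for a short-read BLAST step): a hit is an
## ungapped local match of the query to a reference with at most
## `max_mismatch` mismatches over at least `min_coverage` of the query
## length. Implemented by sliding the full query over the N-padded
## concatenated references and testing every contiguous query sub-window of
## the minimum qualifying length.
## Pad length 30 nt (>= any query length) keeps a qualifying window from
## spanning two references while still allowing query overhang at ref edges.
.prepare_refs <- function(ref_seqs) {
  pad <- strrep("N", 30L)
  subject <- paste0(pad, paste(ref_seqs, collapse = pad), pad)
  list(subject = subject, codes = utf8ToInt(subject))
}

.match_prepared <- function(query, prep, max_mismatch, min_coverage) {
  if (grepl(query, prep$subject, fixed = TRUE)) return(TRUE)
  L <- nchar(query)
  min_len <- as.integer(ceiling(min_coverage * L))
  q <- utf8ToInt(query)
  s <- prep$codes
  n_off <- length(s) - L + 1L
  if (n_off < 1L) return(FALSE)
  off <- seq_len(n_off)
  ## Pad (N) positions carry a penalty that disqualifies any window
  ## containing them, so a hit is always a contiguous query sub-window
  ## aligned fully inside one reference.
  n_pen <- as.integer(max_mismatch + 2L)
  n_code <- utf8ToInt("N")
  pen_at <- function(j) {
    sj <- s[off + j - 1L]
    (sj != q[j]) + (n_pen - 1L) * (sj == n_code)
  }
  full <- integer(n_off)
  for (j in seq_len(L)) {
    full <- full + pen_at(j)
  }
  if (min(full) <= max_mismatch) return(TRUE)
  ## A qualifying window of length min_len implies a full-length penalty of
  ## at most max_mismatch + (L - min_len) * n_pen at the same offset; skip
  ## the window scan when even that bound fails.
  if (min(full) > max_mismatch + (L - min_len) * n_pen) return(FALSE)
  cum <- matrix(0L, n_off, L + 1L)
  for (j in seq_len(L)) {
    cum[, j + 1L] <- cum[, j] + pen_at(j)
  }
  for (j in 0:(L - min_len)) {
    if (any(cum[, j + min_len + 1L] - cum[, j + 1L] <= max_mismatch)) {
      return(TRUE)
    }
  }
  FALSE
}

matches_reference <- function(query, ref_seqs, max_mismatch = 2L,
                              min_coverage = 0.9) {
  if (nchar(query) > 30L) {
    stop("matches_reference: queries longer than 30 nt are not supported")
  }
  .match_prepared(query, .prepare_refs(ref_seqs), max_mismatch, min_coverage)
}

#' Classify small RNA loci by reference class and major RNA size
#'
#' Applies the classification cascade: the major RNA of each locus is
#' matched against the reference sets in the fixed precedence order rRNA >
#' tRNA > snRNA > miRNA > ta-siRNA (first hit wins); unmatched loci with a
#' 20-24 nt major RNA are called `siRNA`; everything else is `other`.
#'
#' @param loci Data frame with at least `id`, `major_rna_seq`,
#'   `major_rna_len`.
#' @param class_refs Named list of reference sequence vectors; names must
#'   cover `rRNA`, `tRNA`, `snRNA`, `miRNA`, `ta-siRNA`.
#' @param max_mismatch Maximum mismatches for a reference hit.
#' @param min_coverage Minimum fraction of the major RNA length an ungapped
#'   hit must cover.
#' @return `loci` with a `class_label` column added.
#' @export
classify_loci <- function(loci, class_refs, max_mismatch = 2L,
                          min_coverage = 0.9) {
  stopifnot(all(REFERENCE_CLASSES %in% names(class_refs)))
  if (nrow(loci) > 0 &&
      (any(is.na(loci$major_rna_seq)) || any(!nzchar(loci$major_rna_seq)))) {
    stop("classify_loci: empty major RNA sequence")
  }
  prepared <- lapply(class_refs[REFERENCE_CLASSES], .prepare_refs)
  label <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    q <- loci$major_rna_seq[i]
    hit <- NA_character_
    for (cl in REFERENCE_CLASSES) {
      if (.match_prepared(q, prepared[[cl]], max_mismatch, min_coverage)) {
        hit <- cl
        break
      }
    }
    if (!is.na(hit)) {
      label[i] <- hit
    } else if (loci$major_rna_len[i] >= 20L && loci$major_rna_len[i] <= 24L) {
      label[i] <- "siRNA"
    } else {
      label[i] <- "other"
    }
  }
  loci$class_label <- label
  loci
}

#' Assign the genomic origin of small RNA loci
#'
#' Labels each locus by >= 1 bp strand-agnostic overlap, with precedence
#' repeat > gene > intergenic, so that every locus receives exactly one
#' origin (the convention the heterochromatic siRNA criteria key on).
#'
#' @param loci Data frame of loci (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param genes,repeats Interval data frames of gene bodies and repeats.
#' @return `loci` with an `origin` column added.
#' @export
assign_genomic_origin <- function(loci, genes, repeats) {
  validate_intervals(loci, "loci")
  known_chroms <- unique(c(genes$chrom, repeats$chrom))
  unknown <- !(loci$chrom %in% known_chroms)
  if (any(unknown)) {
    warning(sum(unknown), " locus/loci on chromosomes absent from the ",
            "annotation; labelled intergenic")
  }
  origin <- rep("intergenic", nrow(loci))
  origin[overlaps_any0(loci, genes)] <- "gene"
  origin[overlaps_any0(loci, repeats)] <- "repeat"
  loci$origin <- origin
  loci
}

#' Call heterochromatic siRNA loci
#'
#' A locus is a heterochromatic siRNA (hc-siRNA) when it meets all three
#' criteria: it overlaps a repeat (origin `repeat`), its major RNA matches
#' no known reference class (class `siRNA`), and its major RNA is 23-24 nt.
#'
#' @param loci Data frame with `class_label`, `origin`, `major_rna_len`.
#' @return `loci` with a logical `is_hc_sirna` column added.
#' @export
call_hc_sirna <- function(loci) {
  stopifnot(all(c("class_label", "origin", "major_rna_len") %in% names(loci)))
  loci$is_hc_sirna <- loci$origin == "repeat" &
    loci$class_label == "siRNA" &
    loci$major_rna_len %in% c(23L, 24L)
  loci
}

#' Summarize classified loci by class and major RNA size
#'
#' Tabulates locus counts over the seven classes (rRNA, tRNA, snRNA, miRNA,
#' ta-siRNA, siRNA, other) and the size bins 20-24 nt plus an `other` bin
#' collecting all remaining lengths.
#'
#' @param loci Data frame with `class_label` and `major_rna_len`.
#' @return List with `counts` (7 x 6 integer matrix), `row_totals`,
#'   `col_totals` and `grand_total`.
#' @export
summarize_class_by_size <- function(loci) {
  size_bin <- ifelse(loci$major_rna_len %in% 20:24,
                     as.character(loci$major_rna_len), "other")
  tab <- table(factor(loci$class_label, levels = SRNA_CLASSES),
               factor(size_bin, levels = SIZE_BINS))
  counts <- matrix(as.integer(tab), nrow = length(SRNA_CLASSES),
                   dimnames = list(SRNA_CLASSES, SIZE_BINS))
  stopifnot(sum(counts) == nrow(loci))
  list(counts = counts,
       row_totals = as.integer(rowSums(counts)) |>
         setNames(rownames(counts)),
       col_totals = as.integer(colSums(counts)) |>
         setNames(colnames(counts)),
       grand_total = as.integer(sum(counts)))
}

#' Post-filter novel microRNA candidates
#'
#' Retains candidates that match no known microRNA, have a 21-22 nt mature
#' sequence located outside coding regions, a significant secondary
#' structure randomization p-value (< 0.05), and a hairpin prediction score
#' strictly greater than 3.
#'
#' @param candidates Data frame with `id`, `mature_len`, `in_coding_region`,
#'   `randfold_p`, `mirdeep_score`, `matches_known`.
#' @return The retained subset of `candidates`.
#' @export
novel_mirna_filter <- function(candidates) {
  need <- c("mature_len", "in_coding_region", "randfold_p", "mirdeep_score",
            "matches_known")
  stopifnot(all(need %in% names(candidates)))
  if (any(candidates$randfold_p < 0 | candidates$randfold_p > 1)) {
    stop("novel_mirna_filter: randfold_p must be in [0, 1]")
  }
  keep <- !candidates$matches_known &
    candidates$mature_len %in% c(21L, 22L) &
    !candidates$in_coding_region &
    candidates$randfold_p < 0.05 &
    candidates$mirdeep_score > 3
  candidates[keep, , drop = FALSE]
}

#' Run the full small RNA classification pipeline
#'
#' Convenience wrapper: classify by reference cascade, assign genomic
#' origin, and call hc-siRNAs.
#'
#' @inheritParams classify_loci
#' @inheritParams assign_genomic_origin
#' @return `loci` with `class_label`, `origin` and `is_hc_sirna` columns.
#' @export
classify_srna_pipeline <- function(loci, class_refs, genes, repeats,
                                   max_mismatch = 2L, min_coverage = 0.9) {
  loci <- classify_loci(loci, class_refs, max_mismatch, min_coverage)
  loci <- assign_genomic_origin(loci, genes, repeats)
  call_hc_sirna(loci)
}
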