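## MicroRNA target prediction and validation: expectation-scored target
## sites on mRNA and lncRNA, degradome peak categories, expression quadrant
## analysis, and microRNA-lncRNA interaction edges.

## T/U equivalence is enforced on input; all pairing is computed on the
## DNA alphabet internally.
.norm_seq <- function(x) toupper(chartr("Uu", "Tt", x))

#' Score microRNA target sites on a transcript
#'
#' Slides the microRNA over every ungapped antiparallel alignment offset of
#' the transcript and scores the pairing per microRNA position (counted
#' from the microRNA 5' end): Watson-Crick pair 0, G:U wobble 0.5, mismatch
#' 1.0, with penalties doubled in the seed-proximal region (microRNA
#' positions 2-13). The expectation is the penalty sum; sites with
#' expectation strictly below `max_expectation` are returned sorted by
#' expectation, then position. The cleavage position is the transcript base
#' paired to microRNA position 10.
#'
#' @param mirna_seq MicroRNA sequence (18-26 nt, RNA or DNA alphabet).
#' @param transcript_seq Transcript sequence.
#' @param max_expectation Strict retention cutoff (default 2).
#' @return Data frame with `start` (0-based transcript position of the
#'   site), `expectation`, `cleavage_pos` (0-based), `alignment` (one
#'   symbol per site position, 5'->3' on the transcript: `|` pair, `o`
#'   wobble, `x` mismatch). Empty when the transcript is shorter than the
#'   microRNA.
#' @export
score_target_site <- function(mirna_seq, transcript_seq, max_expectation = 2) {
  m_seq <- .norm_seq(mirna_seq)
  t_seq <- .norm_seq(transcript_seq)
  m <- nchar(m_seq)
  if (m < 18 || m > 26) stop("score_target_site: miRNA length must be 18-26 nt")
  if (!grepl("^[ACGT]+$", m_seq) || !grepl("^[ACGT]+$", t_seq)) {
    stop("score_target_site: sequences must be over {A,C,G,U/T}")
  }
  n <- nchar(t_seq)
  empty <- data.frame(start = integer(0), expectation = numeric(0),
                      cleavage_pos = integer(0), alignment = character(0),
                      stringsAsFactors = FALSE)
  if (n < m) return(empty)

  q <- utf8ToInt(m_seq)          # miRNA 5'->3'
  s <- utf8ToInt(t_seq)          # transcript 5'->3'
  n_off <- n - m + 1L
  offs <- seq_len(n_off)         # 1-based site start on the transcript
  expectation <- numeric(n_off)
  sym <- matrix("x", n_off, m)
  G <- utf8ToInt("G"); C <- utf8ToInt("C")
  A <- utf8ToInt("A"); T <- utf8ToInt("T")
  pair_of <- integer(128)
  pair_of[c(A, C, G, T)] <- c(T, G, C, A)
  for (j in seq_len(m)) {
    ## miRNA position j (from its 5' end) pairs the site base m - j + 1.
    tb <- s[offs + (m - j)]
    qb <- q[j]
    match <- tb == pair_of[qb]
    wobble <- (qb == G & tb == T) | (qb == T & tb == G)
    pen <- ifelse(match, 0, ifelse(wobble, 0.5, 1.0))
    if (j >= 2 && j <= 13) pen <- pen * 2
    expectation <- expectation + pen
    sym[, m - j + 1L] <- ifelse(match, "|", ifelse(wobble, "o", "x"))
  }
  keep <- which(expectation < max_expectation)
  if (length(keep) == 0) return(empty)
  out <- data.frame(
    start = keep - 1L,
    expectation = expectation[keep],
    cleavage_pos = keep - 1L + (m - 10L),
    alignment = apply(sym[keep, , drop = FALSE], 1, paste, collapse = ""),
    stringsAsFactors = FALSE)
  out[order(out$expectation, out$start), , drop = FALSE]
}

#' Categorize a degradome peak at a cleavage position
#'
#' Applies the standard degradome peak categories, computed over the
#' transcript's position profile: 0 = the cleavage count exceeds 1 read and
#' is the unique transcript maximum; 1 = exceeds 1 read, tied maximum; 2 =
#' exceeds 1 read, above the median of nonzero positions but below the
#' maximum; 3 = exceeds 1 read, at or below the median; 4 = exactly 1 read;
#' `NA` (no category) when the position has no reads. Sites with category
#' 0-2 are treated as degradome-supported.
#'
#' @param profile Data frame with `transcript`, `position` (0-based),
#'   `count`.
#' @param transcript_id Transcript to inspect.
#' @param cleavage_position 0-based position of the predicted cleavage.
#' @return List with `category` (integer or `NA`) and `supported`
#'   (category <= 2).
#' @export
categorize_degradome_peak <- function(profile, transcript_id,
                                      cleavage_position) {
  rows <- profile[profile$transcript == transcript_id & profile$count > 0, ,
                  drop = FALSE]
  if (nrow(rows) == 0) {
    stop("categorize_degradome_peak: no reads on transcript ", transcript_id)
  }
  cnt <- rows$count[rows$position == cleavage_position]
  if (length(cnt) == 0 || cnt == 0) {
    return(list(category = NA_integer_, supported = FALSE))
  }
  cnt <- cnt[1]
  category <- if (cnt == 1) {
    4L
  } else {
    mx <- max(rows$count)
    med <- median(rows$count)
    if (cnt == mx) {
      if (sum(rows$count == mx) == 1) 0L else 1L
    } else if (cnt > med) 2L else 3L
  }
  list(category = category, supported = category <= 2L)
}

#' Expression quadrant analysis of microRNA-target pairs
#'
#' Groups pairs in which both the microRNA and its target are
#' differentially expressed in the same contrast by the signs of their fold
#' changes. Quadrant labels read target-direction `_vs_`
#' microRNA-direction, e.g. `down_vs_up` = downregulated targets of
#' upregulated microRNAs. The `opposite` subset (`up_vs_down`,
#' `down_vs_up`) marks candidate microRNA-driven repression.
#'
#' @param de_mirnas,de_targets [differential_expression()] results from the
#'   same contrast.
#' @param pairs Data frame with `mirna`, `target`.
#' @return Data frame of doubly-DE pairs with `quadrant` and `opposite`
#'   columns; pairs with a non-DE member are excluded and counted in the
#'   `n_excluded` attribute.
#' @export
quadrant_analysis <- function(de_mirnas, de_targets, pairs) {
  mi <- de_mirnas[match(pairs$mirna, de_mirnas$feature_id), ]
  tg <- de_targets[match(pairs$target, de_targets$feature_id), ]
  both <- !is.na(mi$significant) & !is.na(tg$significant) &
    mi$significant & tg$significant
  out <- pairs[both, , drop = FALSE]
  dir_of <- function(lfc) ifelse(lfc > 0, "up", "down")
  out$mirna_direction <- dir_of(mi$log2_fc[both])
  out$target_direction <- dir_of(tg$log2_fc[both])
  out$quadrant <- paste0(out$target_direction, "_vs_", out$mirna_direction)
  out$opposite <- out$quadrant %in% c("up_vs_down", "down_vs_up")
  attr(out, "n_excluded") <- nrow(pairs) - nrow(out)
  rownames(out) <- NULL
  out
}

#' Predict microRNA-lncRNA interaction edges
#'
#' Scores every microRNA against every lncRNA with [score_target_site()]
#' and returns one edge per (microRNA, lncRNA) pair with at least one
#' retained site.
#'
#' @param mirnas Named character vector of microRNA sequences.
#' @param lncrnas Named character vector of lncRNA sequences.
#' @param max_expectation Strict retention cutoff.
#' @return Data frame with `mirna`, `lncrna`, `n_sites`,
#'   `best_expectation`.
#' @export
predict_mirna_lncrna_interactions <- function(mirnas, lncrnas,
                                              max_expectation = 2) {
  rows <- list()
  for (mi in names(mirnas)) {
    for (ln in names(lncrnas)) {
      sites <- score_target_site(mirnas[[mi]], lncrnas[[ln]], max_expectation)
      if (nrow(sites) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mi, lncrna = ln, n_sites = nrow(sites),
          best_expectation = min(sites$expectation),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mirna = character(0), lncrna = character(0),
                      n_sites = integer(0), best_expectation = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
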