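# Independent brute-force oracles, deliberately written as naive nested
# loops so they share no code with the implementations they check.

oracle_origin <- function(loci, genes, repeats) {
  out <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    hit_rep <- FALSE
    hit_gene <- FALSE
    for (j in seq_len(nrow(repeats))) {
      if (repeats$chrom[j] == loci$chrom[i] &&
          repeats$start[j] < loci$end[i] && repeats$end[j] > loci$start[i]) {
        hit_rep <- TRUE
      }
    }
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] == loci$chrom[i] &&
          genes$start[j] < loci$end[i] && genes$end[j] > loci$start[i]) {
        hit_gene <- TRUE
      }
    }
    out[i] <- if (hit_rep) "repeat" else if (hit_gene) "gene" else "intergenic"
  }
  out
}

oracle_partners <- function(lnc_row, genes, window) {
  out <- character(0)
  for (j in seq_len(nrow(genes))) {
    if (genes$chrom[j] != lnc_row$chrom) next
    overlap <- genes$start[j] < lnc_row$end && genes$end[j] > lnc_row$start
    gap <- max(0, max(lnc_row$start, genes$start[j]) -
                 min(lnc_row$end, genes$end[j]))
    keep <- if (lnc_row$zone == "genic") overlap else gap <= window
    if (keep) out <- c(out, genes$gene_id[j])
  }
  sort(out)
}

oracle_qtl <- function(features, qtl) {
  out <- matrix(FALSE, nrow(features), nrow(qtl),
                dimnames = list(features$id, qtl$name))
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(qtl))) {
      out[i, j] <- features$chrom[i] == qtl$chrom[j] &&
        features$start[i] < qtl$end[j] && features$end[i] > qtl$start[j]
    }
  }
  out
}

# Benjamini-Hochberg by the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, p[ord[k]] * m / k)
    adj[ord[k]] <- running
  }
  adj
}

# All-offset target scoring with an explicit per-position penalty loop.
oracle_target_sites <- function(mirna, transcript, cutoff = 2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mir <- toupper(chartr("U", "T", mirna))
  tx <- toupper(chartr("U", "T", transcript))
  m <- nchar(mir)
  n <- nchar(tx)
  res <- NULL
  if (n < m) {
    return(data.frame(start = integer(0), expectation = numeric(0)))
  }
  for (i in 1:(n - m + 1)) {
    e <- 0
    for (j in 1:m) {
      qb <- substr(mir, j, j)
      tb <- substr(tx, i + m - j, i + m - j)
      pen <- if (tb == comp[[qb]]) 0
        else if ((qb == "G" && tb == "T") || (qb == "T" && tb == "G")) 0.5
        else 1
      if (j >= 2 && j <= 13) pen <- 2 * pen
      e <- e + pen
    }
    if (e < cutoff) {
      res <- rbind(res, data.frame(start = i - 1L, expectation = e))
    }
  }
  if (is.null(res)) data.frame(start = integer(0), expectation = numeric(0))
  else res[order(res$expectation, res$start), , drop = FALSE]
}

oracle_degradome_category <- function(profile, tx, pos) {
  rows <- profile[profile$transcript == tx & profile$count > 0, , drop = FALSE]
  cnt <- rows$count[rows$position == pos]
  if (length(cnt) == 0) return(NA_integer_)
  cnt <- cnt[1]
  if (cnt == 1) return(4L)
  mx <- max(rows$count)
  med <- stats::median(rows$count)
  if (cnt == mx && sum(rows$count == mx) == 1) return(0L)
  if (cnt == mx) return(1L)
  if (cnt > med) return(2L)
  3L
}

# Phase score recomputed from the declared definition with plain loops.
oracle_phase_score <- function(aln, locus, p = 24L) {
  fp <- integer(0)
  cnt <- numeric(0)
  for (i in seq_len(nrow(aln))) {
    if (aln$chrom[i] != locus$chrom) next
    raw <- if (aln$strand[i] == "-") aln$end[i] - 1L else aln$start[i]
    if (raw < locus$start || raw >= locus$end) next
    fp <- c(fp, raw + if (aln$strand[i] == "-") 2L else 0L)
    cnt <- c(cnt, aln$count[i])
  }
  best_P <- -1
  best_r <- NA
  for (r in 0:(p - 1)) {
    P <- sum(cnt[(fp - locus$start) %% p == r])
    if (P > best_P) {
      best_P <- P
      best_r <- r
    }
  }
  sel <- (fp - locus$start) %% p == best_r
  k <- length(unique((fp[sel] - locus$start) %/% p))
  U <- sum(cnt) - best_P
  score <- if (k >= 3) (k - 2) * log(1 + 10 * best_P / (1 + U)) else 0
  list(register = best_r, score = score, k = k, P = best_P, U = U)
}

random_loci <- function(n, chroms = c("Chr1", "Chr2"), max_pos = 1e5) {
  w <- sample(50:500, n, replace = TRUE)
  st <- sapply(w, function(wi) sample.int(max_pos - wi, 1) - 1L)
  data.frame(id = sprintf("L%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = st, end = st + w,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(x)), "")[[1]]),
        collapse = "")
}
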