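## Genomic interval helpers. All coordinates inside the package are 0-based
## half-open [start, end); GFF3 (1-based inclusive) is converted on read and
## write, BED is passed through unchanged.

#' Validate a table of genomic intervals
#'
#' Checks the minimal interval contract used throughout the package:
#' non-empty chromosome labels, `0 <= start < end`, and a strand in
#' `+`, `-`, `.` when a strand column is present.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`, 0-based half-open.
#' @param what Label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x, what = "interval table") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop(what, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
      stop(what, ": empty chromosome label")
    }
    if (any(x$start < 0) || any(x$start >= x$end)) {
      stop(what, ": intervals must satisfy 0 <= start < end")
    }
    if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
      stop(what, ": strand must be one of '+', '-', '.'")
    }
  }
  invisible(x)
}

## Convert a 0-based half-open interval data frame to a GRanges object
## (1-based inclusive) for overlap arithmetic.
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

## Strand-agnostic >= 1 bp overlap of each query interval with any subject
## interval. Returns a logical vector along the rows of `query`.
overlaps_any0 <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  ## cross-chromosome comparisons are intended; silence seqlevel chatter
  suppressWarnings(
    IRanges::overlapsAny(as_granges0(query), as_granges0(subject),
                         ignore.strand = TRUE))
}

## Gap distance (bp) between two 0-based half-open intervals on the same
## chromosome: 0 when they overlap or touch, else the number of bases
## strictly between them.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}
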