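#' Construct a table of genomic intervals
#'
#' The universal coordinate unit of the package: 0-based, half-open spans
#' (BED convention) on named chromosomes, with an optional strand.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer-like vector, 0-based inclusive start.
#' @param end integer-like vector, exclusive end; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unset); recycled.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop(what, ": chromosome names must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    stop(what, ": coordinates must be finite", call. = FALSE)
  }
  if (any(x$start < 0)) {
    stop(what, ": negative start coordinate", call. = FALSE)
  }
  if (any(x$start >= x$end)) {
    stop(what, ": start must be < end (0-based half-open)", call. = FALSE)
  }
  if (!all(x$strand %in% c("+", "-", "*"))) {
    stop(what, ": strand must be one of '+', '-', '*'", call. = FALSE)
  }
  invisible(x)
}

#' Convert 1-based closed intervals to the package's 0-based half-open form
#'
#' @param start,end 1-based, both-inclusive coordinates (e.g. GFF-style).
#' @return list with components `start` (= start - 1) and `end` (= end).
#' @export
from_1based_closed <- function(start, end) {
  list(start = start - 1, end = end)
}

## Internal: 0-based half-open -> GRanges (1-based closed)
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  )
}
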