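#' Binned coverage track
#'
#' A per-chromosome array of signal per bin, the substrate of all density
#' computations. Values are fragment-base-pairs per base pair (averaged over
#' each bin), optionally multiplied by a scaling factor.
#'
#' @param values named list, one numeric vector per chromosome; element `i`
#'   covers bases `[(i-1)*binsize, i*binsize)`.
#' @param binsize bin width in bp.
#' @param chrom_lengths named numeric vector of chromosome lengths; each
#'   value vector must have `ceiling(length/binsize)` elements.
#' @param scaled whether a scaling factor has been applied.
#' @param genome label, e.g. `"target"` or `"spikein"`.
#' @param alpha the multiplicative factor that was applied (1 if unscaled).
#' @param n_reads,fragment_length optional provenance metadata used by
#'   [promoter_enrichment_score()].
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(values, binsize, chrom_lengths,
                           scaled = FALSE, genome = "target", alpha = 1,
                           n_reads = NA_real_, fragment_length = NA_real_) {
  stopifnot(is.list(values), !is.null(names(values)), binsize >= 1)
  if (!setequal(names(values), names(chrom_lengths))) {
    stop("coverage_track: values and chrom_lengths name different chromosomes",
         call. = FALSE)
  }
  chrom_lengths <- chrom_lengths[names(values)]
  for (ch in names(values)) {
    v <- values[[ch]]
    if (any(!is.finite(v))) {
      stop("coverage_track: non-finite values on ", ch, call. = FALSE)
    }
    nb <- ceiling(chrom_lengths[[ch]] / binsize)
    if (length(v) != nb) {
      stop("coverage_track: ", ch, " expects ", nb, " bins, got ", length(v),
           call. = FALSE)
    }
  }
  structure(
    list(values = values, binsize = binsize,
         chrom_lengths = chrom_lengths, scaled = scaled, genome = genome,
         alpha = alpha, n_reads = n_reads, fragment_length = fragment_length),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> genome=", x$genome,
      " binsize=", x$binsize, "bp",
      " chroms=", length(x$values),
      " scaled=", x$scaled, " alpha=", signif(x$alpha, 4), "\n", sep = "")
  invisible(x)
}

## Internal: prefix integral of the per-bp step function defined by the bins.
## F(x) = integral of signal over [0, x); x may be any bp offset in [0, L].
## Vectorized over x. Values outside [0, L] are clamped (zero signal outside).
track_prefix <- function(track, chrom, x) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom, call. = FALSE)
  b <- track$binsize
  L <- track$chrom_lengths[[chrom]]
  x <- pmin(pmax(x, 0), L)
  cs <- c(0, cumsum(v)) * b
  k <- pmin(floor(x / b), length(v) - 1)
  cs[k + 1] + (x - k * b) * v[k + 1]
}

## Internal: integral of signal over [start, end) clamped to the chromosome.
track_integral <- function(track, chrom, start, end) {
  track_prefix(track, chrom, end) - track_prefix(track, chrom, start)
}

#' Genome-wide mean signal of a track
#'
#' Mean per-bp signal over all chromosomes (bins weighted by width).
#'
#' @param track a [coverage_track()].
#' @return scalar mean signal per bp.
#' @export
track_mean <- function(track) {
  tot <- sum(vapply(names(track$values), function(ch) {
    track_integral(track, ch, 0, track$chrom_lengths[[ch]])
  }, numeric(1)))
  tot / sum(track$chrom_lengths)
}
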