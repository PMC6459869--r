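#' Construct a read set
#'
#' @param reads `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand` (0-based half-open read intervals; strand required because
#'   fragment extension is strand-directed).
#' @param genome `"target"` or `"spikein"`.
#' @param chrom_lengths named numeric vector of chromosome lengths covering
#'   every chromosome that appears in `reads`.
#' @return an object of class `read_set` with fields `reads`, `genome`,
#'   `n_reads`, `chrom_lengths`.
#' @export
read_set <- function(reads, genome = c("target", "spikein"), chrom_lengths) {
  genome <- match.arg(genome)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (nrow(reads) > 0) {
    if (!all(reads$strand %in% c("+", "-"))) {
      stop("read_set: every read needs strand '+' or '-'", call. = FALSE)
    }
    missing <- setdiff(unique(reads$chrom), names(chrom_lengths))
    if (length(missing)) {
      stop("read_set: reads on chromosomes without declared length: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(reads = reads, genome = genome,
                 n_reads = nrow(reads), chrom_lengths = chrom_lengths),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> genome=", x$genome, " n_reads=", x$n_reads,
      " chroms=", length(x$chrom_lengths), "\n", sep = "")
  invisible(x)
}

#' Construct a ChIP sample (one condition, one antibody)
#'
#' Bundles the four read sets of a ChIP-Rx experiment: IP and input, each
#' split into target-genome and exogenous spike-in reads.
#'
#' @param condition,antibody labels.
#' @param ip_target,ip_spikein,input_target,input_spikein [read_set()]s;
#'   the spike-in sets may be `NULL` when no spike-in material was used.
#' @return an object of class `chip_sample`.
#' @export
chip_sample <- function(condition, antibody,
                        ip_target, ip_spikein = NULL,
                        input_target = NULL, input_spikein = NULL) {
  structure(list(condition = condition, antibody = antibody,
                 ip_target = ip_target, ip_spikein = ip_spikein,
                 input_target = input_target,
                 input_spikein = input_spikein, factor = NULL),
            class = "chip_sample")
}

#' Compute a per-sample scaling factor
#'
#' ChIP-Rx convention: with a constant amount of exogenous chromatin per
#' cell, the number of spike-in reads is inversely proportional to the
#' amount of target chromatin captured, so `alpha = 1e6 / n(IP spike-in
#' reads)` places all samples on a common absolute scale (reads per million
#' spike-in). The `libsize` basis (`1e6 / n(IP target reads)`) deliberately
#' erases global differences and is provided for contrast.
#'
#' @param sample a [chip_sample()].
#' @param basis `"spikein"` or `"libsize"`.
#' @return an object of class `scaling_factor` with fields `alpha`, `basis`.
#' @export
compute_scaling_factor <- function(sample, basis = c("spikein", "libsize")) {
  basis <- match.arg(basis)
  n <- if (basis == "spikein") {
    if (is.null(sample$ip_spikein) || sample$ip_spikein$n_reads == 0) {
      stop("compute_scaling_factor: no IP spike-in reads; ",
           "spike-in basis unavailable", call. = FALSE)
    }
    sample$ip_spikein$n_reads
  } else {
    if (sample$ip_target$n_reads == 0) {
      stop("compute_scaling_factor: empty IP target read set", call. = FALSE)
    }
    sample$ip_target$n_reads
  }
  structure(list(alpha = 1e6 / n, basis = basis), class = "scaling_factor")
}

## Internal: strand-directed fragment intervals for a read set, clipped at
## chromosome ends. A read's fragment starts at its 5' end and extends
## fragment_length bp in the strand direction.
fragment_intervals <- function(readset, fragment_length) {
  r <- readset$reads
  L <- readset$chrom_lengths[r$chrom]
  if (any(r$start < 0) || any(r$end > L)) {
    stop("build_coverage: read beyond chromosome bounds", call. = FALSE)
  }
  fs <- ifelse(r$strand == "+", r$start, r$end - fragment_length)
  fe <- fs + fragment_length
  data.frame(chrom = r$chrom,
             start = pmax(fs, 0),
             end = pmin(fe, L),
             stringsAsFactors = FALSE)
}

#' Build a binned coverage track from a read set
#'
#' Each read is extended to `fragment_length` bp from its 5' end in the
#' strand direction (the track-building convention for single-end ChIP
#' reads); fragments are clipped at chromosome ends. The value of each bin
#' is `alpha * (fragment-bp overlapping the bin) / binsize`, i.e. scaled
#' mean fragment coverage per bp.
#'
#' @param readset a [read_set()].
#' @param fragment_length fragment extension in bp (default 200); must be
#'   at least the read length.
#' @param binsize bin width in bp (default 50).
#' @param factor optional [compute_scaling_factor()] result; `NULL` leaves
#'   the track unscaled (`alpha = 1`).
#' @return a [coverage_track()].
#' @export
build_coverage <- function(readset, fragment_length = 200, binsize = 50,
                           factor = NULL) {
  stopifnot(binsize >= 1, fragment_length >= 1)
  if (readset$n_reads > 0) {
    rl <- max(readset$reads$end - readset$reads$start)
    if (fragment_length < rl) {
      stop("build_coverage: fragment_length shorter than read length",
           call. = FALSE)
    }
  }
  alpha <- if (is.null(factor)) 1 else factor$alpha
  frags <- fragment_intervals(readset, fragment_length)
  chroms <- names(readset$chrom_lengths)
  values <- lapply(chroms, function(ch) {
    L <- readset$chrom_lengths[[ch]]
    nb <- ceiling(L / binsize)
    i <- which(frags$chrom == ch)
    if (length(i) == 0L) return(numeric(nb))
    cov <- IRanges::coverage(
      IRanges::IRanges(start = frags$start[i] + 1, end = frags$end[i]),
      width = L
    )
    cs <- cumsum(as.numeric(cov))
    edges <- pmin(seq_len(nb) * binsize, L)
    alpha * diff(c(0, cs[edges])) / binsize
  })
  names(values) <- chroms
  coverage_track(values, binsize, readset$chrom_lengths,
                 scaled = !is.null(factor), genome = readset$genome,
                 alpha = alpha, n_reads = readset$n_reads,
                 fragment_length = fragment_length)
}

#' Subtract an input track from an IP track
#'
#' Per-bin `max(ip - input, 0)`: signal tracks are nonnegative by contract,
#' so bins where input exceeds IP are clamped to zero. Both tracks must
#' already be scaled, share the binsize, genome label and chromosome set.
#'
#' @param ip,input [coverage_track()]s.
#' @return a [coverage_track()] of the clamped difference.
#' @export
subtract_input <- function(ip, input) {
  if (ip$binsize != input$binsize) {
    stop("subtract_input: binsize mismatch", call. = FALSE)
  }
  if (!identical(ip$genome, input$genome)) {
    stop("subtract_input: genome mismatch", call. = FALSE)
  }
  if (!setequal(names(ip$values), names(input$values))) {
    stop("subtract_input: chromosome sets differ", call. = FALSE)
  }
  values <- lapply(names(ip$values), function(ch) {
    pmax(ip$values[[ch]] - input$values[[ch]], 0)
  })
  names(values) <- names(ip$values)
  coverage_track(values, ip$binsize, ip$chrom_lengths, scaled = TRUE,
                 genome = ip$genome, alpha = ip$alpha,
                 n_reads = ip$n_reads, fragment_length = ip$fragment_length)
}
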