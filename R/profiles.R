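## Reference-point and scale-regions signal matrices with the shared
## min-max normalization used for same-antibody heatmap sets.

new_profile_matrix <- function(values, binsize, anchor, flagged,
                               minmax_factor = 1, extra = list()) {
  structure(c(list(values = values, n_bins = ncol(values),
                   binsize = binsize, anchor = anchor,
                   flagged = flagged, minmax_factor = minmax_factor),
              extra),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> anchor=", x$anchor, " ", nrow(x$values), "x",
      x$n_bins, " binsize=", x$binsize,
      " minmax_factor=", signif(x$minmax_factor, 4), "\n", sep = "")
  invisible(x)
}

## rows x bins matrix of mean per-bp signal over [starts, starts+binw) for
## a block of same-chromosome anchors; bins outside the chromosome get 0.
bin_block <- function(track, chrom, left, n_bins, binw) {
  offs <- (seq_len(n_bins) - 1) * binw
  starts <- outer(left, offs, `+`)
  ends <- starts + binw
  v <- track_integral(track, chrom, as.vector(starts), as.vector(ends))
  matrix(v / binw, nrow = length(left), ncol = n_bins)
}

#' Reference-point signal matrix (e.g. TSS-anchored)
#'
#' One row per anchor covering `[anchor - window_bp, anchor + window_bp)`
#' in `binsize` bins (column count `2 * window_bp / binsize`). Rows of
#' minus-strand anchors are reversed so that column 1 is always the 5'
#' (upstream) side. Bins beyond chromosome ends are zero-filled and the
#' row is flagged.
#'
#' @param track a [coverage_track()].
#' @param anchors `data.frame` with `chrom`, `tss` (anchor bp), `strand`,
#'   and an id column (`gene_id` or `region_id`).
#' @param window_bp half-window (default 5000, i.e. TSS +/- 5 kb).
#' @param binsize bin width (default 50); must divide `window_bp`.
#' @return a `profile_matrix` with rows in input order.
#' @export
reference_point_matrix <- function(track, anchors, window_bp = 5000,
                                   binsize = 50) {
  if (window_bp %% binsize != 0) {
    stop("reference_point_matrix: binsize must divide window_bp",
         call. = FALSE)
  }
  ids <- anchors$gene_id %||% anchors$region_id %||%
    as.character(seq_len(nrow(anchors)))
  nb <- 2 * window_bp / binsize
  vals <- matrix(0, nrow = nrow(anchors), ncol = nb)
  flagged <- logical(nrow(anchors))
  for (ch in unique(anchors$chrom)) {
    i <- which(anchors$chrom == ch)
    left <- anchors$tss[i] - window_bp
    L <- track$chrom_lengths[[ch]]
    vals[i, ] <- bin_block(track, ch, left, nb, binsize)
    flagged[i] <- left < 0 | (anchors$tss[i] + window_bp) > L
  }
  neg <- anchors$strand == "-"
  vals[neg, ] <- vals[neg, nb:1, drop = FALSE]
  rownames(vals) <- ids
  new_profile_matrix(vals, binsize, "reference_point", flagged,
                     extra = list(window_bp = window_bp))
}

#' Scale-regions signal matrix (length-normalized gene bodies)
#'
#' Gene bodies are resampled to `body_bins` equal-width columns by
#' length-weighted averaging; the `flank_bp` regions on each side are
#' binned at `binsize`. Total columns:
#' `body_bins + 2 * flank_bp / binsize`. Minus-strand rows are reversed so
#' columns always run 5' flank, body, 3' flank. Genes shorter than
#' `body_bins` bp are computed from repeated partial bins and flagged, as
#' are rows with out-of-chromosome flank bins (zero-filled).
#'
#' @param track a [coverage_track()].
#' @param genes gene `data.frame` from [read_genes()].
#' @param body_bins columns for the gene body (default 100).
#' @param flank_bp flank width (default 1000).
#' @param binsize flank bin width (default 50); must divide `flank_bp`.
#' @return a `profile_matrix` with rows in input order.
#' @export
scale_regions_matrix <- function(track, genes, body_bins = 100,
                                 flank_bp = 1000, binsize = 50) {
  if (flank_bp %% binsize != 0) {
    stop("scale_regions_matrix: binsize must divide flank_bp",
         call. = FALSE)
  }
  nf <- flank_bp / binsize
  nb <- body_bins + 2 * nf
  vals <- matrix(0, nrow = nrow(genes), ncol = nb)
  flagged <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    L <- track$chrom_lengths[[ch]]
    s <- genes$start[i]; e <- genes$end[i]
    vals[i, seq_len(nf)] <- bin_block(track, ch, s - flank_bp, nf, binsize)
    vals[i, body_bins + nf + seq_len(nf)] <-
      bin_block(track, ch, e, nf, binsize)
    ## body: one variable bin width per gene
    w <- (e - s) / body_bins
    bstart <- s + (matrix(rep(seq_len(body_bins) - 1, each = length(i)),
                          nrow = length(i))) * w
    bend <- bstart + w
    bv <- track_integral(track, ch, as.vector(bstart), as.vector(bend)) /
      as.vector(matrix(rep(w, body_bins), nrow = length(i)))
    vals[i, nf + seq_len(body_bins)] <-
      matrix(bv, nrow = length(i), ncol = body_bins)
    flagged[i] <- (s - flank_bp) < 0 | (e + flank_bp) > L |
      (e - s) < body_bins
  }
  neg <- genes$strand == "-"
  vals[neg, ] <- vals[neg, nb:1, drop = FALSE]
  rownames(vals) <- genes$gene_id
  new_profile_matrix(vals, binsize, "scale_regions", flagged,
                     extra = list(body_bins = body_bins,
                                  flank_bp = flank_bp))
}

#' Shared min-max normalization across same-antibody matrices
#'
#' One factor `1 / (max - min)` is computed over the pooled cells of all
#' matrices in the set and applied to every matrix, so that intensities
#' remain comparable across samples probed with the same antibody; the
#' pooled range after scaling is exactly 1. A constant pooled set gets
#' factor 1 with a warning.
#'
#' @param matrices a list of `profile_matrix` objects (>= 1).
#' @return the same list, every matrix scaled, with `minmax_factor` set.
#' @export
minmax_normalize <- function(matrices) {
  if (inherits(matrices, "profile_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  cells <- unlist(lapply(matrices, function(m) range(m$values)))
  lo <- min(cells); hi <- max(cells)
  if (hi == lo) {
    warning("minmax_normalize: constant pooled matrix; factor set to 1")
    f <- 1
  } else {
    f <- 1 / (hi - lo)
  }
  lapply(matrices, function(m) {
    m$values <- m$values * f
    m$minmax_factor <- f
    m
  })
}

#' Rank regions by a signal value
#'
#' Stable ordering permutation; ties are broken by region id for
#' determinism.
#'
#' @param ids character vector of region/gene ids.
#' @param signal numeric vector aligned with `ids`.
#' @param rule `"by_signal_desc"` (default; e.g. H3K27me3 deposition) or
#'   `"by_signal_asc"` (e.g. ascending H3K36me3 intensity).
#' @return an integer permutation of `seq_along(ids)`.
#' @export
rank_regions <- function(ids, signal, rule = c("by_signal_desc",
                                               "by_signal_asc")) {
  rule <- match.arg(rule)
  stopifnot(length(ids) == length(signal))
  if (rule == "by_signal_desc") order(-signal, ids) else order(signal, ids)
}

#' Per-group promoter intensities with pairwise Wilcoxon comparisons
#'
#' Mean signal density over each promoter (TSS +/- `window_bp`), split by
#' group, with two-sided Wilcoxon rank-sum comparisons between every pair
#' of groups (via [compare_densities()]). Groups with fewer than 2
#' promoters are flagged and excluded from comparisons.
#'
#' @param track a [coverage_track()].
#' @param promoters `data.frame` with `chrom`, `tss` and an id column.
#' @param groups vector of group labels, one per promoter.
#' @param window_bp promoter half-width (default 2500).
#' @return list with `values` (named list of per-group density vectors),
#'   `comparisons` (named list of `comparison_result`, names `"A vs B"`),
#'   and `flagged_groups`.
#' @export
promoter_intensity_summary <- function(track, promoters, groups,
                                       window_bp = 2500) {
  stopifnot(length(groups) == nrow(promoters))
  dens <- numeric(nrow(promoters))
  for (ch in unique(promoters$chrom)) {
    i <- which(promoters$chrom == ch)
    L <- track$chrom_lengths[[ch]]
    s <- pmax(promoters$tss[i] - window_bp, 0)
    e <- pmin(promoters$tss[i] + window_bp, L)
    dens[i] <- track_integral(track, ch, s, e) / (e - s)
  }
  values <- split(dens, groups)
  ok <- names(values)[vapply(values, length, integer(1)) >= 2]
  flagged <- setdiff(names(values), ok)
  comparisons <- list()
  if (length(ok) >= 2) {
    pairs <- utils::combn(ok, 2, simplify = FALSE)
    for (p in pairs) {
      comparisons[[paste(p[1], "vs", p[2])]] <-
        compare_densities(values[[p[1]]], values[[p[2]]], "wilcoxon")
    }
  }
  list(values = values, comparisons = comparisons,
       flagged_groups = flagged)
}
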