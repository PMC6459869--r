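#' Select Polycomb target regions
#'
#' A target region is a SUZ12 peak passing the significance cutoff that
#' overlaps a passing RING1B peak by at least `min_overlap` bp (a
#' co-occupied PRC1/PRC2 site). The SUZ12 span defines the region; each
#' region is paired with its maximal-overlap RING1B partner. The p-value
#' filter follows the conventional lenient peak-call cutoff p <= 0.1, i.e.
#' `-log10(p) >= min_neglog10p` with default 1.
#'
#' @param suz12,ring1b peak `data.frame`s as from [read_peaks()]; must
#'   carry `neg_log10_p`.
#' @param min_neglog10p significance threshold on `-log10(p)` (default 1).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return a `data.frame` in genomic sort order with columns `region_id`
#'   (the SUZ12 peak name), `chrom`, `start`, `end`, `neg_log10_p`,
#'   `partner` (RING1B peak name), `overlap_bp`, and placeholder columns
#'   `gene_id`/`gene_strand` (`NA` until [assign_promoters()]).
#' @export
select_target_regions <- function(suz12, ring1b, min_neglog10p = 1,
                                  min_overlap = 1) {
  stopifnot(min_overlap >= 1)
  s <- suz12[!is.na(suz12$neg_log10_p) &
               suz12$neg_log10_p >= min_neglog10p, , drop = FALSE]
  r <- ring1b[!is.na(ring1b$neg_log10_p) &
                ring1b$neg_log10_p >= min_neglog10p, , drop = FALSE]
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      neg_log10_p = numeric(), partner = character(),
                      overlap_bp = numeric(), gene_id = character(),
                      gene_strand = character(), stringsAsFactors = FALSE)
  if (nrow(s) == 0 || nrow(r) == 0) return(empty)
  gs <- intervals_to_granges(data.frame(chrom = s$chrom, start = s$start,
                                        end = s$end, strand = "*"))
  gr <- intervals_to_granges(data.frame(chrom = r$chrom, start = r$start,
                                        end = r$end, strand = "*"))
  hits <- GenomicRanges::findOverlaps(gs, gr, minoverlap = min_overlap)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(s$end[qi], r$end[si]) - pmax(s$start[qi], r$start[si])
  ## maximal-overlap partner per SUZ12 peak; ties resolved by partner name
  o <- order(qi, -ov, r$name[si])
  first <- o[!duplicated(qi[o])]
  out <- data.frame(
    region_id = s$name[qi[first]],
    chrom = s$chrom[qi[first]],
    start = s$start[qi[first]],
    end = s$end[qi[first]],
    neg_log10_p = s$neg_log10_p[qi[first]],
    partner = r$name[si[first]],
    overlap_bp = ov[first],
    gene_id = NA_character_,
    gene_strand = NA_character_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end, out$region_id), ]
  rownames(out) <- NULL
  out
}

#' Flank windows abutting a target region
#'
#' Returns the region span (`inside`) and the two `flank_bp`-wide windows
#' immediately 5' and 3' of its boundaries. With
#' `orientation = "gene_strand"` and an assigned minus-strand gene, the
#' 5'/3' labels swap (the genomic-left window becomes `out3`). Windows are
#' clipped at chromosome ends and flagged when clipped.
#'
#' @param region one-row `data.frame` from [select_target_regions()] (or
#'   any row with `chrom`, `start`, `end`, optionally `gene_strand`).
#' @param flank_bp flank width in bp (default 1200; the wider 4000 bp
#'   window is the standard alternative).
#' @param chrom_length length of the chromosome (for clipping); `Inf`
#'   disables right clipping.
#' @param orientation `"gene_strand"` (default; falls back to genomic
#'   left/right when no gene is assigned) or `"genomic"`.
#' @return a list with `inside`, `out5`, `out3` (each
#'   `c(start, end)`), `clipped` (logical) and `flank_bp`.
#' @export
spreading_flanks <- function(region, flank_bp = 1200, chrom_length = Inf,
                             orientation = c("gene_strand", "genomic")) {
  orientation <- match.arg(orientation)
  stopifnot(flank_bp > 0)
  s <- region$start; e <- region$end
  left <- c(max(s - flank_bp, 0), s)
  right <- c(e, min(e + flank_bp, chrom_length))
  clipped <- (s - flank_bp < 0) || (e + flank_bp > chrom_length)
  if (left[1] >= left[2] || right[1] >= right[2]) {
    ## no room at a chromosome boundary: degenerate 1 bp window, flagged
    if (left[1] >= left[2]) left <- c(max(s - 1, 0), s)
    if (right[1] >= right[2]) right <- c(e, e + 1)
    clipped <- TRUE
  }
  flip <- orientation == "gene_strand" &&
    !is.null(region$gene_strand) && !is.na(region$gene_strand) &&
    region$gene_strand == "-"
  out5 <- if (flip) right else left
  out3 <- if (flip) left else right
  list(inside = c(s, e), out5 = out5, out3 = out3,
       clipped = clipped, flank_bp = flank_bp)
}

#' Assign the nearest promoter to each peak
#'
#' Each peak is assigned the gene whose TSS lies nearest to the peak
#' center, within `window_bp`; equidistant TSSs are resolved toward the
#' lexicographically smaller `gene_id` for determinism.
#'
#' @param peaks peak or target-region `data.frame` (`chrom`, `start`,
#'   `end`).
#' @param genes gene `data.frame` from [read_genes()].
#' @param window_bp maximum center-to-TSS distance (default 2500).
#' @return `peaks` with `gene_id` and `gene_strand` columns filled
#'   (`NA` where no TSS lies in the window).
#' @export
assign_promoters <- function(peaks, genes, window_bp = 2500) {
  peaks$gene_id <- NA_character_
  peaks$gene_strand <- NA_character_
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(peaks)
  center <- floor((peaks$start + peaks$end) / 2)
  gp <- intervals_to_granges(data.frame(
    chrom = peaks$chrom, start = pmax(center - window_bp, 0),
    end = center + window_bp + 1, strand = "*"))
  gt <- intervals_to_granges(data.frame(
    chrom = genes$chrom, start = genes$tss, end = genes$tss + 1,
    strand = "*"))
  hits <- GenomicRanges::findOverlaps(gp, gt)
  if (length(hits) == 0) return(peaks)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- abs(genes$tss[si] - center[qi])
  o <- order(qi, d, genes$gene_id[si])
  first <- o[!duplicated(qi[o])]
  peaks$gene_id[qi[first]] <- genes$gene_id[si[first]]
  peaks$gene_strand[qi[first]] <- genes$strand[si[first]]
  peaks
}

#' Stratify genes into Polycomb targets and H3K36me3 classes
#'
#' A gene is `PcG` when its promoter (TSS +/- `promoter_bp`) overlaps a
#' target region (this takes precedence regardless of H3K36me3 signal);
#' otherwise `K36pos` when its gene-body mean H3K36me3 density reaches the
#' threshold, else `K36neg`. The default threshold is a deterministic
#' two-class split of the non-PcG gene-body densities (midpoint of the two
#' cluster means, initialized at the 25th/75th percentiles), which adapts
#' to the bimodal active/inactive mixture; `"median"` (strictly above the
#' non-PcG median) and an absolute cutoff are available.
#'
#' @param genes gene `data.frame` from [read_genes()].
#' @param pcg_regions target regions from [select_target_regions()].
#' @param h3k36_track scaled, input-subtracted H3K36me3 [coverage_track()].
#' @param threshold_rule `"kmeans2"`, `"median"`, or `"absolute"`.
#' @param threshold absolute density cutoff when
#'   `threshold_rule = "absolute"`.
#' @param promoter_bp promoter half-width around the TSS (default 2500).
#' @return `genes` with columns `k36_density` and `stratum` (factor with
#'   levels `PcG`, `K36pos`, `K36neg`; exhaustive and exclusive).
#' @export
stratify_genes <- function(genes, pcg_regions, h3k36_track,
                           threshold_rule = c("kmeans2", "median",
                                              "absolute"),
                           threshold = NULL, promoter_bp = 2500) {
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(nrow(genes) > 0)
  dens <- vapply(seq_len(nrow(genes)), function(i) {
    region_density(h3k36_track, genes$chrom[i], genes$start[i],
                   genes$end[i])
  }, numeric(1))
  is_pcg <- rep(FALSE, nrow(genes))
  if (nrow(pcg_regions) > 0) {
    gpr <- intervals_to_granges(data.frame(
      chrom = genes$chrom, start = pmax(genes$tss - promoter_bp, 0),
      end = genes$tss + promoter_bp + 1, strand = "*"))
    gtr <- intervals_to_granges(data.frame(
      chrom = pcg_regions$chrom, start = pcg_regions$start,
      end = pcg_regions$end, strand = "*"))
    is_pcg <- IRanges::overlapsAny(gpr, gtr)
  }
  nonpcg <- dens[!is_pcg]
  thr <- switch(threshold_rule,
    absolute = {
      if (is.null(threshold)) {
        stop("stratify_genes: absolute rule needs `threshold`",
             call. = FALSE)
      }
      threshold
    },
    median = {
      m <- stats::median(nonpcg)
      ## strictly-above-median semantics
      m + .Machine$double.eps * max(1, abs(m))
    },
    kmeans2 = kmeans2_threshold(nonpcg)
  )
  stratum <- ifelse(is_pcg, "PcG",
                    ifelse(dens >= thr, "K36pos", "K36neg"))
  genes$k36_density <- dens
  genes$stratum <- factor(stratum, levels = c("PcG", "K36pos", "K36neg"))
  genes
}

## Deterministic 1-d 2-means: centers initialized at the 25th/75th
## percentiles; returns the midpoint of the converged centers.
kmeans2_threshold <- function(x) {
  if (length(x) < 2 || diff(range(x)) == 0) return(Inf)
  c1 <- stats::quantile(x, 0.25, names = FALSE)
  c2 <- stats::quantile(x, 0.75, names = FALSE)
  if (c1 == c2) c2 <- max(x)
  for (i in 1:100) {
    hi <- x > (c1 + c2) / 2
    if (!any(hi) || all(hi)) break
    n1 <- mean(x[!hi]); n2 <- mean(x[hi])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) { c1 <- n1; c2 <- n2; break }
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}
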