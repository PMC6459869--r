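#' Mean signal density over an interval
#'
#' Sum of per-bp signal across the interval divided by its length, with
#' bins partially covered by the interval weighted by their overlap.
#'
#' @param track a [coverage_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval, within the chromosome.
#' @return mean signal per bp (scalar).
#' @export
region_density <- function(track, chrom, start, end) {
  if (is.null(track$values[[chrom]])) {
    stop("region_density: unknown chromosome: ", chrom, call. = FALSE)
  }
  if (end <= start) stop("region_density: empty interval", call. = FALSE)
  L <- track$chrom_lengths[[chrom]]
  if (start < 0 || end > L) {
    stop("region_density: interval outside chromosome bounds",
         call. = FALSE)
  }
  track_integral(track, chrom, start, end) / (end - start)
}

#' Per-region inside/outside densities and spreading ratios
#'
#' The core statistic: for every target region, the mean signal density
#' inside the region and in the `flank_bp` windows abutting its 5' and 3'
#' boundaries, plus the out/in ratios (a pseudocount is added to numerator
#' and denominator so ratios stay bounded on null tracks). The
#' reciprocal in/out ratios are also emitted. Out/in is the headline:
#' close to 1 when the mark spreads beyond the binding footprint, close
#' to 0 when confined. Regions whose flanks are clipped at chromosome
#' ends are flagged and excluded from downstream tests by default.
#'
#' @param track a [coverage_track()] (typically the spike-in-scaled
#'   H3K27me3 IP track).
#' @param regions target regions from [select_target_regions()].
#' @param flank_bp flank width (default 1200 bp; 4000 bp is the standard
#'   wider window).
#' @param pseudocount epsilon added to both ratio terms (default 0.01
#'   signal per bp).
#' @param orientation passed to [spreading_flanks()].
#' @return a `data.frame` with one row per region: `region_id`, `chrom`,
#'   `start`, `end`, `density_in`, `density_out5`, `density_out3`,
#'   `ratio5`, `ratio3` (out/in), `in_out5`, `in_out3`, `clipped`.
#' @export
spreading_table <- function(track, regions, flank_bp = 1200,
                            pseudocount = 0.01,
                            orientation = c("gene_strand", "genomic")) {
  orientation <- match.arg(orientation)
  n <- nrow(regions)
  out <- data.frame(region_id = regions$region_id,
                    chrom = regions$chrom,
                    start = regions$start, end = regions$end,
                    density_in = NA_real_, density_out5 = NA_real_,
                    density_out3 = NA_real_, ratio5 = NA_real_,
                    ratio3 = NA_real_, in_out5 = NA_real_,
                    in_out3 = NA_real_, clipped = FALSE,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  fl <- lapply(seq_len(n), function(i) {
    L <- track$chrom_lengths[[regions$chrom[i]]]
    spreading_flanks(regions[i, ], flank_bp, chrom_length = L,
                     orientation = orientation)
  })
  bound <- function(part, j) vapply(fl, function(f) f[[part]][j], numeric(1))
  ins_s <- bound("inside", 1); ins_e <- bound("inside", 2)
  o5_s <- bound("out5", 1); o5_e <- bound("out5", 2)
  o3_s <- bound("out3", 1); o3_e <- bound("out3", 2)
  out$clipped <- vapply(fl, `[[`, logical(1), "clipped")
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    out$density_in[i] <-
      track_integral(track, ch, ins_s[i], ins_e[i]) / (ins_e[i] - ins_s[i])
    out$density_out5[i] <-
      track_integral(track, ch, o5_s[i], o5_e[i]) / (o5_e[i] - o5_s[i])
    out$density_out3[i] <-
      track_integral(track, ch, o3_s[i], o3_e[i]) / (o3_e[i] - o3_s[i])
  }
  out$ratio5 <- (out$density_out5 + pseudocount) /
    (out$density_in + pseudocount)
  out$ratio3 <- (out$density_out3 + pseudocount) /
    (out$density_in + pseudocount)
  out$in_out5 <- (out$density_in + pseudocount) /
    (out$density_out5 + pseudocount)
  out$in_out3 <- (out$density_in + pseudocount) /
    (out$density_out3 + pseudocount)
  out
}

#' Compare two sets of densities or ratios
#'
#' `student_t` is the classical two-sample pooled-variance t-test
#' (`welch = TRUE` switches to the unequal-variance form); `wilcoxon` is
#' the two-sided rank-sum test, using the exact null distribution for
#' small untied samples and the tie-corrected normal approximation
#' otherwise. A fully tied pooled sample yields p = 1 by convention.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param test `"student_t"` or `"wilcoxon"`.
#' @param welch use the Welch t variant.
#' @return an object of class `comparison_result`: `test`, `statistic`,
#'   `p_value`, `n_a`, `n_b` (and `df` for the t-test).
#' @export
compare_densities <- function(a, b, test = c("student_t", "wilcoxon"),
                              welch = FALSE) {
  test <- match.arg(test)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (test == "student_t") {
    if (sd(c(a, b)) == 0) {
      res <- list(statistic = 0, p.value = 1,
                  parameter = length(a) + length(b) - 2)
    } else {
      res <- stats::t.test(a, b, var.equal = !welch)
    }
    structure(list(test = "student_t",
                   statistic = unname(res$statistic),
                   p_value = res$p.value,
                   df = unname(res$parameter),
                   n_a = length(a), n_b = length(b)),
              class = "comparison_result")
  } else {
    pooled <- c(a, b)
    if (diff(range(pooled)) == 0) {
      return(structure(list(test = "wilcoxon",
                            statistic = length(a) * length(b) / 2,
                            p_value = 1, n_a = length(a),
                            n_b = length(b)),
                       class = "comparison_result"))
    }
    exact <- !anyDuplicated(pooled) && length(a) < 50 && length(b) < 50
    res <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    structure(list(test = "wilcoxon",
                   statistic = unname(res$statistic),
                   p_value = res$p.value,
                   n_a = length(a), n_b = length(b)),
              class = "comparison_result")
  }
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$test, ": statistic=",
      signif(x$statistic, 5), " p=", signif(x$p_value, 4),
      " (n=", x$n_a, ",", x$n_b, ")\n", sep = "")
  invisible(x)
}

#' Linear regression of paired per-region ratios
#'
#' Least-squares fit of `b ~ a` over regions paired by position, with the
#' Pearson correlation r and coefficient of determination r^2; the
#' comparison used to relate wild-type and knockout spreading ratios.
#'
#' @param ratios_a,ratios_b numeric vectors of equal length (>= 3), paired
#'   by region.
#' @return a `comparison_result` with `slope`, `intercept`, `r`,
#'   `r_squared`, `n_a`, `n_b`.
#' @export
ratio_correlation <- function(ratios_a, ratios_b) {
  stopifnot(length(ratios_a) == length(ratios_b), length(ratios_a) >= 3)
  if (stats::sd(ratios_a) == 0) {
    stop("ratio_correlation: zero variance in predictor; slope undefined",
         call. = FALSE)
  }
  fit <- stats::lm(ratios_b ~ ratios_a)
  r <- stats::cor(ratios_a, ratios_b)
  structure(list(test = "linear_regression",
                 statistic = unname(coef(fit)[2]),
                 p_value = NA_real_,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, r_squared = r^2,
                 n_a = length(ratios_a), n_b = length(ratios_b)),
            class = "comparison_result")
}

#' Best-scoring fraction of regions
#'
#' Returns the `ceiling(q * n)` records with the best scores (larger =
#' better: pass enrichment, or -log10 p for "top by p-value" selections);
#' ties are broken by `region_id` for determinism.
#'
#' @param records `data.frame` with a `region_id` column.
#' @param scores numeric vector aligned with `records`.
#' @param q fraction in (0, 1].
#' @return the selected subset of `records`, best first.
#' @export
top_fraction <- function(records, scores, q) {
  stopifnot(q > 0, q <= 1, length(scores) == nrow(records))
  if (nrow(records) == 0) return(records)
  k <- ceiling(q * nrow(records))
  o <- order(-scores, records$region_id)
  out <- records[o[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Poisson enrichment score for an interval
#'
#' A minimal promoter-ranking score: the upper-tail Poisson probability
#' (including the observed value) of the IP fragment count in the interval
#' given an input-derived expectation, returned as -log10 p. The
#' expectation is the input fragment count scaled by the IP/input
#' library-size ratio, floored at `lambda_min`. Both tracks must be
#' unscaled count-equivalents from [build_coverage()] (so fragment counts
#' can be recovered from fragment-bp).
#'
#' @param ip_track,input_track unscaled [coverage_track()]s carrying
#'   `n_reads` and `fragment_length` metadata.
#' @param chrom,start,end the interval (0-based half-open, length >= 1).
#' @param lambda_min floor on the expectation (default 1).
#' @return `-log10` of the upper-tail p-value.
#' @export
promoter_enrichment_score <- function(ip_track, input_track, chrom,
                                      start, end, lambda_min = 1) {
  if (end <= start) {
    stop("promoter_enrichment_score: zero-length interval", call. = FALSE)
  }
  if (isTRUE(ip_track$scaled) || isTRUE(input_track$scaled)) {
    stop("promoter_enrichment_score: tracks must be unscaled ",
         "count-equivalents", call. = FALSE)
  }
  obs <- round(track_integral(ip_track, chrom, start, end) /
                 ip_track$fragment_length)
  exp_in <- track_integral(input_track, chrom, start, end) /
    input_track$fragment_length
  lam <- max(lambda_min, exp_in * ip_track$n_reads / input_track$n_reads)
  p <- stats::ppois(obs - 1, lam, lower.tail = FALSE)
  -log10(max(p, .Machine$double.xmin))
}
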