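#!/usr/bin/env Rscript

## Stage 4 — the boundary spreading statistic.
##
## For each condition, computes per-region H3K27me3 density inside each
## target region and in the 1.2 kb flanks beyond its boundaries, the
## out/in spreading ratios, and the comparative statistics between
## conditions (pooled t-test, per-region regression). The wider 4 kb
## window is computed alongside.

suppressMessages(library(polyspread))

exp <- readRDS("results/data/experiment.rds")
tracks <- readRDS("results/tracks/tracks.rds")
regions <- readRDS("results/regions/regions.rds")
outdir <- "results/spreading"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

k27 <- grep("H3K27me3", names(tracks), value = TRUE)
tabs <- list()
for (nm in k27) {
  cond <- sub("\\..*$", "", nm)
  for (fl in c(1200, 4000)) {
    tab <- spreading_table(tracks[[nm]]$ip, regions, flank_bp = fl)
    write_tsv(tab, file.path(outdir,
                             sprintf("%s.flank%d.tsv", cond, fl)))
    if (fl == 1200) tabs[[cond]] <- tab
    keep <- !tab$clipped
    message(sprintf(
      "%-8s flank %4d bp: median out/in = %.3f (n = %d regions)",
      cond, fl, median(c(tab$ratio5[keep], tab$ratio3[keep])), sum(keep)))
  }
}

keep <- Reduce(`&`, lapply(tabs, function(t) !t$clipped))
stats <- list()
pairs <- combn(names(tabs), 2, simplify = FALSE)
for (p in pairs) {
  tt <- compare_densities(tabs[[p[1]]]$ratio5[keep],
                          tabs[[p[2]]]$ratio5[keep], "student_t")
  stats[[paste(p, collapse = "_vs_")]] <-
    list(test = "student_t", statistic = tt$statistic,
         p_value = tt$p_value, n = sum(keep))
  message(sprintf("%s vs %s: t = %.1f, p = %.3g", p[1], p[2],
                  tt$statistic, tt$p_value))
}
rc <- ratio_correlation(tabs[[1]]$ratio5[keep], tabs[[2]]$ratio5[keep])
stats$regression <- list(slope = rc$slope, intercept = rc$intercept,
                         r = rc$r, r_squared = rc$r_squared, n = sum(keep))
message(sprintf("Regression %s ~ %s: slope %.3f, r^2 = %.3f",
                names(tabs)[2], names(tabs)[1], rc$slope, rc$r_squared))
jsonlite::write_json(stats, file.path(outdir, "comparisons.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

## ranking plumbing: top 20% of regions by Poisson promoter enrichment
s <- exp$samples$wt.H3K27me3
ip_raw <- build_coverage(s$ip_target, 200, 50)
in_raw <- build_coverage(s$input_target, 200, 50)
scores <- vapply(seq_len(nrow(regions)), function(i) {
  promoter_enrichment_score(ip_raw, in_raw, regions$chrom[i],
                            regions$start[i], regions$end[i])
}, numeric(1))
top <- top_fraction(tabs$wt[!tabs$wt$clipped, ],
                    scores[!tabs$wt$clipped], 0.2)
write_tsv(top, file.path(outdir, "top20pct_regions.tsv"))
message(sprintf("Top 20%% most enriched regions: n = %d", nrow(top)))
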