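#!/usr/bin/env Rscript

## Stage 5 — ranked profile matrices and promoter intensity boxplots.
##
## Builds TSS-anchored (+/- 5 kb) and scale-regions (gene body + 1 kb
## flanks) matrices per condition, applies the shared 1/(max - min)
## factor across the same-antibody set, ranks Polycomb targets by
## H3K27me3 deposition and the rest by ascending H3K36me3, and compares
## promoter intensities between strata by Wilcoxon.

suppressMessages(library(polyspread))

exp <- readRDS("results/data/experiment.rds")
tracks <- readRDS("results/tracks/tracks.rds")
outdir <- "results/profiles"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

strat <- read_tsv("results/regions/gene_strata.tsv")
genes <- exp$genes
genes$stratum <- strat$stratum[match(genes$gene_id, strat$gene_id)]
genes$k36_density <- strat$k36_density[match(genes$gene_id, strat$gene_id)]

k27 <- grep("H3K27me3", names(tracks), value = TRUE)
mats <- lapply(k27, function(nm) {
  reference_point_matrix(tracks[[nm]]$net, genes, 5000, 50)
})
names(mats) <- k27
mats <- minmax_normalize(mats)
message(sprintf("TSS matrices: %d rows x %d bins, shared factor %.4g",
                nrow(mats[[1]]$values), mats[[1]]$n_bins,
                mats[[1]]$minmax_factor))

## ranking: PcG by descending H3K27me3, others by ascending H3K36me3
k27_dens <- rowMeans(mats$wt.H3K27me3$values)
pcg <- genes$stratum == "PcG"
ord <- c(which(pcg)[rank_regions(genes$gene_id[pcg], k27_dens[pcg])],
         which(!pcg)[rank_regions(genes$gene_id[!pcg],
                                  genes$k36_density[!pcg],
                                  "by_signal_asc")])
for (nm in names(mats)) {
  m <- mats[[nm]]
  df <- as.data.frame(m$values[ord, ])
  names(df) <- seq_len(ncol(df)) * 50 - 5050
  df <- cbind(gene_id = rownames(m$values)[ord],
              stratum = as.character(genes$stratum[ord]), df)
  write_tsv(df, file.path(outdir, paste0(nm, ".tss_matrix.tsv")))
}

body <- scale_regions_matrix(tracks$wt.H3K36me3$net, genes, 100, 1000, 50)
message(sprintf("Scale-regions H3K36me3 matrix: %d columns", body$n_bins))

summ <- promoter_intensity_summary(tracks$wt.H3K27me3$ip, genes,
                                   as.character(genes$stratum))
for (nm in names(summ$comparisons)) {
  cmp <- summ$comparisons[[nm]]
  message(sprintf("Promoter H3K27me3, %s: W = %.0f, p = %.3g",
                  nm, cmp$statistic, cmp$p_value))
}
box <- data.frame(
  stratum = rep(names(summ$values), lengths(summ$values)),
  promoter_density = unlist(summ$values))
write_tsv(box, file.path(outdir, "promoter_intensity.tsv"))
jsonlite::write_json(
  lapply(summ$comparisons, unclass),
  file.path(outdir, "promoter_wilcoxon.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
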