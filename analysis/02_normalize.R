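#!/usr/bin/env Rscript

## Stage 2 — scaling factors and coverage tracks.
##
## Computes the spike-in (and, for contrast, library-size) scaling factor
## per sample, builds fragment-extended binned coverage for IP and input,
## and writes the input-subtracted tracks as bedGraph. The key readout:
## the spike-in-normalized genome-wide IP mean tracks the true bulk
## H3K27me3 level, the library-size-normalized one does not.

suppressMessages(library(polyspread))

exp <- readRDS("results/data/experiment.rds")
outdir <- "results/tracks"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tracks <- list()
rows <- list()
for (nm in names(exp$samples)) {
  s <- exp$samples[[nm]]
  f_spike <- compute_scaling_factor(s, "spikein")
  f_lib <- compute_scaling_factor(s, "libsize")
  ip <- build_coverage(s$ip_target, 200, 50, f_spike)
  f_in <- structure(list(alpha = 1e6 / s$input_target$n_reads,
                         basis = "libsize"), class = "scaling_factor")
  input <- build_coverage(s$input_target, 200, 50, f_in)
  net <- subtract_input(ip, input)
  tracks[[nm]] <- list(ip = ip, net = net)
  write_bedgraph(net, file.path(outdir, paste0(nm, ".net.bedgraph")))
  ip_lib <- build_coverage(s$ip_target, 200, 200, f_lib)
  rows[[nm]] <- data.frame(
    sample = nm,
    alpha_spikein = f_spike$alpha,
    alpha_libsize = f_lib$alpha,
    global_mean_spikein = track_mean(ip),
    global_mean_libsize = track_mean(ip_lib),
    true_global_level = exp$configs[[s$condition]]$global_level)
}
saveRDS(tracks, "results/tracks/tracks.rds")

tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write_tsv(tab, file.path(outdir, "scaling_summary.tsv"))
print(tab, digits = 3)

k27 <- tab[grepl("H3K27me3", tab$sample), ]
message(sprintf(
  "Spike-in-normalized global H3K27me3 means scale as %s (bulk levels %s;\n",
  paste(signif(k27$global_mean_spikein / k27$global_mean_spikein[1], 2),
        collapse = " : "),
  paste(k27$true_global_level, collapse = " : ")),
  "the genome-wide mean drops further than the bulk level because the ",
  "spreading-deficient\nconditions also lose their boundary-tail signal ",
  "mass). Library-size normalization pins\nevery sample to the same ",
  "scale and hides the loss entirely.")
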