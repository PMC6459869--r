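mk_peak_df <- function(chrom, start, end, name, nlp = 2) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = 0, strand = "*", signal = 1, neg_log10_p = nlp,
             neg_log10_q = 0, summit = 0, stringsAsFactors = FALSE)
}

test_that("target selection keeps passing SUZ12 peaks overlapping RING1B", {
  suz <- mk_peak_df("c1", c(100, 300), c(200, 400), c("s1", "s2"))
  ring <- mk_peak_df("c1", 150, 250, "r1")
  out <- select_target_regions(suz, ring)
  expect_equal(out$region_id, "s1")
  expect_equal(out$start, 100)   # SUZ12 span defines the region
  expect_equal(out$end, 200)
  expect_equal(out$partner, "r1")
  expect_equal(out$overlap_bp, 50)

  ## failing the p cutoff excludes a peak even when it overlaps
  suz$neg_log10_p <- c(0.5, 2)
  expect_equal(nrow(select_target_regions(suz, ring)), 0)
})

test_that("selection matches the brute-force all-pairs oracle", {
  set.seed(17)
  suz <- random_peaks(1000)
  ring <- random_peaks(1000)
  ring$name <- sprintf("rb%04d", seq_len(nrow(ring)))
  got <- select_target_regions(suz, ring)
  want <- brute_force_targets(suz, ring)
  expect_equal(got$region_id, want$name)
  expect_equal(got$start, want$start)
  expect_equal(got$partner, want$partner)
  expect_equal(got$overlap_bp, want$overlap_bp)
})

test_that("flank windows abut the peak and respect gene orientation", {
  reg <- data.frame(chrom = "c1", start = 5000, end = 7000,
                    region_id = "x", gene_strand = "+",
                    stringsAsFactors = FALSE)
  fl <- spreading_flanks(reg, 1200)
  expect_equal(fl$out5, c(3800, 5000))
  expect_equal(fl$out3, c(7000, 8200))
  expect_false(fl$clipped)
  ## minus-strand gene swaps the labels
  reg$gene_strand <- "-"
  fl2 <- spreading_flanks(reg, 1200)
  expect_equal(fl2$out5, c(7000, 8200))
  expect_equal(fl2$out3, c(3800, 5000))
  ## genomic orientation ignores the gene
  fl3 <- spreading_flanks(reg, 1200, orientation = "genomic")
  expect_equal(fl3$out5, c(3800, 5000))
  ## widths sum to 2 * flank_bp when unclipped, and never overlap inside
  expect_equal(diff(fl$out5) + diff(fl$out3), 2 * 1200)
  expect_true(fl$out5[2] <= fl$inside[1] || fl$out5[1] >= fl$inside[2])
})

test_that("flanks clip at chromosome ends and are flagged", {
  reg <- data.frame(chrom = "c1", start = 500, end = 1500,
                    region_id = "x", gene_strand = NA_character_,
                    stringsAsFactors = FALSE)
  fl <- spreading_flanks(reg, 1200, chrom_length = 10000)
  expect_equal(fl$out5, c(0, 500))
  expect_true(fl$clipped)
  fr <- spreading_flanks(data.frame(chrom = "c1", start = 9000,
                                    end = 9800, region_id = "y",
                                    stringsAsFactors = FALSE),
                         1200, chrom_length = 10000)
  expect_equal(fr$out3, c(9800, 10000))
  expect_true(fr$clipped)
})

test_that("promoter assignment picks the nearest TSS with a stable tie rule", {
  peaks <- mk_peak_df("c1", 500, 1500, "p")  # center 1000
  genes <- data.frame(chrom = "c1", start = c(1200, 5000), end = c(3000, 7000),
                      gene_id = c("gB", "gA"), score = 0,
                      strand = c("+", "+"), tss = c(1200, 5000),
                      stringsAsFactors = FALSE)
  out <- assign_promoters(peaks, genes, window_bp = 2500)
  expect_equal(out$gene_id, "gB")
  ## nothing in window
  out2 <- assign_promoters(peaks, genes[2, ], window_bp = 2500)
  expect_true(is.na(out2$gene_id))
  ## equidistant: lexicographically smaller id wins
  genes3 <- data.frame(chrom = "c1", start = c(800, 1200),
                       end = c(900, 1300), gene_id = c("gZ", "gA"),
                       score = 0, strand = "+", tss = c(800, 1200),
                       stringsAsFactors = FALSE)
  out3 <- assign_promoters(peaks, genes3, window_bp = 2500)
  expect_equal(out3$gene_id, "gA")
})

test_that("stratification rules: PcG precedence, exhaustive partition", {
  ## 0 over [0, 10 kb), 4 over [10, 20 kb)
  track <- toy_track(rep(c(0, 4), each = 200), binsize = 50, L = 20000)
  genes <- data.frame(chrom = "chrA",
                      start = c(100, 12600, 600),
                      end = c(500, 13000, 900),
                      gene_id = c("g1", "g2", "g3"), score = 0,
                      strand = "+", tss = c(100, 12600, 600),
                      stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "chrA", start = 50, end = 700,
                        region_id = "R", stringsAsFactors = FALSE)
  ## g1 and g3 promoters overlap the region -> PcG even with K36 signal
  out <- stratify_genes(genes, regions, track, "absolute", threshold = 1)
  expect_equal(as.character(out$stratum), c("PcG", "K36pos", "PcG"))
  expect_equal(sum(table(out$stratum)), nrow(genes))  # partition
  ## flat-zero track: all non-PcG genes are K36neg under the median rule
  zero <- toy_track(rep(0, 400), binsize = 50, L = 20000)
  out2 <- stratify_genes(genes, regions, zero, "median")
  expect_equal(as.character(out2$stratum), c("PcG", "K36neg", "PcG"))
})

test_that("the active gene fraction is recovered from simulated H3K36me3", {
  exp <- fixture_experiment()
  s <- exp$samples$wt.H3K36me3
  f_in <- structure(list(alpha = 1e6 / s$input_target$n_reads,
                         basis = "libsize"), class = "scaling_factor")
  k36 <- subtract_input(
    build_coverage(s$ip_target, 200, 50,
                   compute_scaling_factor(s, "libsize")),
    build_coverage(s$input_target, 200, 50, f_in))
  regions <- select_target_regions(exp$peaks, exp$ring1b)
  out <- stratify_genes(exp$genes, regions, k36)
  nonpcg <- out[out$stratum != "PcG", ]
  frac <- mean(nonpcg$stratum == "K36pos")
  expect_equal(frac, 0.4, tolerance = 0.05 / 0.4)
  ## recovered labels agree with the hidden truth flags
  agree <- mean((nonpcg$stratum == "K36pos") == nonpcg$active)
  expect_gt(agree, 0.95)
})
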