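test_that("reference-point matrix has exact geometry and strand symmetry", {
  tr <- toy_track(seq_len(400), binsize = 50)  # ramp, L = 20000
  anchors <- data.frame(chrom = "chrA", tss = c(6000, 6000),
                        strand = c("+", "-"), gene_id = c("gp", "gm"),
                        stringsAsFactors = FALSE)
  m <- reference_point_matrix(tr, anchors, window_bp = 5000, binsize = 50)
  expect_equal(m$n_bins, 200)  # TSS +/- 5 kb at 50 bp
  ## minus-strand row is the reverse of the plus-strand row
  expect_equal(m$values["gm", ], rev(m$values["gp", ]))
  ## reversing twice is the identity
  expect_equal(rev(rev(m$values["gm", ])), m$values["gm", ])
  expect_error(reference_point_matrix(tr, anchors, 5000, 33), "divide")

  cm <- reference_point_matrix(toy_track(rep(3, 400)), anchors, 5000, 50)
  expect_true(all(cm$values == 3))            # constant track
  expect_equal(unname(colMeans(cm$values)), rep(3, 200))
})

test_that("out-of-chromosome bins are zero-filled and flagged", {
  tr <- toy_track(rep(2, 100), binsize = 50)  # L = 5000
  anchors <- data.frame(chrom = "chrA", tss = c(1000, 2500),
                        strand = "+", gene_id = c("edge", "ok"),
                        stringsAsFactors = FALSE)
  m <- reference_point_matrix(tr, anchors, window_bp = 2500, binsize = 50)
  expect_true(m$flagged[1] && !m$flagged[2])
  expect_equal(unname(m$values["edge", 1:30]), rep(0, 30))  # [-1500, 0)
  expect_true(all(m$values["ok", ] == 2))
})

test_that("scale-regions matrix resamples bodies independent of length", {
  ## step track: 0 before 10000, 4 after
  tr <- toy_track(rep(c(0, 4), each = 200), binsize = 50)  # L = 20000
  mk_gene <- function(s, e, id) {
    data.frame(chrom = "chrA", start = s, end = e, gene_id = id,
               score = 0, strand = "+", tss = s, stringsAsFactors = FALSE)
  }
  ## both genes centered on the step; body lengths 2 kb and 8 kb
  g <- rbind(mk_gene(9000, 11000, "short"), mk_gene(6000, 14000, "long"))
  m <- scale_regions_matrix(tr, g, body_bins = 100, flank_bp = 1000,
                            binsize = 50)
  expect_equal(m$n_bins, 140)  # 100 body + 2 * 20 flank columns
  body <- 21:120
  for (id in c("short", "long")) {
    expect_equal(unname(m$values[id, body[1:50]]), rep(0, 50))
    expect_equal(unname(m$values[id, body[51:100]]), rep(4, 50))
  }
  expect_error(scale_regions_matrix(tr, g, 100, 1000, 33), "divide")
  ## constant track stays constant after length normalization
  cm <- scale_regions_matrix(toy_track(rep(2, 400)), g, 100, 1000, 50)
  expect_true(all(cm$values == 2))
})

test_that("shared min-max scaling has unit pooled range and keeps order", {
  m1 <- new_pm(matrix(c(1, 2, 3, 5), 2))
  m2 <- new_pm(matrix(c(2, 2.5, 4, 4.5), 2))
  out <- minmax_normalize(list(m1, m2))
  pooled <- unlist(lapply(out, function(m) m$values))
  expect_equal(max(pooled) - min(pooled), 1)       # range = 1
  expect_equal(out[[1]]$minmax_factor, 1 / (5 - 1))  # 1/(max - min)
  ## monotone map: every pairwise ordering preserved
  before <- unlist(lapply(list(m1, m2), function(m) m$values))
  expect_equal(order(pooled), order(before))
  ## already unit-range single matrix is unchanged
  u <- new_pm(matrix(c(0, 1, 0.3, 0.7), 2))
  expect_equal(minmax_normalize(list(u))[[1]]$values, u$values)
  expect_warning(minmax_normalize(list(new_pm(matrix(1, 2, 2)))),
                 "constant")
})

test_that("region ranking is deterministic under ties", {
  expect_equal(rank_regions(c("a", "b", "c"), c(3, 1, 2)), c(1, 3, 2))
  expect_equal(rank_regions(c("a", "b", "c"), c(3, 1, 2),
                            "by_signal_asc"), c(2, 3, 1))
  expect_equal(rank_regions(c("a", "b", "c"), c(1, 1, 1)), 1:3)
  set.seed(53)
  sig <- runif(1000)
  ids <- sprintf("r%04d", 1:1000)
  expect_equal(rank_regions(ids, sig), order(-sig, ids))  # sort oracle
})

test_that("promoter intensity summary is consistent and discriminates", {
  tr <- fixture_track("wt.H3K27me3", "ip", "spikein")
  exp <- fixture_experiment()
  g <- exp$genes
  groups <- ifelse(startsWith(g$gene_id, "gP"), "PcG", "background")
  res <- promoter_intensity_summary(tr, g, groups, window_bp = 2500)
  ## mean over the TSS window equals region_density on that interval
  i <- which(groups == "PcG")[1]
  expect_equal(res$values$PcG[1],
               region_density(tr, g$chrom[i], g$tss[i] - 2500,
                              g$tss[i] + 2500))
  ## Polycomb promoters carry H3K27me3; background promoters do not
  cmp <- res$comparisons[["PcG vs background"]]
  expect_lt(cmp$p_value, 0.01)
  expect_gt(median(res$values$PcG), median(res$values$background))
  ## identical groups compare at p = 1
  same <- promoter_intensity_summary(
    tr, rbind(g[i, ], g[i, ], g[i, ], g[i, ]),
    c("x", "x", "y", "y"))
  expect_equal(same$comparisons[["x vs y"]]$p_value, 1)
  ## tiny group flagged and skipped
  one <- promoter_intensity_summary(tr, g[1:3, ], c("a", "a", "b"))
  expect_equal(one$flagged_groups, "b")
  expect_length(one$comparisons, 0)
})
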