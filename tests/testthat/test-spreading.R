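test_that("region density averages per-bp signal with partial-bin weights", {
  tr <- toy_track(rep(2, 10), binsize = 50)
  expect_equal(region_density(tr, "chrA", 13, 471), 2)  # constant track
  tr2 <- toy_track(c(4, 0), binsize = 50)
  expect_equal(region_density(tr2, "chrA", 25, 75), 2)  # half high, half 0
  expect_error(region_density(tr, "chrA", 100, 100), "empty")
  expect_error(region_density(tr, "chrA", 400, 600), "bounds")
  expect_error(region_density(tr, "chrB", 0, 10), "chromosome")
})

test_that("region density equals the per-bp expansion oracle", {
  set.seed(19)
  tr <- toy_track(runif(200), binsize = 37, L = 200 * 37 - 11)
  for (i in 1:500) {
    s <- floor(runif(1, 0, 7000))
    e <- s + 1 + floor(runif(1, 0, 380))
    expect_equal(region_density(tr, "chrA", s, e),
                 density_oracle(tr, "chrA", s, e), tolerance = 1e-9)
  }
})

test_that("spreading table flags clipped regions and bounds null ratios", {
  tr <- toy_track(rep(0, 200), binsize = 50)  # null track
  regions <- data.frame(chrom = "chrA", start = c(500, 4000),
                        end = c(2500, 6000), region_id = c("a", "b"),
                        gene_strand = NA_character_,
                        stringsAsFactors = FALSE)
  tab <- spreading_table(tr, regions, flank_bp = 1200)
  expect_equal(tab$clipped, c(TRUE, FALSE))
  expect_equal(tab$ratio5, c(1, 1))  # pseudocount keeps 0/0 defined
  expect_equal(tab$in_out3, c(1, 1))
})

test_that("confined domains give near-zero out/in ratios", {
  cfg <- sim_config(genome_length = 4e5, n_chroms = 1, n_peaks = 12,
                    peak_width_range = c(3000, 6000), decay_length = 0,
                    enrichment = 50, ip_depth = 3e5, n_genes = 0,
                    seed = 23)
  exp <- simulate_experiment(list(ko = cfg))
  s <- exp$samples$ko.H3K27me3
  tr <- build_coverage(s$ip_target, 200, 50,
                       compute_scaling_factor(s, "spikein"))
  regs <- select_target_regions(exp$peaks, exp$ring1b)
  tab <- spreading_table(tr, regs, 1200)
  expect_lt(median(c(tab$ratio5, tab$ratio3)), 0.1)
})

test_that("pseudocount halving/doubling barely moves the median ratio", {
  exp <- fixture_experiment()
  tr <- fixture_track("wt.H3K27me3", "ip", "spikein")
  regs <- select_target_regions(exp$peaks, exp$ring1b)
  meds <- sapply(c(0.005, 0.01, 0.02), function(eps) {
    tab <- spreading_table(tr, regs, 1200, pseudocount = eps)
    median(tab$ratio5[!tab$clipped])
  })
  expect_lt(abs(meds[1] / meds[2] - 1), 0.01)
  expect_lt(abs(meds[3] / meds[2] - 1), 0.01)
})

test_that("pooled t-test matches the closed-form two-sample formula", {
  r <- compare_densities(c(1, 2, 3), c(1, 2, 3), "student_t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- compare_densities(c(1, 2, 3), c(2, 3, 4), "student_t")
  expect_equal(r2$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r2$df, 4)
  expect_equal(r2$p_value, 0.2878641, tolerance = 1e-6)
  ## frozen from the pooled-variance formula:
  ## sp2 = 1, t = -1 / sqrt(2/3), p = 2 * pt(t, 4)
})

test_that("rank-sum p equals exact enumeration for small groups", {
  cases <- list(list(a = c(1, 2), b = c(10, 11)),
                list(a = c(5, 1, 7), b = c(2, 9)),
                list(a = c(3, 8, 2, 14), b = c(6, 1, 11, 4)))
  for (cs in cases) {
    got <- compare_densities(cs$a, cs$b, "wilcoxon")
    expect_equal(got$p_value, ranksum_exact_oracle(cs$a, cs$b))
  }
  ## fully tied pooled sample: p = 1 by convention
  expect_equal(compare_densities(c(2, 2), c(2, 2), "wilcoxon")$p_value, 1)
})

test_that("ratio correlation reproduces the normal-equations fit", {
  a <- c(1, 2, 3, 4)
  expect_equal(ratio_correlation(a, a)$slope, 1)
  expect_equal(ratio_correlation(a, a)$r_squared, 1)
  expect_equal(ratio_correlation(a, -a + 5)$r, -1)
  expect_error(ratio_correlation(rep(1, 4), a), "variance")
  set.seed(29)
  x <- runif(50); y <- 0.7 * x + rnorm(50, 0, 0.1)
  got <- ratio_correlation(x, y)
  want <- normal_equations_oracle(x, y)
  expect_equal(got$slope, want$slope, tolerance = 1e-9)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-9)
  expect_equal(got$r, want$r, tolerance = 1e-9)
  expect_equal(got$r_squared, got$r^2, tolerance = 1e-12)
})

test_that("top fraction selects best scores with deterministic ties", {
  rec <- data.frame(region_id = sprintf("r%02d", 1:10),
                    stringsAsFactors = FALSE)
  set.seed(37)
  sc <- runif(10)
  out <- top_fraction(rec, sc, 0.2)
  expect_equal(nrow(out), 2)
  full <- rec[order(-sc, rec$region_id), , drop = FALSE]
  expect_equal(out$region_id, full$region_id[1:2])  # sort oracle
  expect_equal(top_fraction(rec, sc, 1)$region_id, full$region_id)
  tied <- top_fraction(rec, rep(1, 10), 0.3)
  expect_equal(tied$region_id, c("r01", "r02", "r03"))
})

test_that("Poisson enrichment score matches direct tail summation", {
  mk <- function(v, n_reads, L = 5000) {
    t <- toy_track(v, binsize = 50, L = L)
    t$n_reads <- n_reads; t$fragment_length <- 200; t$scaled <- FALSE
    t
  }
  ## observed = expected = 10: upper tail including obs
  ip <- mk(rep(10 * 200 / 1000, 100), n_reads = 100)
  input <- mk(rep(10 * 200 / 1000, 100), n_reads = 100)
  s <- promoter_enrichment_score(ip, input, "chrA", 2000, 3000)
  expect_equal(10^(-s), 1 - ppois(9, 10), tolerance = 1e-12)
  expect_equal(10^(-s), 0.5420703, tolerance = 1e-6)
  ## observed 0 with lambda floor 1: p = 1
  ip0 <- mk(rep(0, 100), n_reads = 100)
  in0 <- mk(rep(0, 100), n_reads = 100)
  expect_equal(promoter_enrichment_score(ip0, in0, "chrA", 0, 1000), 0)
  ## observed 25 vs lambda 5: direct pmf summation oracle
  ip25 <- mk(rep(25 * 200 / 1000, 100), n_reads = 500)
  in5 <- mk(rep(5 * 200 / 1000, 100), n_reads = 500)
  s2 <- promoter_enrichment_score(ip25, in5, "chrA", 2000, 3000)
  expect_equal(10^(-s2), poisson_tail_oracle(25, 5), tolerance = 1e-10)
  expect_error(promoter_enrichment_score(ip, input, "chrA", 10, 10),
               "zero-length")
})

test_that("expected spreading ratio increases strictly with decay length", {
  meds <- sapply(c(0, 300, 600, 1200, 2400), function(lam) {
    cfg <- sim_config(genome_length = 6e5, n_chroms = 1, n_peaks = 18,
                      peak_width_range = c(3000, 6000),
                      decay_length = lam, decay_sdlog = 0,
                      enrichment = 200, ip_depth = 4e5, n_genes = 0,
                      seed = 47)
    exp <- simulate_experiment(list(x = cfg))
    s <- exp$samples$x.H3K27me3
    tr <- build_coverage(s$ip_target, 200, 50,
                         compute_scaling_factor(s, "spikein"))
    regs <- select_target_regions(exp$peaks, exp$ring1b)
    tab <- spreading_table(tr, regs, 1200)
    median(c(tab$ratio5, tab$ratio3)[!tab$clipped])
  })
  expect_true(all(diff(meds) > 0))
})
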