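## Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

## A desk-scale two-condition ChIP-Rx experiment with genes, reused by
## the regions / spreading / profiles tests.
fixture_experiment <- function() {
  if (is.null(.fixture_env$exp)) {
    base <- sim_config(genome_length = 1.5e6, n_chroms = 2, n_peaks = 25,
                       peak_width_range = c(2000, 5000),
                       decay_length = 1200, decay_sdlog = 0.5,
                       enrichment = 50, ip_depth = 3e5, input_depth = 4e5,
                       spikein_depth = 5e4, spike_genome_length = 5e4,
                       n_genes = 200, frac_active = 0.4, seed = 42)
    .fixture_env$exp <- simulate_experiment(
      list(wt = base,
           ko = update_config(base, decay_length = 0, global_level = 0.3,
                              seed = 43)))
  }
  .fixture_env$exp
}

fixture_track <- function(sample_name = "wt.H3K27me3",
                          component = "ip", basis = "spikein") {
  key <- paste(sample_name, component, basis, sep = "/")
  if (is.null(.fixture_env$tracks)) .fixture_env$tracks <- list()
  if (is.null(.fixture_env$tracks[[key]])) {
    exp <- fixture_experiment()
    s <- exp$samples[[sample_name]]
    f <- compute_scaling_factor(s, basis)
    ip <- build_coverage(s$ip_target, 200, 50, f)
    tr <- if (component == "ip") ip else {
      fin <- structure(list(alpha = 1e6 / s$input_target$n_reads,
                            basis = "libsize"), class = "scaling_factor")
      subtract_input(ip, build_coverage(s$input_target, 200, 50, fin))
    }
    .fixture_env$tracks[[key]] <- tr
  }
  .fixture_env$tracks[[key]]
}

## A small deterministic track for arithmetic tests.
toy_track <- function(values, binsize = 50, L = length(values) * binsize) {
  coverage_track(list(chrA = values), binsize,
                 c(chrA = L), scaled = TRUE)
}

new_pm <- function(m) {
  polyspread:::new_profile_matrix(m, 50, "reference_point",
                                  rep(FALSE, nrow(m)))
}

withr_tempfile <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

random_peaks <- function(n, chroms = c("c1", "c2"), L = 1e6,
                         width = c(200, 2000)) {
  s <- floor(runif(n, 0, L - width[2]))
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = s,
    end = s + floor(runif(n, width[1], width[2])),
    name = sprintf("pk%04d", seq_len(n)),
    score = 0, strand = "*", signal = 1,
    neg_log10_p = runif(n, 0, 4),
    neg_log10_q = 0, summit = 0,
    stringsAsFactors = FALSE
  )
}
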