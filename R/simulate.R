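#' Relative enrichment of a spreading mark beyond a domain boundary
#'
#' The boundary-decay kernel of the simulator: inside a domain the relative
#' enrichment is 1; at `distance_bp` beyond the boundary it decays
#' exponentially with length scale `decay_length` (lambda). `lambda = 0`
#' models a fully confined mark (0 beyond the boundary), `lambda = Inf` a
#' mark that spreads without attenuation.
#'
#' @param distance_bp distance beyond the domain edge in bp (>= 0);
#'   vectorized.
#' @param decay_length lambda of the exponential kernel in bp (>= 0).
#' @return relative enrichment in `[0, 1]`.
#' @examples
#' spreading_profile(600, 600)  # exp(-1)
#' @export
spreading_profile <- function(distance_bp, decay_length) {
  if (any(distance_bp < 0)) {
    stop("spreading_profile: distance must be >= 0", call. = FALSE)
  }
  if (decay_length < 0) {
    stop("spreading_profile: decay_length must be >= 0", call. = FALSE)
  }
  if (decay_length == 0) {
    return(ifelse(distance_bp > 0, 0, 1))
  }
  exp(-distance_bp / decay_length)
}

#' Expected out/in density ratio over a boundary flank
#'
#' Closed form of the mean of the exponential boundary kernel over a flank
#' `[0, F]`, relative to a saturated inside density:
#' `(lambda/F) * (1 - exp(-F/lambda))`. This is the analytic expectation the
#' simulator's truth table stores and against which the empirical spreading
#' ratio is checked.
#'
#' @param decay_length lambda in bp (vectorized; 0 gives 0, `Inf` gives 1).
#' @param flank_bp flank width F in bp (> 0).
#' @return expected out/in ratio in `[0, 1]`.
#' @export
flank_ratio_expected <- function(decay_length, flank_bp) {
  stopifnot(flank_bp > 0)
  r <- ifelse(decay_length == 0, 0,
              (decay_length / flank_bp) *
                (1 - exp(-flank_bp / decay_length)))
  ifelse(is.infinite(decay_length), 1, r)
}

#' Simulation configuration for one condition
#'
#' Defaults emulate a desk-scale ChIP-Rx experiment on an abundant,
#' broadly-domained histone mark: a 2 Mb target genome carrying 60
#' Polycomb-like domains whose boundary spreading has median decay length
#' 6 kb with per-domain lognormal heterogeneity, 80-fold enrichment over
#' captured background at domain centers, and a constant amount of
#' exogenous spike-in chromatin.
#'
#' @param genome_length total target genome length in bp.
#' @param n_chroms number of target chromosomes (named `t_1`, `t_2`, ...).
#' @param n_peaks number of enrichment domains (SUZ12-like peaks).
#' @param peak_width_range min/max domain width in bp.
#' @param decay_length median boundary decay length lambda in bp; 0 models
#'   a spreading-deficient condition.
#' @param decay_sdlog sdlog of the per-domain lognormal multiplier on
#'   `decay_length` (0 = identical lambda everywhere). The multipliers are
#'   part of the shared layout, so conditions are paired per domain.
#' @param enrichment fold enrichment over background capture at domain
#'   centers.
#' @param global_level multiplicative bulk-signal factor in `[0, 1]`
#'   (1 = wild-type level); scales the enrichment term only, and the
#'   realized target-genome yield with it, which is what makes the factor
#'   recoverable only through the constant spike-in material.
#' @param background_rate optional reads per bp of background; when `NULL`
#'   (default) the background level is set so that the reference condition
#'   yields `ip_depth` target reads.
#' @param ip_depth expected IP target-genome reads for the reference
#'   condition (the first config passed to [simulate_experiment()]).
#' @param input_depth expected input target-genome reads.
#' @param spikein_depth expected spike-in reads per library; constant
#'   across conditions by construction.
#' @param spike_genome_length length of the exogenous genome (`s_1`).
#' @param n_genes number of gene models (0 disables genes and the
#'   H3K36me3 sample).
#' @param frac_active fraction of non-Polycomb genes given H3K36me3
#'   gene-body signal.
#' @param gene_length_range min/max gene-body length in bp.
#' @param k36_enrichment fold enrichment of H3K36me3 over background on
#'   active gene bodies.
#' @param fragment_length sonication fragment length in bp.
#' @param read_length sequenced read length in bp.
#' @param seed RNG seed for this condition's read draws (the first
#'   config's seed also fixes the shared layout).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chroms = 2,
                       n_peaks = 60,
                       peak_width_range = c(3000, 8000),
                       decay_length = 6000,
                       decay_sdlog = 1,
                       enrichment = 80,
                       global_level = 1,
                       background_rate = NULL,
                       ip_depth = 5e5,
                       input_depth = 1e6,
                       spikein_depth = 2e5,
                       spike_genome_length = 2e5,
                       n_genes = 250,
                       frac_active = 0.4,
                       gene_length_range = c(1000, 4000),
                       k36_enrichment = 20,
                       fragment_length = 200,
                       read_length = 36,
                       seed = 1337) {
  cfg <- list(genome_length = genome_length, n_chroms = n_chroms,
              n_peaks = n_peaks, peak_width_range = peak_width_range,
              decay_length = decay_length, decay_sdlog = decay_sdlog,
              enrichment = enrichment, global_level = global_level,
              background_rate = background_rate, ip_depth = ip_depth,
              input_depth = input_depth, spikein_depth = spikein_depth,
              spike_genome_length = spike_genome_length,
              n_genes = n_genes, frac_active = frac_active,
              gene_length_range = gene_length_range,
              k36_enrichment = k36_enrichment,
              fragment_length = fragment_length, read_length = read_length,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(genome_length > 0, n_chroms >= 1, n_peaks >= 0,
              length(peak_width_range) == 2,
              peak_width_range[1] <= peak_width_range[2],
              decay_length >= 0, decay_sdlog >= 0, enrichment >= 1,
              input_depth >= 0, spikein_depth >= 0, ip_depth >= 0,
              n_genes >= 0, frac_active >= 0, frac_active <= 1,
              fragment_length >= read_length, read_length > 0,
              seed == round(seed))
    if (global_level < 0 || global_level > 1) {
      stop("sim_config: global_level must lie in [0, 1]", call. = FALSE)
    }
    if (peak_width_range[1] < 100) {
      stop("sim_config: peak widths must be at least twice the default ",
           "50 bp bin", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Update fields of a simulation configuration
#' @param cfg a [sim_config()].
#' @param ... fields to replace.
#' @return a new validated `sim_config`.
#' @export
update_config <- function(cfg, ...) {
  new <- list(...)
  bad <- setdiff(names(new), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(new)] <- new
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Standard condition set: wild type, spreading-deficient, null
#'
#' Wild type keeps the base configuration. The EZH2-KO-like condition
#' retains domains but loses boundary spreading (`decay_length = 0`) and
#' drops bulk signal to 30% of wild type; the dKO-like null condition has
#' no signal at all (`global_level = 0`).
#'
#' @param base a [sim_config()] for the wild-type condition.
#' @return named list of three `sim_config`s (`wt`, `ezh2ko`, `dko`).
#' @export
default_conditions <- function(base = sim_config()) {
  list(
    wt = base,
    ezh2ko = update_config(base, decay_length = 0, global_level = 0.3,
                           seed = base$seed + 1),
    dko = update_config(base, decay_length = 0, global_level = 0,
                        seed = base$seed + 2)
  )
}

## ---- layout -------------------------------------------------------------

target_chrom_lengths <- function(cfg) {
  L <- floor(cfg$genome_length / cfg$n_chroms)
  lens <- rep(L, cfg$n_chroms)
  lens[cfg$n_chroms] <- cfg$genome_length - L * (cfg$n_chroms - 1)
  setNames(lens, paste0("t_", seq_len(cfg$n_chroms)))
}

## Draw the condition-shared layout (peaks, decay multipliers, genes) from
## the reference config's seed. Domains are laid out on an even grid with
## jitter so that neighbouring domains never overlap.
simulate_layout <- function(cfg) {
  set.seed(cfg$seed)
  lens <- target_chrom_lengths(cfg)
  n_per <- diff(round(cumsum(c(0, lens)) / sum(lens) * cfg$n_peaks))
  peaks <- list()
  for (k in seq_along(lens)) {
    n <- n_per[k]
    if (n == 0) next
    L <- lens[[k]]
    slot <- L / n
    centers <- ((seq_len(n) - 0.5) + runif(n, -0.1, 0.1)) * slot
    w <- round(runif(n, cfg$peak_width_range[1], cfg$peak_width_range[2]))
    start <- pmax(round(centers - w / 2), 200)
    end <- pmin(start + w, L - 200)
    peaks[[k]] <- data.frame(chrom = names(lens)[k], start = start,
                             end = end, stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peaks)
  np <- nrow(peaks)
  peaks$name <- sprintf("P%04d", seq_len(np))
  pass <- runif(np) < 0.9
  peaks$neg_log10_p <- ifelse(pass, runif(np, 1.5, 8), runif(np, 0.2, 0.9))
  peaks$score <- round(10 * peaks$neg_log10_p)
  peaks$strand <- "*"
  peaks$signal <- cfg$enrichment
  peaks$neg_log10_q <- peaks$neg_log10_p
  peaks$summit <- floor((peaks$end - peaks$start) / 2)
  peaks$decay_scale <- if (cfg$decay_sdlog > 0) {
    exp(rnorm(np, 0, cfg$decay_sdlog))
  } else rep(1, np)

  ## RING1B evidence: the same domains, shifted by a quarter width in
  ## alternating directions (still overlapping), plus a few decoys in gaps.
  shift <- round(0.25 * (peaks$end - peaks$start)) *
    rep_len(c(1L, -1L), np)
  ring1b <- data.frame(
    chrom = peaks$chrom,
    start = pmax(peaks$start + shift, 0),
    end = peaks$end + shift,
    name = sprintf("R%04d", seq_len(np)),
    score = round(10 * runif(np, 1.5, 8)),
    strand = "*", signal = 10,
    neg_log10_p = runif(np, 1.5, 8),
    neg_log10_q = runif(np, 1.5, 8),
    summit = floor((peaks$end - peaks$start) / 2),
    stringsAsFactors = FALSE
  )
  n_decoy <- max(1, round(0.05 * np))
  decoy_after <- which(diff(c(peaks$start, Inf)) > 8000 &
                         peaks$chrom == c(peaks$chrom[-1],
                                          peaks$chrom[np]))[seq_len(n_decoy)]
  decoy_after <- decoy_after[!is.na(decoy_after)]
  if (length(decoy_after)) {
    mid <- round((peaks$end[decoy_after] + peaks$start[decoy_after + 1]) / 2)
    ring1b <- rbind(ring1b, data.frame(
      chrom = peaks$chrom[decoy_after], start = mid - 500, end = mid + 500,
      name = sprintf("Rdecoy%02d", seq_along(decoy_after)),
      score = 30, strand = "*", signal = 10,
      neg_log10_p = runif(length(decoy_after), 1.5, 8),
      neg_log10_q = runif(length(decoy_after), 1.5, 8),
      summit = 500, stringsAsFactors = FALSE))
  }

  genes <- simulate_genes(cfg, lens, peaks)
  list(chrom_lengths = lens, peaks = peaks, ring1b = ring1b, genes = genes)
}

## Genes: ~15% are Polycomb targets with their TSS inside a domain (never
## transcriptionally active); the rest sit in inter-domain background and
## are active (H3K36me3-marked gene body) with probability frac_active.
simulate_genes <- function(cfg, lens, peaks) {
  if (cfg$n_genes == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), gene_id = character(),
                      score = numeric(), strand = character(),
                      tss = numeric(), active = logical(),
                      stringsAsFactors = FALSE))
  }
  np <- nrow(peaks)
  n_pcg <- min(np, round(0.15 * cfg$n_genes))
  rows <- list()
  if (n_pcg > 0) {
    idx <- seq_len(n_pcg)
    center <- floor((peaks$start[idx] + peaks$end[idx]) / 2)
    strand <- sample(c("+", "-"), n_pcg, replace = TRUE)
    len <- round(runif(n_pcg, cfg$gene_length_range[1],
                       cfg$gene_length_range[2]))
    tss <- center
    start <- ifelse(strand == "+", tss, tss - len + 1)
    end <- start + len
    L <- lens[peaks$chrom[idx]]
    start <- pmax(start, 0); end <- pmin(end, L)
    rows$pcg <- data.frame(chrom = peaks$chrom[idx], start = start,
                           end = end,
                           gene_id = sprintf("gP%04d", idx), score = 0,
                           strand = strand,
                           tss = ifelse(strand == "+", start, end - 1),
                           active = FALSE, stringsAsFactors = FALSE)
  }
  n_bg <- cfg$n_genes - n_pcg
  if (n_bg > 0) {
    ## background genes keep clear of domains (promoter window + decay
    ## margin) and of each other: gene bodies never overlap
    placed <- if (n_pcg > 0) {
      rows$pcg[, c("chrom", "start", "end")]
    } else data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
    acc_ch <- character(0); acc_s <- numeric(0); acc_e <- numeric(0)
    acc_strand <- character(0)
    tries <- 0
    while (length(acc_ch) < n_bg && tries < 50 * n_bg) {
      tries <- tries + 1
      ch <- sample(names(lens), 1, prob = lens / sum(lens))
      L <- lens[[ch]]
      len <- round(runif(1, cfg$gene_length_range[1],
                         cfg$gene_length_range[2]))
      s <- floor(runif(1, 3000, L - len - 3000))
      e <- s + len
      p <- peaks[peaks$chrom == ch, , drop = FALSE]
      if (nrow(p) > 0 && any(s < p$end + 4000 & e > p$start - 4000)) next
      prev_s <- c(placed$start[placed$chrom == ch],
                  acc_s[acc_ch == ch])
      prev_e <- c(placed$end[placed$chrom == ch],
                  acc_e[acc_ch == ch])
      if (length(prev_s) && any(s < prev_e + 200 & e > prev_s - 200)) next
      acc_ch <- c(acc_ch, ch); acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
      acc_strand <- c(acc_strand, sample(c("+", "-"), 1))
    }
    if (length(acc_ch) < n_bg) {
      stop("simulate_genes: could not place background genes; ",
           "genome too crowded", call. = FALSE)
    }
    rows$bg <- data.frame(chrom = acc_ch, start = acc_s, end = acc_e,
                          gene_id = sprintf("gB%04d", seq_len(n_bg)),
                          score = 0, strand = acc_strand,
                          tss = ifelse(acc_strand == "+", acc_s,
                                       acc_e - 1),
                          active = as.logical(rbinom(n_bg, 1,
                                                     cfg$frac_active)),
                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- read drawing -------------------------------------------------------

## Per-chromosome relative-enrichment profile s(x): 1 inside each domain,
## exponential tail beyond each boundary; contributions of nearby domains
## add. Evaluated at per-bp resolution.
domain_profiles <- function(lens, peaks, lambdas) {
  prof <- lapply(lens, function(L) numeric(L))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    L <- lens[[ch]]
    s <- peaks$start[i]; e <- peaks$end[i]
    prof[[ch]][(s + 1):e] <- prof[[ch]][(s + 1):e] + 1
    lam <- lambdas[i]
    if (lam > 0) {
      dmax <- min(ceiling(9.2 * lam), L)
      d <- seq_len(dmax)
      tail_v <- exp(-d / lam)
      li <- s - d      # 0-based positions s-1, s-2, ...
      keep <- li >= 0
      if (any(keep)) {
        prof[[ch]][li[keep] + 1] <- prof[[ch]][li[keep] + 1] + tail_v[keep]
      }
      ri <- e + d - 1  # 0-based positions e, e+1, ...
      keep <- ri < L
      if (any(keep)) {
        prof[[ch]][ri[keep] + 1] <- prof[[ch]][ri[keep] + 1] + tail_v[keep]
      }
    }
  }
  prof
}

## Draw single-end reads whose fragment starts follow per-bp Poisson rates.
draw_reads <- function(rate_by_chrom, lens, fragment_length, read_length) {
  out <- vector("list", length(rate_by_chrom))
  for (k in seq_along(rate_by_chrom)) {
    ch <- names(rate_by_chrom)[k]
    L <- lens[[ch]]
    lam <- rate_by_chrom[[k]]
    usable <- L - fragment_length + 1
    counts <- rpois(usable, lam[seq_len(usable)])
    tot <- sum(counts)
    if (tot == 0) next
    nz <- which(counts > 0)
    pos <- rep(nz - 1, counts[nz])
    strand <- sample(c("+", "-"), tot, replace = TRUE)
    start <- ifelse(strand == "+", pos, pos + fragment_length - read_length)
    out[[k]] <- data.frame(chrom = ch, start = start,
                           end = start + read_length, strand = strand,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

draw_uniform_reads <- function(total, lens, fragment_length, read_length) {
  rate <- lapply(lens, function(L) {
    rep(total / sum(lens), L)
  })
  names(rate) <- names(lens)
  draw_reads(rate, lens, fragment_length, read_length)
}

#' Simulate a multi-condition ChIP-Rx experiment
#'
#' All conditions share one genome layout (chromosomes, domains with their
#' per-domain decay multipliers, genes), drawn from the first config's
#' seed; each condition then draws its own reads from its own seed. Per
#' condition the generator emits an H3K27me3 ChIP-Rx sample (IP + input,
#' target + spike-in reads) and, when genes are present, an H3K36me3
#' sample sharing the condition's input.
#'
#' The IP fragment-start rate at base x is
#' `bg * (1 + (enrichment - 1) * global_level * s(x))` with `s(x)` the
#' domain profile (1 inside a domain, exponential boundary tail outside),
#' so `enrichment = 1` yields pure background. The realized target-genome
#' yield scales with the captured signal mass relative to the reference
#' condition, while spike-in reads stay at `spikein_depth` regardless —
#' the ChIP-Rx property that makes the global level recoverable.
#'
#' @param configs a named list of [sim_config()]s (or a single config);
#'   the first entry is the reference condition. Layout-defining fields
#'   must agree across conditions.
#' @param flank_bp flank width used for the analytic truth table.
#' @return an object of class `simulated_experiment` with fields
#'   `samples` (list of [chip_sample()]s named `condition.antibody`),
#'   `peaks` (SUZ12-like calls, with per-domain `decay_scale`), `ring1b`,
#'   `genes` (with the hidden `active` flag), `truth`, `chrom_lengths`,
#'   `spike_chrom_lengths`, `configs`.
#' @export
simulate_experiment <- function(configs, flank_bp = 1200) {
  if (inherits(configs, "sim_config")) configs <- list(cond = configs)
  stopifnot(length(configs) >= 1)
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    stop("simulate_experiment: configs must be a named list", call. = FALSE)
  }
  shared <- c("genome_length", "n_chroms", "n_peaks", "peak_width_range",
              "decay_sdlog", "n_genes", "frac_active", "gene_length_range",
              "fragment_length", "read_length", "spikein_depth",
              "spike_genome_length", "ip_depth", "input_depth")
  ref <- configs[[1]]
  for (nm in names(configs)[-1]) {
    for (f in shared) {
      if (!identical(configs[[nm]][[f]], ref[[f]])) {
        stop("simulate_experiment: condition '", nm, "' differs from the ",
             "reference in shared layout field '", f, "'", call. = FALSE)
      }
    }
  }

  layout <- simulate_layout(ref)
  lens <- layout$chrom_lengths
  spike_lens <- setNames(ref$spike_genome_length, "s_1")
  fl <- ref$fragment_length; rl <- ref$read_length

  ## Reference signal mass anchors the depth scaling: the reference config
  ## at full signal yields ip_depth target reads in expectation.
  ref_prof <- domain_profiles(lens, layout$peaks,
                              ref$decay_length * layout$peaks$decay_scale)
  ref_mass <- sum(lens) + (ref$enrichment - 1) * 1 *
    sum(vapply(ref_prof, sum, numeric(1)))

  active_bodies <- layout$genes[layout$genes$active, , drop = FALSE]

  samples <- list()
  truth <- list()
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    set.seed(cfg$seed)
    lambdas <- cfg$decay_length * layout$peaks$decay_scale
    prof <- if (identical(cfg$decay_length, ref$decay_length)) ref_prof
            else domain_profiles(lens, layout$peaks, lambdas)
    e <- cfg$enrichment; g <- cfg$global_level
    base_rate <- if (is.null(cfg$background_rate)) {
      cfg$ip_depth / ref_mass
    } else cfg$background_rate
    rate <- lapply(prof, function(p) base_rate * (1 + (e - 1) * g * p))

    ip_t <- read_set(draw_reads(rate, lens, fl, rl), "target", lens)
    ip_s <- read_set(draw_uniform_reads(rpois(1, cfg$spikein_depth),
                                        spike_lens, fl, rl),
                     "spikein", spike_lens)
    in_t <- read_set(draw_uniform_reads(rpois(1, cfg$input_depth),
                                        lens, fl, rl),
                     "target", lens)
    in_s <- read_set(draw_uniform_reads(rpois(1, cfg$spikein_depth),
                                        spike_lens, fl, rl),
                     "spikein", spike_lens)
    samples[[paste0(nm, ".H3K27me3")]] <-
      chip_sample(nm, "H3K27me3", ip_t, ip_s, in_t, in_s)

    if (nrow(active_bodies) > 0) {
      bprof <- lapply(lens, function(L) numeric(L))
      for (i in seq_len(nrow(active_bodies))) {
        ch <- active_bodies$chrom[i]
        bprof[[ch]][(active_bodies$start[i] + 1):active_bodies$end[i]] <- 1
      }
      e36 <- cfg$k36_enrichment
      m36 <- sum(lens) + (e36 - 1) * sum(vapply(bprof, sum, numeric(1)))
      rate36 <- lapply(bprof, function(p) {
        (cfg$ip_depth / m36) * (1 + (e36 - 1) * p)
      })
      k36_t <- read_set(draw_reads(rate36, lens, fl, rl), "target", lens)
      k36_s <- read_set(draw_uniform_reads(rpois(1, cfg$spikein_depth),
                                           spike_lens, fl, rl),
                        "spikein", spike_lens)
      samples[[paste0(nm, ".H3K36me3")]] <-
        chip_sample(nm, "H3K36me3", k36_t, k36_s, in_t, in_s)
    }

    r <- flank_ratio_expected(lambdas, flank_bp)
    truth[[nm]] <- data.frame(
      condition = nm,
      region_id = layout$peaks$name,
      chrom = layout$peaks$chrom,
      start = layout$peaks$start,
      end = layout$peaks$end,
      decay_length = lambdas,
      enrichment = e,
      global_level = g,
      expected_density_in = 1 + (e - 1) * g,
      expected_density_out5 = 1 + (e - 1) * g * r,
      expected_density_out3 = 1 + (e - 1) * g * r,
      expected_flank_ratio = r,
      flank_bp = flank_bp,
      stringsAsFactors = FALSE
    )
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(samples = samples, peaks = layout$peaks,
                 ring1b = layout$ring1b, genes = layout$genes,
                 truth = truth, chrom_lengths = lens,
                 spike_chrom_lengths = spike_lens,
                 configs = configs, flank_bp = flank_bp),
            class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("<simulated_experiment> conditions=",
      paste(names(x$configs), collapse = ","),
      " peaks=", nrow(x$peaks), " genes=", nrow(x$genes),
      " samples=", length(x$samples), "\n", sep = "")
  invisible(x)
}

#' Write the simulator's analytic ground truth as TSV
#'
#' One row per (condition, domain) with the expected inside and flank
#' densities (in background units) and the closed-form expected out/in
#' flank ratio. Round-trips through [read_tsv()].
#'
#' @param experiment a [simulate_experiment()] result.
#' @param path output file path.
#' @export
write_truth <- function(experiment, path) {
  write_tsv(experiment$truth, path)
}
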