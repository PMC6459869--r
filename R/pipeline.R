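#' Default pipeline configuration
#'
#' A compact, fully-specified configuration for the five-stage pipeline
#' (simulate, normalize, regions, spread, profile): a 400 kb genome with
#' 20 domains, wild-type and spreading-deficient conditions.
#'
#' @param seed RNG seed recorded in every output sidecar.
#' @return a nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1337) {
  list(
    seed = seed,
    flank_bp = 1200,
    pseudocount = 0.01,
    basis = "spikein",
    binsize = 50,
    fragment_length = 200,
    window_bp = 5000,
    base = list(genome_length = 5e5, n_chroms = 1, n_peaks = 20,
                peak_width_range = c(2000, 5000), ip_depth = 1.2e5,
                input_depth = 1.2e5, spikein_depth = 4e4,
                spike_genome_length = 5e4, n_genes = 40),
    conditions = list(
      wt = list(),
      ezh2ko = list(decay_length = 0, global_level = 0.3)
    )
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("run_pipeline: config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- default_pipeline_config()
  for (f in setdiff(names(defaults), names(config))) {
    config[[f]] <- defaults[[f]]
  }
  if (config$flank_bp <= 0) {
    stop("run_pipeline: flank_bp must be > 0", call. = FALSE)
  }
  if (config$binsize < 1 || config$fragment_length < 1) {
    stop("run_pipeline: binsize and fragment_length must be >= 1",
         call. = FALSE)
  }
  if (!config$basis %in% c("spikein", "libsize")) {
    stop("run_pipeline: basis must be 'spikein' or 'libsize'",
         call. = FALSE)
  }
  if (length(config$conditions) < 1) {
    stop("run_pipeline: at least one condition required", call. = FALSE)
  }
  config
}

stage_dir <- function(outdir, name) {
  d <- file.path(outdir, name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

run_stage <- function(outdir, name, fun) {
  d <- stage_dir(outdir, name)
  tryCatch(fun(d), error = function(e) {
    unlink(d, recursive = TRUE)  # no partial stage outputs
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Chains simulate, normalize, regions, spread and profile over a
#' configuration (a list or a YAML file path), writing each stage's
#' artifacts under `outdir` plus a `manifest.json` recording inputs,
#' parameters, versions and the seed. Reruns with the same configuration
#' are byte-identical for all tables.
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure.
#' @param outdir output directory.
#' @return (invisibly) a list with the experiment, tracks, regions,
#'   spreading tables, comparisons and matrices.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = "pipeline_out") {
  config <- read_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package = "polyspread",
                   package_version =
                     as.character(utils::packageVersion("polyspread")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   parameters = config[c("flank_bp", "pseudocount",
                                         "basis", "binsize",
                                         "fragment_length", "window_bp")],
                   stages = list())

  ## -- simulate ----------------------------------------------------------
  base <- do.call(sim_config, c(config$base, list(seed = config$seed)))
  cfgs <- list()
  for (i in seq_along(config$conditions)) {
    nm <- names(config$conditions)[i]
    ov <- config$conditions[[i]]
    cfgs[[nm]] <- do.call(update_config,
                          c(list(base), ov,
                            list(seed = config$seed + i)))
  }
  exp <- NULL
  manifest$stages$simulate <- run_stage(outdir, "01_simulate", function(d) {
    exp <<- simulate_experiment(cfgs, flank_bp = config$flank_bp)
    write_peaks(exp$peaks, file.path(d, "suz12.narrowPeak"))
    write_peaks(exp$ring1b, file.path(d, "ring1b.narrowPeak"))
    write_genes(exp$genes, file.path(d, "genes.bed"))
    write_truth(exp, file.path(d, "truth.tsv"))
    for (nm in names(exp$samples)) {
      s <- exp$samples[[nm]]
      write_reads(s$ip_target, file.path(d, paste0(nm, ".ip.bed")))
      write_reads(s$ip_spikein,
                  file.path(d, paste0(nm, ".ip.spikein.bed")))
    }
    yaml::write_yaml(lapply(cfgs, unclass),
                     file.path(d, "config_echo.yaml"))
    list(outputs = sort(list.files(d)), n_peaks = nrow(exp$peaks),
         n_genes = nrow(exp$genes))
  })

  ## -- normalize ---------------------------------------------------------
  tracks <- list(); factors <- list()
  manifest$stages$normalize <- run_stage(outdir, "02_normalize",
                                         function(d) {
    for (nm in names(exp$samples)) {
      s <- exp$samples[[nm]]
      f <- compute_scaling_factor(s, config$basis)
      factors[[nm]] <<- f
      ip <- build_coverage(s$ip_target, config$fragment_length,
                           config$binsize, f)
      inp <- build_coverage(
        s$input_target, config$fragment_length, config$binsize,
        structure(list(alpha = 1e6 / s$input_target$n_reads,
                       basis = "libsize"), class = "scaling_factor"))
      net <- subtract_input(ip, inp)
      tracks[[nm]] <<- list(ip = ip, input = inp, net = net)
      write_bedgraph(net, file.path(d, paste0(nm, ".net.bedgraph")))
    }
    jsonlite::write_json(
      lapply(factors, function(f) list(alpha = f$alpha, basis = f$basis)),
      file.path(d, "factors.json"), auto_unbox = TRUE, digits = NA)
    list(outputs = sort(list.files(d)), basis = config$basis)
  })

  ## -- regions -----------------------------------------------------------
  regions <- NULL
  manifest$stages$regions <- run_stage(outdir, "03_regions", function(d) {
    regions <<- select_target_regions(exp$peaks, exp$ring1b)
    if (nrow(exp$genes) > 0) {
      regions <<- assign_promoters(regions, exp$genes)
    }
    bed <- sprintf("%s\t%d\t%d\t%s\t%d\t.", regions$chrom,
                   as.integer(regions$start), as.integer(regions$end),
                   regions$region_id,
                   as.integer(round(10 * regions$neg_log10_p)))
    writeLines(bed, file.path(d, "target_regions.bed"))
    write_tsv(regions, file.path(d, "target_regions.tsv"))
    list(outputs = sort(list.files(d)), n_regions = nrow(regions))
  })

  ## -- spread ------------------------------------------------------------
  spreading <- list(); comparisons <- list()
  manifest$stages$spread <- run_stage(outdir, "04_spread", function(d) {
    k27 <- grep("\\.H3K27me3$", names(exp$samples), value = TRUE)
    for (nm in k27) {
      tab <- spreading_table(tracks[[nm]]$ip, regions,
                             flank_bp = config$flank_bp,
                             pseudocount = config$pseudocount)
      spreading[[nm]] <<- tab
      write_tsv(tab, file.path(d, paste0(nm, ".spreading.tsv")))
    }
    if (length(k27) >= 2) {
      a <- spreading[[k27[1]]]; b <- spreading[[k27[2]]]
      keep <- !a$clipped & !b$clipped
      comparisons$t_test <<- compare_densities(a$ratio5[keep],
                                               b$ratio5[keep],
                                               "student_t")
      comparisons$regression <<- ratio_correlation(a$ratio5[keep],
                                                   b$ratio5[keep])
      jsonlite::write_json(
        lapply(comparisons, function(x) unclass(x)),
        file.path(d, "comparisons.json"), auto_unbox = TRUE, digits = NA)
    }
    list(outputs = sort(list.files(d)), flank_bp = config$flank_bp)
  })

  ## -- profile -----------------------------------------------------------
  matrices <- NULL
  manifest$stages$profile <- run_stage(outdir, "05_profile", function(d) {
    k27 <- grep("\\.H3K27me3$", names(exp$samples), value = TRUE)
    anchors <- if (nrow(exp$genes) > 0) exp$genes else
      data.frame(chrom = regions$chrom,
                 tss = floor((regions$start + regions$end) / 2),
                 strand = "+", gene_id = regions$region_id,
                 stringsAsFactors = FALSE)
    mats <- lapply(k27, function(nm) {
      reference_point_matrix(tracks[[nm]]$net, anchors,
                             window_bp = config$window_bp,
                             binsize = config$binsize)
    })
    names(mats) <- k27
    mats <- minmax_normalize(mats)
    matrices <<- mats
    for (nm in names(mats)) {
      m <- mats[[nm]]
      df <- as.data.frame(m$values)
      names(df) <- seq_len(ncol(df)) * m$binsize - config$window_bp -
        m$binsize
      df <- cbind(id = rownames(m$values), df)
      write_tsv(df, file.path(d, paste0(nm, ".tss_matrix.tsv")))
      jsonlite::write_json(
        list(anchor = m$anchor, binsize = m$binsize,
             minmax_factor = m$minmax_factor, seed = config$seed,
             n_rows = nrow(m$values), n_bins = m$n_bins),
        file.path(d, paste0(nm, ".tss_matrix.json")),
        auto_unbox = TRUE, digits = NA)
    }
    list(outputs = sort(list.files(d)), window_bp = config$window_bp)
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(experiment = exp, tracks = tracks, regions = regions,
                 spreading = spreading, comparisons = comparisons,
                 matrices = matrices, manifest = manifest))
}
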