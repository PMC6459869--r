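## Readers and writers for the plain-text genomic formats the pipeline
## touches. All coordinates on disk and in memory are 0-based half-open
## (BED convention); files are tab-separated UTF-8 without header rows
## except where noted. Parsers are strict: malformed lines raise errors
## naming the line number.

read_tab <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop(what, ": file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) return(NULL)
  fields <- strsplit(raw, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < n_min_cols)
  if (length(bad)) {
    stop(what, ": line ", bad[1], " has ", nf[bad[1]],
         " fields, expected >= ", n_min_cols, call. = FALSE)
  }
  fields
}

num_field <- function(fields, i, what) {
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  bad <- which(is.na(x))
  if (length(bad)) {
    stop(what, ": line ", bad[1], ": field ", i, " is not numeric",
         call. = FALSE)
  }
  x
}

check_lines <- function(ok, what, msg) {
  bad <- which(!ok)
  if (length(bad)) stop(what, ": line ", bad[1], ": ", msg, call. = FALSE)
}

#' Read peak calls (narrowPeak or BED6)
#'
#' @param path file path.
#' @param dialect `"narrowPeak"` (ENCODE 10-column; column 8 is the
#'   -log10 p-value of the call, which is authoritative for significance
#'   filtering) or `"bed6"` (no p-value; `neg_log10_p` is `NA`).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `neg_log10_p`, `neg_log10_q`, `summit`;
#'   rows preserve input order.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6")) {
  dialect <- match.arg(dialect)
  ncol_min <- if (dialect == "narrowPeak") 10L else 6L
  f <- read_tab(path, ncol_min, "read_peaks")
  if (is.null(f)) return(empty_peaks())
  what <- "read_peaks"
  chrom <- vapply(f, `[[`, "", 1)
  start <- num_field(f, 2, what)
  end <- num_field(f, 3, what)
  name <- vapply(f, `[[`, "", 4)
  score <- num_field(f, 5, what)
  strand <- vapply(f, `[[`, "", 6)
  strand[strand == "."] <- "*"
  check_lines(nzchar(chrom), what, "empty chromosome name")
  check_lines(start >= 0, what, "negative start coordinate")
  check_lines(start < end, what, "start must be < end (0-based half-open)")
  check_lines(strand %in% c("+", "-", "*"), what, "invalid strand")
  if (dialect == "narrowPeak") {
    signal <- num_field(f, 7, what)
    nlp <- num_field(f, 8, what)
    nlq <- num_field(f, 9, what)
    summit <- num_field(f, 10, what)
    check_lines(nlp >= 0, what, "-log10 p-value must be >= 0")
  } else {
    signal <- rep(NA_real_, length(chrom))
    nlp <- rep(NA_real_, length(chrom))
    nlq <- rep(NA_real_, length(chrom))
    summit <- rep(NA_real_, length(chrom))
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, strand = strand, signal = signal,
             neg_log10_p = nlp, neg_log10_q = nlq, summit = summit,
             stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             signal = numeric(), neg_log10_p = numeric(),
             neg_log10_q = numeric(), summit = numeric(),
             stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak
#'
#' @param peaks a peak `data.frame` as returned by [read_peaks()].
#' @param path output file path.
#' @export
write_peaks <- function(peaks, path) {
  strand <- ifelse(peaks$strand %in% c("+", "-"), peaks$strand, ".")
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%.6g\t%.6g\t%.6g\t%d",
                   peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$name,
                   as.integer(round(peaks$score)), strand,
                   ifelse(is.na(peaks$signal), 0, peaks$signal),
                   ifelse(is.na(peaks$neg_log10_p), -1, peaks$neg_log10_p),
                   ifelse(is.na(peaks$neg_log10_q), -1, peaks$neg_log10_q),
                   as.integer(ifelse(is.na(peaks$summit), -1, peaks$summit)))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a BED6-like table
#'
#' The strand column is required: the transcription start site (TSS) is the
#' strand-aware 5' end of the gene body (`start` on `+`, `end - 1` on `-`).
#'
#' @param path file path to a 6-column BED file (name column = gene id).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `gene_id`,
#'   `score`, `strand`, `tss`.
#' @export
read_genes <- function(path) {
  f <- read_tab(path, 6L, "read_genes")
  if (is.null(f)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), gene_id = character(),
                      score = numeric(), strand = character(),
                      tss = numeric(), stringsAsFactors = FALSE))
  }
  what <- "read_genes"
  chrom <- vapply(f, `[[`, "", 1)
  start <- num_field(f, 2, what)
  end <- num_field(f, 3, what)
  gene_id <- vapply(f, `[[`, "", 4)
  score <- num_field(f, 5, what)
  strand <- vapply(f, `[[`, "", 6)
  check_lines(start >= 0, what, "negative start coordinate")
  check_lines(start < end, what, "start must be < end")
  check_lines(strand %in% c("+", "-"), what,
              "gene strand must be '+' or '-'")
  data.frame(chrom = chrom, start = start, end = end, gene_id = gene_id,
             score = score, strand = strand,
             tss = ifelse(strand == "+", start, end - 1),
             stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#' @param genes a gene `data.frame` as returned by [read_genes()].
#' @param path output file path.
#' @export
write_genes <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   genes$chrom, as.integer(genes$start),
                   as.integer(genes$end), genes$gene_id,
                   as.integer(round(genes$score)), genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write aligned reads as BED6
#' @param readset a `read_set` (see [simulate_experiment()]).
#' @param path output file path.
#' @export
write_reads <- function(readset, path) {
  r <- readset$reads
  lines <- sprintf("%s\t%d\t%d\tr%d\t0\t%s",
                   r$chrom, as.integer(r$start), as.integer(r$end),
                   seq_len(nrow(r)), r$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned reads from a BED6 file into a read set
#'
#' Chromosome namespaces distinguish genomes in one file: names starting
#' with the spike-in prefix (default `"s_"`) belong to the exogenous
#' genome, everything else to the target genome.
#'
#' @param path BED6 file of reads.
#' @param genome `"target"` or `"spikein"`: which namespace to keep.
#' @param chrom_lengths named vector of chromosome lengths; if `NULL`,
#'   lengths are set to the maximum end seen per chromosome.
#' @param spikein_prefix chromosome-name prefix of the exogenous genome.
#' @return a `read_set` object.
#' @export
read_reads <- function(path, genome = c("target", "spikein"),
                       chrom_lengths = NULL, spikein_prefix = "s_") {
  genome <- match.arg(genome)
  f <- read_tab(path, 6L, "read_reads")
  if (is.null(f)) {
    return(read_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric(), strand = character(),
                               stringsAsFactors = FALSE),
                    genome, chrom_lengths %||% numeric()))
  }
  what <- "read_reads"
  chrom <- vapply(f, `[[`, "", 1)
  start <- num_field(f, 2, what)
  end <- num_field(f, 3, what)
  strand <- vapply(f, `[[`, "", 6)
  check_lines(start >= 0 & start < end, what, "invalid interval")
  check_lines(strand %in% c("+", "-"), what, "reads must carry strand")
  keep <- if (genome == "spikein") startsWith(chrom, spikein_prefix)
          else !startsWith(chrom, spikein_prefix)
  r <- data.frame(chrom = chrom[keep], start = start[keep], end = end[keep],
                  strand = strand[keep], stringsAsFactors = FALSE)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(r$end, r$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  read_set(r, genome, chrom_lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a bedGraph file into a coverage track
#'
#' Accepts unsorted input; intervals on one chromosome must not overlap.
#' For bin-aligned input (all boundaries multiples of `binsize`) the
#' round-trip through [write_bedgraph()] reproduces per-bin values exactly.
#'
#' @param path bedGraph file path.
#' @param binsize bin width; if `NULL`, inferred as the greatest common
#'   divisor of all interval boundaries.
#' @param chrom_lengths named lengths; if `NULL`, the maximum end per
#'   chromosome.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, binsize = NULL, chrom_lengths = NULL) {
  f <- read_tab(path, 4L, "read_bedgraph")
  if (is.null(f)) stop("read_bedgraph: empty file", call. = FALSE)
  what <- "read_bedgraph"
  chrom <- vapply(f, `[[`, "", 1)
  start <- num_field(f, 2, what)
  end <- num_field(f, 3, what)
  value <- num_field(f, 4, what)
  check_lines(start >= 0, what, "negative coordinate")
  check_lines(start < end, what, "start must be < end")
  for (ch in unique(chrom)) {
    i <- chrom == ch
    o <- order(start[i])
    s <- start[i][o]; e <- end[i][o]
    if (any(s[-1] < e[-length(e)])) {
      stop("read_bedgraph: overlapping intervals on ", ch, call. = FALSE)
    }
  }
  if (is.null(binsize)) {
    gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
    binsize <- Reduce(gcd2, unique(c(start, end)))
    if (binsize < 1) binsize <- 1
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(end, chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  values <- lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / binsize)
    v <- numeric(nb)
    i <- which(chrom == ch)
    for (j in i) {
      b0 <- floor(start[j] / binsize)
      b1 <- ceiling(end[j] / binsize)
      v[(b0 + 1):b1] <- value[j]
    }
    v
  })
  names(values) <- names(chrom_lengths)
  coverage_track(values, binsize, chrom_lengths, scaled = TRUE)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged into one line; zero-valued runs
#' are written too, so that a read-back reproduces every bin exactly.
#'
#' @param track a [coverage_track()].
#' @param path output file path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  b <- track$binsize
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    L <- track$chrom_lengths[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths) * b
    starts <- c(0, ends[-length(ends)])
    ends <- pmin(ends, L)
    writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, as.integer(starts),
                       as.integer(ends), r$values), con)
  }
  invisible(path)
}

#' Write a tab-separated table with a header row
#' @param df a `data.frame`.
#' @param path output file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table with a header row
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
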