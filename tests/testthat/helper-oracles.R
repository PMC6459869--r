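## Independent oracles: deliberately naive implementations used only to
## check the package's vectorized code paths.

## Per-bp pileup by looping over reads, then bin-averaged.
pileup_oracle <- function(readset, fragment_length, binsize, alpha = 1) {
  out <- list()
  for (ch in names(readset$chrom_lengths)) {
    L <- readset$chrom_lengths[[ch]]
    cov <- numeric(L)
    r <- readset$reads[readset$reads$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      if (r$strand[i] == "+") {
        fs <- r$start[i]; fe <- fs + fragment_length
      } else {
        fe <- r$end[i]; fs <- fe - fragment_length
      }
      fs <- max(fs, 0); fe <- min(fe, L)
      if (fe > fs) cov[(fs + 1):fe] <- cov[(fs + 1):fe] + 1
    }
    nb <- ceiling(L / binsize)
    v <- numeric(nb)
    for (b in seq_len(nb)) {
      i0 <- (b - 1) * binsize + 1
      i1 <- min(b * binsize, L)
      v[b] <- alpha * sum(cov[i0:i1]) / binsize
    }
    out[[ch]] <- v
  }
  out
}

## Mean density by expanding the track to per-bp values.
density_oracle <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  L <- track$chrom_lengths[[chrom]]
  perbp <- rep(v, each = track$binsize)[seq_len(L)]
  mean(perbp[(start + 1):end])
}

## Exact two-sided rank-sum p by enumerating all group assignments.
ranksum_exact_oracle <- function(a, b) {
  n <- length(a) + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  idx <- utils::combn(n, length(a))
  u_all <- apply(idx, 2, function(i) {
    sum(rank(pooled)[i]) - length(a) * (length(a) + 1) / 2
  })
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

## Upper-tail Poisson probability (including obs) by direct pmf summation.
poisson_tail_oracle <- function(obs, lambda, kmax = 1000) {
  sum(stats::dpois(seq(obs, obs + kmax), lambda))
}

## O(n^2) all-pairs overlap selection of SUZ12 target regions.
brute_force_targets <- function(suz12, ring1b, min_neglog10p = 1,
                                min_overlap = 1) {
  s <- suz12[suz12$neg_log10_p >= min_neglog10p, , drop = FALSE]
  r <- ring1b[ring1b$neg_log10_p >= min_neglog10p, , drop = FALSE]
  keep <- logical(nrow(s))
  partner <- character(nrow(s))
  best <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(nrow(r))) {
      if (s$chrom[i] != r$chrom[j]) next
      ov <- min(s$end[i], r$end[j]) - max(s$start[i], r$start[j])
      if (ov >= min_overlap) {
        if (!keep[i] || ov > best[i] ||
            (ov == best[i] && r$name[j] < partner[i])) {
          best[i] <- ov
          partner[i] <- r$name[j]
        }
        keep[i] <- TRUE
      }
    }
  }
  out <- s[keep, c("chrom", "start", "end", "name", "neg_log10_p")]
  out$partner <- partner[keep]
  out$overlap_bp <- best[keep]
  out <- out[order(out$chrom, out$start, out$end, out$name), ]
  rownames(out) <- NULL
  out
}

## Simple least-squares via the normal equations.
normal_equations_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(intercept = beta[1], slope = beta[2], r = r)
}
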