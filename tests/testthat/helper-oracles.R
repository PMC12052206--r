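# Independent brute-force oracles used to validate the implementation.

# O(fragments x bins) per-bin overlap count
oracle_bin_coverage <- function(frags, grid, factor = 1) {
  bw <- grid$bin_width
  lapply(names(grid$chrom_sizes), function(chrom) {
    nb <- grid$n_bins[[chrom]]
    v <- numeric(nb)
    f <- frags[frags$chrom == chrom, , drop = FALSE]
    for (b in seq_len(nb)) {
      bs <- (b - 1) * bw
      be <- min(bs + bw, grid$chrom_sizes[[chrom]])
      if (nrow(f) > 0) {
        v[b] <- sum(f$start < be & f$end > bs) * factor
      }
    }
    v
  })
}

# exhaustive gap-rule scan over one bin-value vector; returns matrix of
# (first_bin, last_bin) 1-based rows
oracle_link_bins <- function(v, cutoff, max_gap_bins, jump_frac) {
  hot <- which(v >= cutoff)
  if (length(hot) == 0) return(matrix(numeric(0), ncol = 2))
  doms <- list(c(hot[1], hot[1]))
  if (length(hot) > 1) {
    for (i in 2:length(hot)) {
      prev <- doms[[length(doms)]]
      gap <- (hot[i] - prev[2]) - 1
      gap_ok <- gap == 0 ||
        (gap <= max_gap_bins &&
           all(v[(prev[2] + 1):(hot[i] - 1)] >= jump_frac * cutoff))
      if (gap_ok) {
        doms[[length(doms)]][2] <- hot[i]
      } else {
        doms[[length(doms) + 1]] <- c(hot[i], hot[i])
      }
    }
  }
  do.call(rbind, doms)
}

# per-bp label-vector disjoin on a single chromosome of length L
oracle_disjoin_1chrom <- function(domain_sets, L) {
  n_cond <- length(domain_sets)
  lab <- matrix(FALSE, nrow = L, ncol = n_cond)
  for (j in seq_len(n_cond)) {
    d <- domain_sets[[j]]
    for (i in seq_len(nrow(d))) {
      if (d$end[i] > d$start[i]) {
        lab[(d$start[i] + 1):d$end[i], j] <- TRUE
      }
    }
  }
  # bit-encode the per-bp membership tuple, then run-length scan
  key <- as.integer(lab %*% 2^(seq_len(n_cond) - 1))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  out <- data.frame(start = starts[keep] - 1, end = ends[keep])
  memb <- vapply(seq_len(n_cond), function(j)
    bitwAnd(r$values[keep], 2^(j - 1)) > 0, logical(sum(keep)))
  cbind(out, as.data.frame(matrix(memb, ncol = n_cond,
                                  dimnames = list(NULL,
                                                  paste0("V", seq_len(n_cond))))))
}

# upper-tail hypergeometric by enumerating all size-n subsets of 1..N
oracle_hyper_enum <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# random non-overlapping grid-aligned domains on one chromosome
random_domains <- function(L, n_max = 6, bw = 100) {
  n <- sample.int(n_max, 1)
  starts <- sort(sample.int(L / bw - 2, n)) * bw
  ends <- pmin(starts + sample.int(20, n) * bw, L)
  keep <- c(TRUE, starts[-1] >= ends[-n])
  data.frame(chrom = "chrT", start = starts[keep], end = ends[keep])
}

# wide-format truth table built by hand (two conditions)
manual_truth <- function(chrom, ref_start, ref_end, tr_start, tr_end,
                         ref_present = TRUE, tr_present = TRUE,
                         scenario = "same") {
  data.frame(chrom = chrom,
             start = pmin(ref_start, tr_start),
             end = pmax(ref_end, tr_end),
             scenario = scenario,
             name = paste0("m", seq_along(chrom), "_", scenario),
             reference_present = ref_present,
             reference_start = ref_start, reference_end = ref_end,
             treated_present = tr_present,
             treated_start = tr_start, treated_end = tr_end,
             stringsAsFactors = FALSE)
}

# CoverageTrack from raw bin values (one chromosome)
make_track <- function(values, bw = 100, smoothed = TRUE,
                       chrom = "chrT") {
  sizes <- stats::setNames(length(values) * bw, chrom)
  tr <- bin_coverage(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0)),
                     bin_grid(sizes, bw))
  tr$values[[chrom]] <- as.numeric(values)
  tr$smoothed <- smoothed
  tr
}
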