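#' Simulation configuration
#'
#' Parameters of the synthetic fragment generator used to validate the
#' domain pipeline without sequencing data.  Fragment midpoints are drawn
#' from a piecewise-constant density that is `enrichment_fold` times
#' higher inside condition-present planted domains than in background;
#' `background_rate` optionally mixes in a pure genome-uniform component.
#'
#' @param chrom_sizes named vector of toy target chromosome lengths (bp);
#'   multiples of the downstream bin width keep expectations exact.
#' @param spike_chrom_sizes named vector of spike-in chromosome lengths;
#'   names should be prefixed `spike_` so one BED file can carry both
#'   genomes unambiguously.
#' @param n_target_fragments,n_spike_fragments,n_igg_fragments fragment
#'   counts emitted per call to [simulate_fragments()].
#' @param fraglen_mean,fraglen_sd fragment length distribution (bp);
#'   lengths are drawn normal and clipped to `[fraglen_min, fraglen_max]`,
#'   spanning the retention windows of both assays so that length-filter
#'   tests exercise keep and drop branches.
#' @param fraglen_min,fraglen_max clip bounds in bp.
#' @param background_rate fraction of target fragments placed uniformly
#'   regardless of planted domains (0 = all fragments follow the
#'   enrichment density).
#' @param enrichment_fold midpoint density inside planted domains relative
#'   to background; must be >= 1.
#' @param seed root RNG seed; per-stream seeds (truth, fragments, mixture)
#'   are derived from it so adding one stream does not perturb others.
#' @return A `SimConfig` object.
#' @export
sim_config <- function(chrom_sizes = c(chrT = 5e6),
                       spike_chrom_sizes = c(spike_1 = 1e6),
                       n_target_fragments = 100000,
                       n_spike_fragments = 2600,
                       n_igg_fragments = 50000,
                       fraglen_mean = 180, fraglen_sd = 40,
                       fraglen_min = 50, fraglen_max = 600,
                       background_rate = 0,
                       enrichment_fold = 8,
                       seed = 1L) {
  stopifnot(all(chrom_sizes > 0), all(spike_chrom_sizes > 0),
            n_target_fragments >= 0, n_spike_fragments >= 0,
            n_igg_fragments >= 0,
            fraglen_mean > 0, fraglen_sd >= 0,
            fraglen_min > 0, fraglen_min <= fraglen_max,
            background_rate >= 0, background_rate <= 1,
            enrichment_fold >= 1)
  structure(list(chrom_sizes = chrom_sizes,
                 spike_chrom_sizes = spike_chrom_sizes,
                 n_target_fragments = n_target_fragments,
                 n_spike_fragments = n_spike_fragments,
                 n_igg_fragments = n_igg_fragments,
                 fraglen_mean = fraglen_mean, fraglen_sd = fraglen_sd,
                 fraglen_min = fraglen_min, fraglen_max = fraglen_max,
                 background_rate = background_rate,
                 enrichment_fold = enrichment_fold,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Deterministic per-stream seed derivation: polynomial hash of the stream
# name folded into the root seed, kept below 2^31.
derive_seed <- function(root, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483646
  as.integer((as.numeric(root) * 7919 + h) %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Plant a truth set of domains with known change scenarios
#'
#' Places non-overlapping domains on the toy genome and assigns each a
#' boundary-change scenario across the given conditions: `same` (identical
#' boundaries), `shrinking` (boundaries retract), `spreading` (boundaries
#' extend), `new` (absent in the first condition), `lost` (absent after
#' the first condition).  For more than two conditions the shifting
#' boundaries interpolate linearly, rounded to the bin grid.
#'
#' @param config [sim_config()] object.
#' @param n_domains number of domains to place.
#' @param scenario_mix named fractions over scenarios, summing to 1.
#' @param conditions ordered condition names; the first is the reference.
#' @param domain_len_range domain length range in bp (sampled uniformly in
#'   bin-width steps).  Defaults span the 10-30 kb scale of broad
#'   facultative-heterochromatin domains; with the default domain count
#'   the planted regions cover roughly a tenth of the toy genome, the
#'   regime a percentile-based domain cutoff presumes (the enriched
#'   fraction must exceed 100 - F percent of windows).
#' @param shift_range bp range of each boundary retraction/extension.
#' @param min_gap minimum separation between planted domains in bp (keep
#'   larger than the smoothing span plus the maximal boundary shift so
#'   that planted domains stay resolvable).
#' @param bin_width grid step to which all coordinates are rounded.
#' @return `data.frame` with one row per domain: `chrom`, `start`, `end`
#'   (the union footprint), `scenario`, `name`, and for every condition
#'   `<cond>_present`, `<cond>_start`, `<cond>_end`.
#' @export
make_truth_set <- function(config, n_domains,
                           scenario_mix = c(same = 0.25, shrinking = 0.25,
                                            spreading = 0.25, new = 0.25),
                           conditions = c("reference", "treated"),
                           domain_len_range = c(10000, 30000),
                           shift_range = c(2000, 4000),
                           min_gap = 10000,
                           bin_width = 100) {
  stopifnot(inherits(config, "SimConfig"), n_domains >= 0,
            length(conditions) >= 2)
  known <- c("same", "shrinking", "spreading", "new", "lost")
  if (!all(names(scenario_mix) %in% known)) {
    stop("unknown scenario(s): ",
         paste(setdiff(names(scenario_mix), known), collapse = ", "))
  }
  if (abs(sum(scenario_mix) - 1) > 1e-9) stop("scenario_mix must sum to 1")
  cols <- c("chrom", "start", "end", "scenario", "name",
            as.vector(t(outer(conditions, c("_present", "_start", "_end"),
                              paste0))))
  if (n_domains == 0) {
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                         cols))
    return(out)
  }
  # largest-remainder apportionment of scenario counts
  raw <- scenario_mix * n_domains
  counts <- floor(raw)
  rem <- n_domains - sum(counts)
  if (rem > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1
  }
  scenarios <- rep(names(counts), counts)

  with_seed(derive_seed(config$seed, "truth"), {
    scenarios <- sample(scenarios)
    snap <- function(x) round(x / bin_width) * bin_width
    max_shift <- snap(shift_range[2])
    placed <- list()
    occupied <- lapply(names(config$chrom_sizes), function(x)
      numeric(0))  # flattened (start,end) pairs incl. margin
    names(occupied) <- names(config$chrom_sizes)
    for (i in seq_len(n_domains)) {
      len <- snap(stats::runif(1, domain_len_range[1], domain_len_range[2]))
      ok <- FALSE
      for (attempt in 1:200) {
        chrom <- sample(names(config$chrom_sizes), 1,
                        prob = config$chrom_sizes)
        cl <- config$chrom_sizes[[chrom]]
        lo <- max_shift + min_gap
        hi <- cl - len - max_shift - min_gap
        if (hi <= lo) next
        start <- snap(stats::runif(1, lo, hi))
        end <- start + len
        occ <- occupied[[chrom]]
        clash <- FALSE
        if (length(occ) > 0) {
          os <- occ[c(TRUE, FALSE)]
          oe <- occ[c(FALSE, TRUE)]
          clash <- any(start - max_shift - min_gap < oe &
                         end + max_shift + min_gap > os)
        }
        if (!clash) {
          occupied[[chrom]] <- c(occ, start, end)
          placed[[i]] <- list(chrom = chrom, start = start, end = end)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("genome too small: could not place domain ", i, " of ",
             n_domains, " (length ", len, " bp) without overlap")
      }
    }
    m <- length(conditions)
    rows <- lapply(seq_len(n_domains), function(i) {
      p <- placed[[i]]
      sc <- scenarios[i]
      shift_l <- snap(stats::runif(1, shift_range[1], shift_range[2]))
      shift_r <- snap(stats::runif(1, shift_range[1], shift_range[2]))
      frac <- if (m == 2) c(0, 1) else seq(0, 1, length.out = m)
      row <- list(chrom = p$chrom, scenario = sc,
                  name = paste0("dom", i, "_", sc))
      union_s <- p$start; union_e <- p$end
      for (j in seq_len(m)) {
        cond <- conditions[j]
        present <- TRUE
        s <- p$start; e <- p$end
        if (sc == "shrinking") {
          s <- snap(p$start + frac[j] * shift_l)
          e <- snap(p$end - frac[j] * shift_r)
        } else if (sc == "spreading") {
          s <- snap(p$start - frac[j] * shift_l)
          e <- snap(p$end + frac[j] * shift_r)
        } else if (sc == "new") {
          present <- j > 1
        } else if (sc == "lost") {
          present <- j == 1
        }
        if (present) {
          union_s <- min(union_s, s); union_e <- max(union_e, e)
        }
        row[[paste0(cond, "_present")]] <- present
        row[[paste0(cond, "_start")]] <- s
        row[[paste0(cond, "_end")]] <- e
      }
      row$start <- union_s
      row$end <- union_e
      row
    })
    out <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    out <- out[order(out$chrom, out$start), cols, drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Intervals of a truth set present in one condition
#'
#' @param truth output of [make_truth_set()].
#' @param condition condition name.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `scenario`.
#' @export
truth_intervals <- function(truth, condition) {
  pc <- paste0(condition, c("_present", "_start", "_end"))
  if (!all(pc %in% names(truth))) {
    known <- sub("_present$", "", grep("_present$", names(truth),
                                       value = TRUE))
    stop("unknown condition '", condition, "'; known: ",
         paste(known, collapse = ", "))
  }
  sel <- truth[[pc[1]]]
  data.frame(chrom = truth$chrom[sel], start = truth[[pc[2]]][sel],
             end = truth[[pc[3]]][sel], name = truth$name[sel],
             scenario = truth$scenario[sel], stringsAsFactors = FALSE)
}

# sample n fragment midpoints from a piecewise-uniform density over the
# target genome: weight `fold` inside `domains`, 1 elsewhere.
sample_midpoints <- function(n, chrom_sizes, domains, fold,
                             background_rate) {
  if (n == 0) {
    return(data.frame(chrom = character(0), mid = numeric(0)))
  }
  # build weighted regions: background complement per chromosome + domains
  regs <- list()
  for (chrom in names(chrom_sizes)) {
    cl <- chrom_sizes[[chrom]]
    d <- domains[domains$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    pos <- 0
    if (nrow(d) > 0) {
      for (i in seq_len(nrow(d))) {
        if (d$start[i] > pos) {
          regs[[length(regs) + 1]] <- list(chrom, pos, d$start[i], 1)
        }
        regs[[length(regs) + 1]] <- list(chrom, d$start[i], d$end[i], fold)
        pos <- d$end[i]
      }
    }
    if (pos < cl) regs[[length(regs) + 1]] <- list(chrom, pos, cl, 1)
  }
  rchrom <- vapply(regs, `[[`, character(1), 1)
  rstart <- vapply(regs, `[[`, numeric(1), 2)
  rend <- vapply(regs, `[[`, numeric(1), 3)
  rw <- vapply(regs, `[[`, numeric(1), 4)
  len <- rend - rstart
  n_unif <- stats::rbinom(1, n, background_rate)
  n_w <- n - n_unif
  pick_w <- if (n_w > 0) {
    sample.int(length(regs), n_w, replace = TRUE, prob = len * rw)
  } else integer(0)
  pick_u <- if (n_unif > 0) {
    sample.int(length(regs), n_unif, replace = TRUE, prob = len)
  } else integer(0)
  pick <- c(pick_w, pick_u)
  mid <- rstart[pick] + stats::runif(length(pick)) * len[pick]
  data.frame(chrom = rchrom[pick], mid = mid, stringsAsFactors = FALSE)
}

# turn midpoints into fragments with clipped-normal lengths
midpoints_to_fragments <- function(mids, chrom_sizes, config) {
  n <- nrow(mids)
  if (n == 0) return(empty_fragments())
  len <- round(stats::rnorm(n, config$fraglen_mean, config$fraglen_sd))
  len <- pmax(pmin(len, config$fraglen_max), config$fraglen_min)
  len <- pmax(len, 1)
  cl <- unname(chrom_sizes[mids$chrom])
  len <- pmin(len, cl)
  start <- round(mids$mid - len / 2)
  start <- pmax(0, pmin(start, cl - len))
  out <- fragments(mids$chrom, start, start + len)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Simulate fragment sets for one condition
#'
#' Draws target fragments whose midpoint density is `enrichment_fold`-fold
#' elevated inside the truth domains present in `condition`, a uniform
#' spike-in pool on the spike genome, and a flat IgG background on the
#' target genome.
#'
#' @param truth [make_truth_set()] output (may have zero rows).
#' @param condition condition to simulate.
#' @param config [sim_config()] object.
#' @param replicate replicate index; folded into the derived seed so
#'   replicates are independent but reproducible.
#' @return list with fragment `data.frame`s `target`, `spike`, `igg`.
#' @export
simulate_fragments <- function(truth, condition, config, replicate = 1L) {
  stopifnot(inherits(config, "SimConfig"))
  present <- if (nrow(truth) > 0) {
    truth_intervals(truth, condition)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  seed <- derive_seed(config$seed,
                      paste0("fragments/", condition, "/", replicate))
  with_seed(seed, {
    target <- midpoints_to_fragments(
      sample_midpoints(config$n_target_fragments, config$chrom_sizes,
                       present, config$enrichment_fold,
                       config$background_rate),
      config$chrom_sizes, config)
    spike <- midpoints_to_fragments(
      sample_midpoints(config$n_spike_fragments, config$spike_chrom_sizes,
                       data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), 1, 0),
      config$spike_chrom_sizes, config)
    igg <- midpoints_to_fragments(
      sample_midpoints(config$n_igg_fragments, config$chrom_sizes,
                       data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), 1, 0),
      config$chrom_sizes, config)
    list(target = target, spike = spike, igg = igg)
  })
}

#' Sample from the two-component normal mixture of the bimodal model
#'
#' Draws from the mixture whose density is proportional to
#' `A0*exp(-((x-A1)/A2)^2) + A3*exp(-((x-A4)/A5)^2)`: component means
#' `A1`, `A4`, standard deviations `A2/sqrt(2)`, `A5/sqrt(2)`, and mixing
#' proportions proportional to `A0*A2` and `A3*A5` (the component areas).
#'
#' @param A numeric vector `c(A0, A1, A2, A3, A4, A5)`.
#' @param n sample size.
#' @param seed RNG seed.
#' @return numeric vector of `n` draws.
#' @export
simulate_log2_mixture <- function(A, n, seed = 1L) {
  stopifnot(length(A) == 6, n >= 0)
  A0 <- A[1]; A1 <- A[2]; A2 <- A[3]
  A3 <- A[4]; A4 <- A[5]; A5 <- A[6]
  if (A2 <= 0 || A5 <= 0) stop("component widths A2, A5 must be > 0")
  w <- c(A0 * A2, A3 * A5)
  if (any(w < 0) || sum(w) <= 0) {
    stop("component weights derived from amplitudes must be positive")
  }
  if (n == 0) return(numeric(0))
  with_seed(derive_seed(seed, "mixture"), {
    comp <- sample.int(2, n, replace = TRUE, prob = w)
    means <- c(A1, A4)[comp]
    sds <- (c(A2, A5) / sqrt(2))[comp]
    stats::rnorm(n, means, sds)
  })
}

#' Write a truth set as BED6 for one condition
#'
#' The name column carries the domain id and scenario; score is 0 and
#' strand ".".
#'
#' @param truth [make_truth_set()] output.
#' @param condition condition whose present intervals are written.
#' @param path output path.
#' @export
write_truth_bed <- function(truth, condition, path) {
  iv <- truth_intervals(truth, condition)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(iv) > 0) {
    writeLines(paste(iv$chrom, iv$start, iv$end, iv$name, 0, ".",
                     sep = "\t"), con)
  }
  invisible(path)
}
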