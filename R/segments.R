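#' Merge overlapping or bookended intervals
#'
#' Minimal covering set per chromosome (interval-union "reduce").
#'
#' @param domains `data.frame` with `chrom`, `start`, `end`.
#' @return reduced intervals, sorted.
#' @export
reduce_domains <- function(domains) {
  if (nrow(domains) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  gr_to_bed(GenomicRanges::sort(GenomicRanges::reduce(bed_to_gr(domains))))
}

#' Decompose multi-condition domain sets into unique segments
#'
#' The atomic, pairwise-disjoint intervals induced by all boundary
#' coordinates of the input domain sets.  Every segment lies fully inside
#' or fully outside each condition's (reduced) domains; the union of the
#' segments equals the union of the inputs, bp-exact.
#'
#' @param domain_sets named list (condition -> domain `data.frame`).
#' @return `data.frame` with `chrom`, `start`, `end`, `width` and one
#'   logical membership column `in_<condition>` per condition.
#' @export
disjoin_segments <- function(domain_sets) {
  stopifnot(length(domain_sets) >= 1, !is.null(names(domain_sets)))
  grs <- lapply(domain_sets, function(d) {
    GenomicRanges::reduce(bed_to_gr(d))
  })
  all_gr <- suppressWarnings(do.call(c, unname(grs)))
  if (length(all_gr) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), width = numeric(0))
    for (cond in names(domain_sets)) out[[paste0("in_", cond)]] <- logical(0)
    return(out)
  }
  dj <- GenomicRanges::sort(GenomicRanges::disjoin(all_gr))
  out <- gr_to_bed(dj)
  out$width <- out$end - out$start
  for (cond in names(domain_sets)) {
    out[[paste0("in_", cond)]] <-
      IRanges::overlapsAny(dj, grs[[cond]], minoverlap = 1)
  }
  out
}

#' Per-segment enrichment across conditions
#'
#' Mean normalized bin value of every condition's track over each
#' segment, plus the pseudocounted log2 values used downstream for
#' clustering and ratio analyses.
#'
#' @param segments segment `data.frame` aligned to the tracks' bin grid.
#' @param tracks named list (condition -> `CoverageTrack`) on one grid.
#' @param pseudocount added before taking log2, in normalized units.
#' @return `segments` with `mean_<cond>` and `log2_<cond>` columns.
#' @export
segment_enrichment <- function(segments, tracks, pseudocount = 0.01) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!grids_identical(t$grid, ref$grid)) stop("tracks on different grids")
  }
  for (cond in names(tracks)) {
    m <- if (nrow(segments) > 0) {
      segment_means(tracks[[cond]], segments)
    } else numeric(0)
    segments[[paste0("mean_", cond)]] <- m
    segments[[paste0("log2_", cond)]] <- log2(m + pseudocount)
  }
  segments
}

log2_cols <- function(segments) {
  grep("^log2_", names(segments), value = TRUE)
}

#' K-means clustering of segment trajectories
#'
#' Clusters the per-segment log2 enrichment rows (optionally row
#' z-scored, the default, so the clustering follows trajectory shape).
#' Clusters are relabeled 1..k by ascending mean change between the last
#' and first condition, so cluster 1 holds the strongest losses and
#' cluster k the strongest gains.  Labels are invariant to the input row
#' order: k-means runs on a canonically ordered copy of the features and
#' rows are then assigned to the nearest converged center.
#'
#' @param segments output of [segment_enrichment()].
#' @param k number of clusters (>= 2).
#' @param seed RNG seed for the k-means restarts.
#' @param n_start number of random restarts; the lowest within-cluster
#'   sum of squares wins.
#' @param scale_rows z-score each feature row before clustering.
#' @return `segments` with an integer `cluster` column.
#' @export
cluster_segments <- function(segments, k = 6, seed = 1L, n_start = 50,
                             scale_rows = TRUE) {
  stopifnot(k >= 2)
  lc <- log2_cols(segments)
  if (length(lc) < 1) stop("segments carry no log2_<condition> columns")
  feat <- as.matrix(segments[, lc, drop = FALSE])
  if (scale_rows) {
    mu <- rowMeans(feat)
    sd <- apply(feat, 1, stats::sd)
    sd[sd == 0] <- 1
    feat <- (feat - mu) / sd
  }
  if (nrow(unique(feat)) < k) {
    stop("fewer than k = ", k, " distinct feature rows")
  }
  ord <- do.call(order, as.data.frame(feat))
  fit <- with_seed(as.integer(seed), {
    stats::kmeans(feat[ord, , drop = FALSE], centers = k,
                  nstart = n_start, iter.max = 100)
  })
  # assign every original row to its nearest center (ties -> lowest index)
  d2 <- vapply(seq_len(k), function(j) {
    rowSums(sweep(feat, 2, fit$centers[j, ], `-`)^2)
  }, numeric(nrow(feat)))
  raw <- max.col(-d2, ties.method = "first")
  # relabel by ascending mean(last - first) log2 change
  change <- segments[[lc[length(lc)]]] - segments[[lc[1]]]
  mean_change <- vapply(seq_len(k), function(j) {
    if (any(raw == j)) mean(change[raw == j]) else Inf
  }, numeric(1))
  rank_map <- match(seq_len(k), order(mean_change))
  segments$cluster <- rank_map[raw]
  segments
}

#' Classify boundary changes between two conditions
#'
#' Disjoins the treated and reference domain sets and labels every unique
#' segment: `same` for bp covered in both conditions, `spreading` for
#' treated-only bp of a treated domain that touches a reference domain,
#' `new` for segments of treated domains with no reference overlap at
#' all, and `shrinking` for reference-only bp (boundary retraction, or an
#' entirely lost domain).
#'
#' @param treated_domains,reference_domains domain `data.frame`s.
#' @param tolerance bp slack: treated-only or reference-only segments not
#'   wider than this are absorbed into `same` (0 = a one-bin shift
#'   already counts as a boundary change).
#' @return segment `data.frame` with membership columns and `category`.
#' @export
classify_change <- function(treated_domains, reference_domains,
                            tolerance = 0) {
  treated <- reduce_domains(treated_domains)
  reference <- reduce_domains(reference_domains)
  seg <- disjoin_segments(list(treated = treated, reference = reference))
  if (nrow(seg) == 0) {
    seg$category <- character(0)
    return(seg)
  }
  tr_gr <- bed_to_gr(treated)
  seg_gr <- bed_to_gr(seg)
  tr_touches_ref <- IRanges::overlapsAny(tr_gr, bed_to_gr(reference))
  # which treated domain contains each treated segment
  parent <- GenomicRanges::findOverlaps(seg_gr, tr_gr, select = "first")
  category <- character(nrow(seg))
  both <- seg$in_treated & seg$in_reference
  t_only <- seg$in_treated & !seg$in_reference
  r_only <- !seg$in_treated & seg$in_reference
  category[both] <- "same"
  category[r_only] <- "shrinking"
  category[t_only] <- ifelse(tr_touches_ref[parent[t_only]],
                             "spreading", "new")
  if (tolerance > 0) {
    small <- seg$width <= tolerance &
      category %in% c("spreading", "shrinking")
    category[small] <- "same"
  }
  seg$category <- category
  seg
}

#' Base-pair totals per cluster and change category
#'
#' @param segments segments carrying `cluster` and `category` columns.
#' @param categories category order for the output columns.
#' @return `data.frame`: one row per cluster with per-category bp, the
#'   cluster bp total, per-category percentages (rows sum to 100), and an
#'   `empty` flag for clusters with zero bp.
#' @export
category_bp_summary <- function(segments,
                                categories = c("same", "shrinking",
                                               "spreading", "new")) {
  if (is.null(segments$category) ||
      any(is.na(segments$category) | segments$category == "")) {
    stop("all segments must be classified")
  }
  if (is.null(segments$cluster)) {
    segments$cluster <- 1L
  }
  clusters <- sort(unique(segments$cluster))
  rows <- lapply(clusters, function(cl) {
    s <- segments[segments$cluster == cl, , drop = FALSE]
    bp <- vapply(categories, function(cat) {
      sum(s$width[s$category == cat])
    }, numeric(1))
    tot <- sum(bp)
    pct <- if (tot > 0) 100 * bp / tot else rep(0, length(bp))
    out <- data.frame(cluster = cl, total_bp = tot, empty = tot == 0)
    for (i in seq_along(categories)) {
      out[[paste0("bp_", categories[i])]] <- bp[i]
      out[[paste0("pct_", categories[i])]] <- pct[i]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of segments per cluster containing a feature
#'
#' A segment "contains" a feature (CpG island, bivalent promoter, ...)
#' when they overlap by at least 1 bp.
#'
#' @param segments clustered segment `data.frame`.
#' @param features interval `data.frame` (`chrom`, `start`, `end`).
#' @return `data.frame` with per-cluster segment counts and the
#'   percentage of segments containing at least one feature.
#' @export
feature_fraction <- function(segments, features) {
  if (is.null(segments$cluster)) segments$cluster <- 1L
  hit <- if (nrow(segments) == 0 || nrow(features) == 0) {
    rep(FALSE, nrow(segments))
  } else {
    IRanges::overlapsAny(bed_to_gr(segments), bed_to_gr(features),
                         minoverlap = 1)
  }
  clusters <- sort(unique(segments$cluster))
  out <- data.frame(
    cluster = clusters,
    n_segments = vapply(clusters, function(cl)
      sum(segments$cluster == cl), numeric(1)),
    n_with_feature = vapply(clusters, function(cl)
      sum(hit[segments$cluster == cl]), numeric(1)))
  out$pct_with_feature <- ifelse(out$n_segments > 0,
                                 100 * out$n_with_feature / out$n_segments,
                                 0)
  out
}

#' Per-cluster percentage of bp overlapping a reference domain set
#'
#' @param segments clustered segment `data.frame`.
#' @param reference_domains interval `data.frame`.
#' @return `data.frame` with per-cluster total bp, overlapping bp and
#'   percentage.
#' @export
overlap_bp_with_reference <- function(segments, reference_domains) {
  if (is.null(segments$cluster)) segments$cluster <- 1L
  ov_bp <- rep(0, nrow(segments))
  if (nrow(segments) > 0 && nrow(reference_domains) > 0) {
    seg_gr <- bed_to_gr(segments)
    ref_gr <- GenomicRanges::reduce(bed_to_gr(reference_domains))
    hits <- GenomicRanges::findOverlaps(seg_gr, ref_gr)
    if (length(hits) > 0) {
      w <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(seg_gr)[S4Vectors::queryHits(hits)],
        GenomicRanges::ranges(ref_gr)[S4Vectors::subjectHits(hits)]))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      ov_bp[as.integer(names(agg))] <- agg
    }
  }
  clusters <- sort(unique(segments$cluster))
  out <- data.frame(
    cluster = clusters,
    total_bp = vapply(clusters, function(cl)
      sum(segments$width[segments$cluster == cl]), numeric(1)),
    overlap_bp = vapply(clusters, function(cl)
      sum(ov_bp[segments$cluster == cl]), numeric(1)))
  out$pct_overlap <- ifelse(out$total_bp > 0,
                            100 * out$overlap_bp / out$total_bp, 0)
  out
}

#' Signal matrix around domain centers
#'
#' One row per domain: normalized bin values centered on the domain
#' midpoint, `flank` bp to each side.  Bins beyond a chromosome end are
#' filled with `NA`.
#'
#' @param domains domain `data.frame`.
#' @param track `CoverageTrack`.
#' @param flank flank in bp on each side of the center bin; multiple of
#'   the bin width.
#' @return numeric matrix, one column per bin offset.
#' @export
signal_matrix_around_centers <- function(domains, track, flank = 20000) {
  bw <- track$grid$bin_width
  if (flank %% bw != 0) stop("flank must be a multiple of bin width")
  h <- flank / bw
  offsets <- -h:h
  mat <- matrix(NA_real_, nrow = nrow(domains), ncol = length(offsets),
                dimnames = list(NULL, offsets * bw))
  for (i in seq_len(nrow(domains))) {
    chrom <- domains$chrom[i]
    v <- track$values[[chrom]]
    if (is.null(v)) stop("unknown chromosome: ", chrom)
    center_bin <- floor(floor((domains$start[i] + domains$end[i]) / 2) / bw) + 1
    idx <- center_bin + offsets
    valid <- idx >= 1 & idx <= length(v)
    mat[i, valid] <- v[idx[valid]]
  }
  mat
}

#' Log2-ratio matrix around domain centers
#'
#' Element-wise log2 ratio of two center-anchored signal matrices, with
#' all values outside the domain boundaries set to 0.
#'
#' @param domains domain `data.frame`.
#' @param track_num,track_den numerator and denominator tracks on one
#'   grid.
#' @param flank flank in bp.
#' @param pseudocount added to both matrices before the ratio.
#' @return numeric matrix.
#' @export
ratio_matrix_around_centers <- function(domains, track_num, track_den,
                                        flank = 20000, pseudocount = 0.01) {
  if (!grids_identical(track_num$grid, track_den$grid)) {
    stop("tracks on different grids")
  }
  num <- signal_matrix_around_centers(domains, track_num, flank)
  den <- signal_matrix_around_centers(domains, track_den, flank)
  out <- log2((num + pseudocount) / (den + pseudocount))
  bw <- track_num$grid$bin_width
  h <- flank / bw
  offsets <- -h:h
  for (i in seq_len(nrow(domains))) {
    center <- floor((domains$start[i] + domains$end[i]) / 2)
    pos <- floor(center / bw) * bw + offsets * bw
    inside <- pos >= domains$start[i] & pos < domains$end[i]
    out[i, !inside] <- 0
  }
  out[is.na(out)] <- 0
  out
}

#' Write unique segments as BED6+
#'
#' Extra columns: per-condition log2 values, cluster, category (when
#' present).
#'
#' @param segments segment `data.frame`.
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(segments) > 0) {
    lc <- log2_cols(segments)
    extra <- lapply(seq_len(nrow(segments)), function(i) {
      parts <- signif(unlist(segments[i, lc]), 6)
      paste(c(parts,
              if (!is.null(segments$cluster)) segments$cluster[i],
              if (!is.null(segments$category)) segments$category[i]),
            collapse = "\t")
    })
    writeLines(paste(segments$chrom, segments$start, segments$end,
                     paste0("seg_", seq_len(nrow(segments))), 0, ".",
                     unlist(extra), sep = "\t"), con)
  }
  invisible(path)
}
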