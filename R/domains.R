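#' Domain-calling parameters
#'
#' @param F percentile defining the domain cutoff: the cutoff is the
#'   smallest normalized bin value greater than the values of `F`% of all
#'   genome-wide bins.  95 suits most datasets; 75 suits datasets with a
#'   depleted global signal (e.g. K27M-mutant lines).
#' @param max_jump maximal gap in bp that may be bridged while linking
#'   windows (tolerates short mappability dropouts).
#' @param jump_frac fraction of the cutoff every gap bin must still reach
#'   for the gap to be bridged.
#' @param min_log2_igg minimal log2 enrichment over the IgG control for a
#'   domain to be retained (2 = 4-fold over IgG).
#' @param igg_pseudocount pseudocount added symmetrically to both means in
#'   the IgG ratio, in normalized units.
#' @return A `DomainCallParams` object.
#' @export
domain_call_params <- function(F = 95, max_jump = 750, jump_frac = 0.75,
                               min_log2_igg = 2, igg_pseudocount = 0.01) {
  stopifnot(F > 0, F < 100, max_jump >= 0, jump_frac > 0, jump_frac <= 1,
            igg_pseudocount >= 0)
  structure(list(F = F, max_jump = max_jump, jump_frac = jump_frac,
                 min_log2_igg = min_log2_igg,
                 igg_pseudocount = igg_pseudocount),
            class = "DomainCallParams")
}

#' Percentile domain cutoff
#'
#' The cutoff is the smallest observed bin value strictly greater than the
#' values of `F`% of all genome-wide bins (nearest rank over every bin
#' including zeros; no interpolation).
#'
#' @param track `CoverageTrack` (typically combined and smoothed).
#' @param F percentile (0 < F < 100).
#' @return numeric cutoff.
#' @export
domain_cutoff <- function(track, F = 95) {
  v <- track_values(track)
  if (length(v) == 0) stop("empty track")
  m <- length(v)
  sv <- sort(v)
  # unique values with counts of strictly smaller bins
  uv <- unique(sv)
  below <- c(0, cumsum(tabulate(match(sv, uv))))[seq_along(uv)]
  need <- F * m / 100 - 1e-9
  ok <- below >= need
  if (!any(ok)) {
    stop("degenerate distribution: no bin value exceeds ", F,
         "% of the windows")
  }
  uv[which(ok)[1]]
}

#' Link bins into domains with gap jumping
#'
#' Maximal runs of bins with value >= cutoff are merged across a gap iff
#' the gap is at most `max_jump` bp long and every gap bin still reaches
#' `jump_frac * cutoff`.  Domains never span chromosomes.
#'
#' @param track smoothed `CoverageTrack`.
#' @param cutoff domain cutoff from [domain_cutoff()].
#' @param params [domain_call_params()] object.
#' @return `data.frame` of domains: `chrom`, `start`, `end`,
#'   `mean_signal` (mean over all included bins).
#' @export
link_domains <- function(track, cutoff, params = domain_call_params()) {
  stopifnot(cutoff > 0)
  bw <- track$grid$bin_width
  max_gap_bins <- floor(params$max_jump / bw)
  res <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    hot <- v >= cutoff
    if (!any(hot)) next
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge consecutive hot runs when the gap qualifies
    merged <- list()
    cur <- c(runs$start[1], runs$end[1])
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        gap_bins <- runs$start[i] - cur[2] - 1
        gap_vals <- v[(cur[2] + 1):(runs$start[i] - 1)]
        if (gap_bins <= max_gap_bins &&
            all(gap_vals >= params$jump_frac * cutoff)) {
          cur[2] <- runs$end[i]
        } else {
          merged[[length(merged) + 1]] <- cur
          cur <- c(runs$start[i], runs$end[i])
        }
      }
    }
    merged[[length(merged) + 1]] <- cur
    cl <- track$grid$chrom_sizes[[chrom]]
    for (m in merged) {
      res[[length(res) + 1]] <- data.frame(
        chrom = chrom,
        start = (m[1] - 1) * bw,
        end = min(m[2] * bw, cl),
        mean_signal = mean(v[m[1]:m[2]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_signal = numeric(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter domains by enrichment over IgG
#'
#' Keeps domains with `log2((mean_signal + eps) / (mean_igg + eps))`
#' above `min_log2_igg`; the log2 enrichment of every kept domain is
#' recorded in the `log2_igg` column.
#'
#' @param domains [link_domains()] output.
#' @param track the signal track the domains were called on.
#' @param igg_track IgG control track on the same grid.
#' @param params [domain_call_params()] object.
#' @return filtered domains with `log2_igg` column.
#' @export
igg_filter <- function(domains, track, igg_track,
                       params = domain_call_params()) {
  if (!grids_identical(track$grid, igg_track$grid)) {
    stop("signal and IgG tracks are on different grids")
  }
  eps <- params$igg_pseudocount
  if (nrow(domains) == 0) {
    domains$log2_igg <- numeric(0)
    return(domains)
  }
  mean_sig <- segment_means(track, domains)
  mean_igg <- segment_means(igg_track, domains)
  l2 <- log2((mean_sig + eps) / (mean_igg + eps))
  out <- domains[l2 > params$min_log2_igg, , drop = FALSE]
  out$log2_igg <- l2[l2 > params$min_log2_igg]
  rownames(out) <- NULL
  out
}

#' Call domains on a track
#'
#' Convenience wrapper: percentile cutoff, gap-jump linking, and (when an
#' IgG track is supplied) IgG enrichment filtering.
#'
#' @param track combined, smoothed `CoverageTrack`.
#' @param igg_track optional IgG control track.
#' @param params [domain_call_params()] object.
#' @return domain `data.frame`; the cutoff used is attached as attribute
#'   `cutoff`.
#' @export
call_domains <- function(track, igg_track = NULL,
                         params = domain_call_params()) {
  cutoff <- domain_cutoff(track, params$F)
  domains <- link_domains(track, cutoff, params)
  if (!is.null(igg_track)) {
    domains <- igg_filter(domains, track, igg_track, params)
  }
  attr(domains, "cutoff") <- cutoff
  domains
}

#' Coalesce annotation segments of one state
#'
#' Merges same-chromosome segments carrying the requested state label
#' whose ends lie within `max_gap` bp of each other (transitively), e.g.
#' "FacultativeHet" segments of a genome segmentation.
#'
#' @param segments `data.frame` with `chrom`, `start`, `end` and a label
#'   column.
#' @param state_label label value to coalesce.
#' @param max_gap maximal merged gap in bp.
#' @param label_col name of the label column.
#' @return merged intervals with a `width` column.
#' @export
coalesce_segments <- function(segments, state_label, max_gap = 500,
                              label_col = "state") {
  if (!label_col %in% names(segments)) {
    stop("segments lack a '", label_col, "' column")
  }
  sel <- segments[segments[[label_col]] == state_label, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), width = numeric(0)))
  }
  gr <- GenomicRanges::reduce(bed_to_gr(sel), min.gapwidth = max_gap + 1)
  out <- gr_to_bed(GenomicRanges::sort(gr))
  out$width <- out$end - out$start
  out
}

#' Write domains as BED6
#'
#' Score encodes the IgG enrichment as `round(100 * log2_igg)` clamped to
#' `[0, 1000]` (0 when no `log2_igg` column is present).
#'
#' @param domains domain `data.frame`.
#' @param path output path.
#' @param prefix domain-name prefix.
#' @export
write_domains_bed <- function(domains, path, prefix = "domain") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(domains) > 0) {
    score <- if (!is.null(domains$log2_igg)) {
      pmin(pmax(round(100 * domains$log2_igg), 0), 1000)
    } else rep(0, nrow(domains))
    writeLines(paste(domains$chrom, domains$start, domains$end,
                     paste0(prefix, "_", seq_len(nrow(domains))),
                     score, ".", sep = "\t"), con)
  }
  invisible(path)
}

#' Read a labeled BED file (e.g. genome-segmentation states)
#'
#' @param path BED path; column 4 is taken as the state label.
#' @return `data.frame` with `chrom`, `start`, `end`, `state`.
#' @export
read_labeled_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("labeled BED needs at least 4 columns")
  data.frame(chrom = as.character(tab[[1]]), start = as.numeric(tab[[2]]),
             end = as.numeric(tab[[3]]), state = as.character(tab[[4]]),
             stringsAsFactors = FALSE)
}
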