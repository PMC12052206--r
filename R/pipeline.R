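#' Build a pipeline run configuration
#'
#' Either `samples` (file-based input) or `simulate` (synthetic demo) must
#' be given.  File-based samples map each condition to replicate fragment
#' BEDs, spike-in fragment BEDs (one per replicate, spike_in mode) and
#' IgG fragment BEDs.
#'
#' @param conditions ordered condition names; the first is the reference.
#' @param samples named list: per condition, a list with `fragments`
#'   (character vector of BED paths), `spike` (same length, spike_in
#'   mode) and optionally `igg` (BED paths; required when IgG filtering
#'   is on).
#' @param simulate a [sim_config()] plus truth options: list with
#'   `config`, `n_domains`, `scenario_mix`, `n_replicates`.
#' @param chrom_sizes named vector (file mode) of target chromosome
#'   lengths.
#' @param norm_mode `"spike_in"` or `"depth"`.
#' @param params [domain_call_params()].
#' @param min_len,max_len fragment length retention window in bp.
#' @param bin_width,half_span binning and smoothing scales in bp.
#' @param k clusters for the trajectory k-means.
#' @param seed run seed (all randomness flows from it).
#' @param use_igg apply the IgG enrichment filter.
#' @param out_dir output directory.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(conditions, samples = NULL, simulate = NULL,
                       chrom_sizes = NULL,
                       norm_mode = c("spike_in", "depth"),
                       params = domain_call_params(),
                       min_len = 120, max_len = 500,
                       bin_width = 100, half_span = 1000,
                       k = 6, seed = 1L, use_igg = TRUE,
                       out_dir = tempfile("k27run")) {
  norm_mode <- match.arg(norm_mode)
  if (is.null(samples) == is.null(simulate)) {
    stop("exactly one of 'samples' or 'simulate' must be given")
  }
  if (length(conditions) < 2) stop("need at least two conditions")
  if (!is.null(samples)) {
    missing <- setdiff(conditions, names(samples))
    if (length(missing) > 0) {
      stop("no sample entry for condition(s): ",
           paste(missing, collapse = ", "))
    }
    for (cond in conditions) {
      s <- samples[[cond]]
      if (is.null(s$fragments) || length(s$fragments) == 0) {
        stop("condition '", cond, "' has no fragment files")
      }
      if (norm_mode == "spike_in" &&
          length(s$spike) != length(s$fragments)) {
        stop("condition '", cond,
             "': spike_in mode needs one spike-in file per replicate")
      }
      if (use_igg && (is.null(s$igg) || length(s$igg) == 0)) {
        stop("condition '", cond,
             "': IgG filtering enabled but no IgG files given")
      }
    }
    if (is.null(chrom_sizes)) stop("file mode requires chrom_sizes")
  }
  structure(list(conditions = conditions, samples = samples,
                 simulate = simulate, chrom_sizes = chrom_sizes,
                 norm_mode = norm_mode, params = params,
                 min_len = min_len, max_len = max_len,
                 bin_width = bin_width, half_span = half_span, k = k,
                 seed = as.integer(seed), use_igg = use_igg,
                 out_dir = out_dir),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(domain_call_params,
                    y$params %||% list())
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate$config %||% list()
    if (!is.null(sim_args$chrom_sizes)) {
      sim_args$chrom_sizes <- unlist(sim_args$chrom_sizes)
    }
    if (!is.null(sim_args$spike_chrom_sizes)) {
      sim_args$spike_chrom_sizes <- unlist(sim_args$spike_chrom_sizes)
    }
    sim <- list(config = do.call(sim_config, sim_args),
                n_domains = y$simulate$n_domains %||% 12,
                scenario_mix = unlist(y$simulate$scenario_mix %||%
                                        c(same = 0.25, shrinking = 0.25,
                                          spreading = 0.25, new = 0.25)),
                n_replicates = y$simulate$n_replicates %||% 3)
  }
  run_config(conditions = y$conditions,
             samples = y$samples,
             simulate = sim,
             chrom_sizes = if (!is.null(y$chrom_sizes))
               unlist(y$chrom_sizes),
             norm_mode = y$norm_mode %||% "spike_in",
             params = params,
             min_len = y$min_len %||% 120, max_len = y$max_len %||% 500,
             bin_width = y$bin_width %||% 100,
             half_span = y$half_span %||% 1000,
             k = y$k %||% 6, seed = y$seed %||% 1L,
             use_igg = y$use_igg %||% TRUE,
             out_dir = y$out_dir %||% tempfile("k27run"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fragments (target, spike, igg lists per replicate) for one condition
load_condition_fragments <- function(config, cond, truth = NULL) {
  if (!is.null(config$simulate)) {
    n_rep <- config$simulate$n_replicates
    reps <- lapply(seq_len(n_rep), function(r) {
      simulate_fragments(truth, cond, config$simulate$config,
                         replicate = r)
    })
  } else {
    s <- config$samples[[cond]]
    reps <- lapply(seq_along(s$fragments), function(r) {
      list(target = read_fragments_bed(s$fragments[r]),
           spike = if (config$norm_mode == "spike_in")
             read_fragments_bed(s$spike[r]) else empty_fragments(),
           igg = if (config$use_igg && r <= length(s$igg))
             read_fragments_bed(s$igg[r]) else empty_fragments())
    })
  }
  reps
}

condition_tracks <- function(config, cond, grid, truth, log) {
  reps <- load_condition_fragments(config, cond, truth)
  rep_tracks <- list()
  igg_tracks <- list()
  for (r in seq_along(reps)) {
    frags <- filter_fragments(reps[[r]]$target, config$min_len,
                              config$max_len)
    factor <- if (config$norm_mode == "spike_in") {
      spike_in_factor(nrow(reps[[r]]$spike))
    } else {
      depth_factor(nrow(reps[[r]]$target))
    }
    log(list(stage = "normalize", condition = cond, replicate = r,
             n_fragments = nrow(frags), norm_mode = config$norm_mode,
             factor = factor))
    rep_tracks[[r]] <- bin_coverage(frags, grid, factor,
                                    sample_id = paste0(cond, "_rep", r),
                                    norm_mode = config$norm_mode)
    if (config$use_igg && nrow(reps[[r]]$igg) > 0) {
      igg <- filter_fragments(reps[[r]]$igg, config$min_len,
                              config$max_len)
      igg_tracks[[length(igg_tracks) + 1]] <-
        bin_coverage(igg, grid, factor,
                     sample_id = paste0(cond, "_igg", r),
                     norm_mode = config$norm_mode)
    }
  }
  combined <- smooth_running_average(combine_replicates(rep_tracks),
                                     config$half_span)
  igg <- if (length(igg_tracks) > 0) {
    smooth_running_average(combine_replicates(igg_tracks),
                           config$half_span)
  } else NULL
  list(track = combined, igg = igg)
}

#' Run the domain-dynamics pipeline end to end
#'
#' Per condition: length-filter fragments, normalize (spike-in or depth),
#' bin at 100 bp, combine replicates, smooth; then call domains
#' (percentile cutoff, gap linking, IgG filter), classify boundary
#' changes of every non-reference condition against the reference,
#' disjoin all conditions into unique segments, quantify and cluster
#' their trajectories, and fit the bimodal model to the last-vs-first
#' log2 ratios.  All outputs are plain text and reruns with the same
#' config are byte-identical.
#'
#' @param config a `RunConfig`.
#' @return invisibly, a result bundle: tracks, domains, segments,
#'   summaries, fit, cut points, truth (simulate mode), provenance.
#' @export
run_domain_diff <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list()
  logf <- file.path(config$out_dir, "provenance.jsonl")
  if (file.exists(logf)) unlink(logf)
  log <- function(entry) {
    prov[[length(prov) + 1]] <<- entry
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n", file = logf,
        append = TRUE, sep = "")
  }
  log(list(stage = "config", conditions = config$conditions,
           norm_mode = config$norm_mode, F = config$params$F,
           max_jump = config$params$max_jump,
           jump_frac = config$params$jump_frac,
           min_log2_igg = config$params$min_log2_igg,
           min_len = config$min_len, max_len = config$max_len,
           bin_width = config$bin_width, half_span = config$half_span,
           k = config$k, seed = config$seed))
  truth <- NULL
  if (!is.null(config$simulate)) {
    truth_args <- list(config = config$simulate$config,
                       n_domains = config$simulate$n_domains,
                       scenario_mix = config$simulate$scenario_mix,
                       conditions = config$conditions,
                       bin_width = config$bin_width)
    for (opt in c("domain_len_range", "shift_range", "min_gap")) {
      if (!is.null(config$simulate[[opt]])) {
        truth_args[[opt]] <- config$simulate[[opt]]
      }
    }
    truth <- do.call(make_truth_set, truth_args)
    chrom_sizes <- config$simulate$config$chrom_sizes
    utils::write.table(truth, file.path(config$out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    chrom_sizes <- config$chrom_sizes
  }
  grid <- bin_grid(chrom_sizes, config$bin_width)

  tracks <- list()
  domain_sets <- list()
  cutoffs <- numeric(0)
  for (cond in config$conditions) {
    ct <- condition_tracks(config, cond, grid, truth, log)
    tracks[[cond]] <- ct$track
    write_bedgraph(ct$track,
                   file.path(config$out_dir, paste0(cond, ".bedgraph")))
    igg <- if (config$use_igg) ct$igg else NULL
    doms <- call_domains(ct$track, igg, config$params)
    cutoffs[cond] <- attr(doms, "cutoff")
    log(list(stage = "call_domains", condition = cond,
             cutoff = cutoffs[[cond]], n_domains = nrow(doms)))
    domain_sets[[cond]] <- doms
    write_domains_bed(doms,
                      file.path(config$out_dir,
                                paste0(cond, "_domains.bed")),
                      prefix = cond)
  }

  ref <- config$conditions[1]
  classified <- list()
  for (cond in setdiff(config$conditions, ref)) {
    classified[[cond]] <- classify_change(domain_sets[[cond]],
                                          domain_sets[[ref]])
  }

  segments <- disjoin_segments(lapply(domain_sets, function(d)
    d[, c("chrom", "start", "end")]))
  segments <- segment_enrichment(segments, tracks)
  fit <- NULL
  groups_tab <- NULL
  if (nrow(segments) > 0) {
    last <- config$conditions[length(config$conditions)]
    segments$log2_ratio <- segments[[paste0("log2_", last)]] -
      segments[[paste0("log2_", ref)]]
    distinct <- nrow(unique(segments[, log2_cols(segments), drop = FALSE]))
    if (distinct >= config$k) {
      segments <- cluster_segments(segments, k = config$k,
                                   seed = config$seed)
    } else {
      log(list(stage = "cluster", note = "skipped: too few distinct rows"))
    }
    # per-segment change category against the reference (last condition)
    lastclass <- classified[[length(classified)]]
    hit <- GenomicRanges::findOverlaps(bed_to_gr(segments),
                                       bed_to_gr(lastclass),
                                       select = "first")
    segments$category <- lastclass$category[hit]
    if (nrow(segments) >= 100) {
      fit <- fit_bimodal(segments$log2_ratio)
      segments$group <- partition_groups(segments$log2_ratio, fit)
      groups_tab <- table(segments$group)
      log(list(stage = "mixture_fit", A = as.list(round(fit$A, 6)),
               rss = fit$rss, cut_low = fit$cut_low,
               cut_high = fit$cut_high))
    } else {
      log(list(stage = "mixture_fit",
               note = "skipped: fewer than 100 segments"))
    }
  }
  write_segments_bed(segments, file.path(config$out_dir, "segments.bed"))
  summary_tab <- if (!is.null(segments$category) &&
                     !anyNA(segments$category)) {
    category_bp_summary(segments)
  } else NULL
  if (!is.null(summary_tab)) {
    utils::write.table(summary_tab,
                       file.path(config$out_dir, "category_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bundle <- list(config = config, grid = grid, truth = truth,
                 tracks = tracks, domain_sets = domain_sets,
                 cutoffs = cutoffs, classified = classified,
                 segments = segments, fit = fit, groups = groups_tab,
                 category_summary = summary_tab, provenance = prov,
                 out_dir = config$out_dir)
  class(bundle) <- "k27_run"
  invisible(bundle)
}

#' Render a static report of a pipeline run
#'
#' Writes PNG figures (trajectory heatmap by cluster, category bp bars,
#' mixture-fit curve with cut points) and a plain-text summary into the
#' run's output directory.
#'
#' @param bundle result of [run_domain_diff()].
#' @return invisibly, the paths written.
#' @export
run_report <- function(bundle) {
  stopifnot(inherits(bundle, "k27_run"))
  dir <- bundle$out_dir
  paths <- character(0)
  seg <- bundle$segments
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  if (is.null(seg) || nrow(seg) == 0) {
    writeLines(c("== domain dynamics report ==", "no domains called"),
               con)
    close(con)
    return(invisible(txt))
  }
  writeLines(c("== domain dynamics report ==",
               paste("conditions:",
                     paste(bundle$config$conditions, collapse = ", ")),
               paste("domains per condition:",
                     paste(vapply(bundle$domain_sets, nrow, 1L),
                           collapse = ", ")),
               paste("cutoffs:", paste(signif(bundle$cutoffs, 4),
                                       collapse = ", ")),
               paste("unique segments:", nrow(seg))), con)
  close(con)
  paths <- txt
  lc <- log2_cols(seg)
  lc <- setdiff(lc, "log2_ratio")
  if (!is.null(seg$cluster) && length(lc) >= 2) {
    long <- do.call(rbind, lapply(lc, function(cn) {
      data.frame(segment = seq_len(nrow(seg)),
                 cluster = seg$cluster,
                 condition = sub("^log2_", "", cn),
                 log2 = seg[[cn]])
    }))
    long$condition <- factor(long$condition,
                             levels = sub("^log2_", "", lc))
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = condition,
      y = stats::reorder(segment, cluster),
      fill = log2)) +
      ggplot2::geom_tile() +
      ggplot2::facet_grid(rows = ggplot2::vars(cluster),
                          scales = "free_y", space = "free_y") +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                    high = "red") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
      ggplot2::labs(x = NULL, y = "segments by cluster",
                    fill = "log2 signal")
    f <- file.path(dir, "cluster_heatmap.png")
    ggplot2::ggsave(f, p, width = 5, height = 7, dpi = 120)
    paths <- c(paths, f)
  }
  if (!is.null(bundle$category_summary)) {
    cs <- bundle$category_summary
    pct_cols <- grep("^pct_", names(cs), value = TRUE)
    long <- do.call(rbind, lapply(pct_cols, function(pc) {
      data.frame(cluster = factor(cs$cluster),
                 category = sub("^pct_", "", pc), pct = cs[[pc]])
    }))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = cluster,
                                            y = pct,
                                            fill = category)) +
      ggplot2::geom_col() +
      ggplot2::theme_minimal() +
      ggplot2::labs(y = "% bp", fill = "category")
    f <- file.path(dir, "category_bars.png")
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
    paths <- c(paths, f)
  }
  if (!is.null(bundle$fit)) {
    vals <- seg$log2_ratio
    h <- graphics::hist(vals, breaks = 60, plot = FALSE)
    df <- data.frame(x = h$mids, y = h$density)
    xs <- seq(min(vals), max(vals), length.out = 400)
    curve_df <- data.frame(x = xs, y = bimodal_curve(xs, bundle$fit$A))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
      ggplot2::geom_col(width = diff(h$mids[1:2]), fill = "grey80") +
      ggplot2::geom_line(data = curve_df, colour = "red") +
      ggplot2::geom_vline(xintercept = c(bundle$fit$cut_low,
                                         bundle$fit$cut_high),
                          linetype = "dashed") +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "log2 ratio", y = "density")
    f <- file.path(dir, "mixture_fit.png")
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Bundled synthetic demo configuration
#'
#' A small two-condition run (reference vs G1-extended "treated") with
#' planted spreading/new/shrinking/same/lost domains; the lost domains
#' balance the enriched genome fraction between conditions, the regime a
#' shared percentile cutoff presumes.  Completes in a few minutes.
#'
#' @param seed run seed.
#' @param out_dir output directory.
#' @return `RunConfig`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("k27demo")) {
  run_config(
    conditions = c("reference", "treated"),
    simulate = list(
      config = sim_config(chrom_sizes = c(chrT = 4.4e6),
                          n_target_fragments = 60000,
                          n_spike_fragments = 2000,
                          n_igg_fragments = 30000,
                          enrichment_fold = 8, seed = seed),
      n_domains = 14,
      scenario_mix = c(spreading = 3, new = 3, shrinking = 2, same = 2,
                       lost = 4) / 14,
      n_replicates = 3),
    k = 4, seed = seed, out_dir = out_dir)
}
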