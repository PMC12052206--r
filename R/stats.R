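#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; input order is preserved.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overlap enrichment between two clusterings
#'
#' For every pair of an A-cluster and a B-cluster over a common segment
#' universe, tests whether the number of segments in both clusters is
#' larger (enrichment, upper tail) or smaller (depletion, lower tail)
#' than expected under random sampling without replacement.  Both
#' one-tailed p-values enter a single Benjamini-Hochberg family; the
#' smaller tail and its direction are reported per pair.
#'
#' @param labels_a,labels_b cluster label vectors over the same universe
#'   (equal length, aligned element-wise).
#' @return `data.frame` with one row per cluster pair: `cluster_a`,
#'   `cluster_b`, `k` (overlap), `K` (A-cluster size), `n` (B-cluster
#'   size), `N` (universe), `direction`, `p`, `p_adj`.
#' @export
hypergeom_overlap <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  N <- length(labels_a)
  if (N == 0) stop("empty segment universe")
  ca <- sort(unique(labels_a))
  cb <- sort(unique(labels_b))
  grid <- expand.grid(cluster_a = ca, cluster_b = cb,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$cluster_a[i]; b <- grid$cluster_b[i]
    K <- sum(labels_a == a)
    n <- sum(labels_b == b)
    k <- sum(labels_a == a & labels_b == b)
    p_enr <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_dep <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
    data.frame(cluster_a = a, cluster_b = b, k = k, K = K, n = n, N = N,
               p_enriched = p_enr, p_depleted = p_dep,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  adj <- bh_adjust(c(res$p_enriched, res$p_depleted))
  m <- nrow(res)
  adj_enr <- adj[seq_len(m)]
  adj_dep <- adj[m + seq_len(m)]
  enriched <- res$p_enriched <= res$p_depleted
  res$direction <- ifelse(enriched, "enriched", "depleted")
  res$p <- ifelse(enriched, res$p_enriched, res$p_depleted)
  res$p_adj <- ifelse(enriched, adj_enr, adj_dep)
  res[, c("cluster_a", "cluster_b", "k", "K", "n", "N", "direction", "p",
          "p_adj")]
}

#' Atomic correspondence between two segmentations
#'
#' Two experiments segment the genome differently; their comparison unit
#' is the set of atomic intersection pieces carrying both parents'
#' cluster labels.  Use the returned label columns with
#' [hypergeom_overlap()].
#'
#' @param segments_a,segments_b clustered segment `data.frame`s
#'   (`chrom`, `start`, `end`, `cluster`).
#' @return `data.frame` of intersection pieces with `cluster_a`,
#'   `cluster_b` and `width`.
#' @export
segment_correspondence <- function(segments_a, segments_b) {
  if (nrow(segments_a) == 0 || nrow(segments_b) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), width = numeric(0),
                      cluster_a = integer(0), cluster_b = integer(0)))
  }
  gr_a <- bed_to_gr(segments_a)
  gr_b <- bed_to_gr(segments_b)
  pieces <- GenomicRanges::disjoin(c(gr_a, gr_b))
  ha <- GenomicRanges::findOverlaps(pieces, gr_a, select = "first")
  hb <- GenomicRanges::findOverlaps(pieces, gr_b, select = "first")
  keep <- !is.na(ha) & !is.na(hb)
  out <- gr_to_bed(pieces[keep])
  out$width <- out$end - out$start
  out$cluster_a <- segments_a$cluster[ha[keep]]
  out$cluster_b <- segments_b$cluster[hb[keep]]
  out
}

#' Two-sided Mann-Whitney / Wilcoxon rank-sum test
#'
#' Exact p-value by complete enumeration of group assignments (handling
#' ties through midranks) when the combined sample size is at most
#' `exact_limit`; otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_limit combined-size bound for the exact branch.
#' @return list with `statistic` (U for group `a`), `p_value`, `method`.
#' @export
rank_sum <- function(a, b, exact_limit = 20) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_limit) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    list(statistic = U, p_value = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    list(statistic = U, p_value = wt$p.value,
         method = "normal approximation")
  }
}

pairwise_rank_sum <- function(values_by_group) {
  groups <- names(values_by_group)
  if (length(groups) < 2) {
    return(data.frame(group_a = character(0), group_b = character(0),
                      statistic = numeric(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  pairs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    rs <- rank_sum(values_by_group[[g1]], values_by_group[[g2]])
    data.frame(group_a = g1, group_b = g2, statistic = rs$statistic,
               p = rs$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Per-cluster expression fold changes of overlapping genes
#'
#' Assigns genes to segment clusters by >= 1 bp overlap of the gene body
#' (a gene overlapping several clusters joins all of them), keeps
#' significantly changing genes, and compares clusters pairwise with the
#' rank-sum test and Benjamini-Hochberg correction.
#'
#' @param gene_table `data.frame` with `chrom`, `start`, `end`,
#'   `gene_id`, `log2fc`, `padj`.
#' @param segments clustered segment `data.frame`.
#' @param min_abs_log2fc,max_padj significance thresholds for inclusion.
#' @return list: `assignments` (gene/cluster pairs), `by_cluster`
#'   (named list of log2FC vectors), `tests` (pairwise rank-sum table,
#'   empty with a note when < 2 clusters have genes), `n_unassigned`
#'   (significant genes overlapping no segment).
#' @export
gene_cluster_expression <- function(gene_table, segments,
                                    min_abs_log2fc = 1, max_padj = 0.05) {
  need <- c("chrom", "start", "end", "gene_id", "log2fc", "padj")
  if (!all(need %in% names(gene_table))) {
    stop("gene_table needs columns: ", paste(need, collapse = ", "))
  }
  sig <- gene_table[!is.na(gene_table$padj) &
                      abs(gene_table$log2fc) > min_abs_log2fc &
                      gene_table$padj < max_padj, , drop = FALSE]
  if (nrow(sig) == 0 || nrow(segments) == 0) {
    return(list(assignments = data.frame(), by_cluster = list(),
                tests = data.frame(), n_unassigned = nrow(sig),
                note = "no significant genes overlap any segment"))
  }
  hits <- GenomicRanges::findOverlaps(bed_to_gr(sig), bed_to_gr(segments),
                                      minoverlap = 1)
  qh <- S4Vectors::queryHits(hits)
  assignments <- data.frame(
    gene_id = sig$gene_id[qh],
    log2fc = sig$log2fc[qh],
    cluster = segments$cluster[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  assignments <- unique(assignments)
  n_unassigned <- sum(!seq_len(nrow(sig)) %in% qh)
  by_cluster <- split(assignments$log2fc, assignments$cluster)
  note <- NULL
  if (length(by_cluster) < 2) {
    note <- "all assigned genes fall in one cluster; no pairwise tests"
    tests <- data.frame()
  } else {
    tests <- pairwise_rank_sum(by_cluster)
  }
  list(assignments = assignments, by_cluster = by_cluster, tests = tests,
       n_unassigned = n_unassigned, note = note)
}

#' Distribution summaries of external log2 ratios per segment group
#'
#' @param groups character vector of group labels per segment (e.g.
#'   CL1-CL3 from [partition_groups()]).
#' @param values numeric vector of external log2 ratios, aligned with
#'   `groups`; segments with missing values are dropped (count reported).
#' @return list: `summary` (per-group n, median, quartiles), `tests`
#'   (pairwise rank-sum + BH; skipped with a note when any group has a
#'   single segment), `n_dropped`.
#' @export
group_log2_summary <- function(groups, values) {
  if (length(groups) != length(values)) {
    stop("groups and values must be aligned")
  }
  keep <- !is.na(values)
  n_dropped <- sum(!keep)
  groups <- groups[keep]
  values <- values[keep]
  by_group <- split(values, groups)
  summary <- do.call(rbind, lapply(names(by_group), function(g) {
    v <- by_group[[g]]
    data.frame(group = g, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  note <- NULL
  if (length(by_group) < 2 || any(vapply(by_group, length, 1L) < 2)) {
    note <- "tests skipped: need >= 2 groups with >= 2 segments each"
    tests <- data.frame()
  } else {
    tests <- pairwise_rank_sum(by_group)
  }
  list(summary = summary, tests = tests, n_dropped = n_dropped,
       note = note)
}
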