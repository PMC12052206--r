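test_that("disjoin produces the atomic segments of the boundary union", {
  A <- data.frame(chrom = "chrT", start = 0, end = 300)
  B <- data.frame(chrom = "chrT", start = 100, end = 400)
  seg <- disjoin_segments(list(A = A, B = B))
  expect_equal(seg$start, c(0, 100, 300))
  expect_equal(seg$end, c(100, 300, 400))
  expect_equal(seg$in_A, c(TRUE, TRUE, FALSE))
  expect_equal(seg$in_B, c(FALSE, TRUE, TRUE))

  same <- disjoin_segments(list(A = A, B = A))
  expect_equal(same[, c("chrom", "start", "end")], A)
})

test_that("disjoin invariants hold: disjoint, union-preserving, atomic", {
  set.seed(202)
  for (i in 1:100) {
    sets <- list(a = random_domains(1e5), b = random_domains(1e5),
                 c = random_domains(1e5))
    seg <- disjoin_segments(sets)
    # pairwise disjoint
    expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
    # union preserved, bp-exact
    all_in <- reduce_domains(do.call(rbind, sets))
    expect_equal(reduce_domains(seg[, 1:3]), all_in)
    # matches the per-bp label-vector oracle
    oracle <- oracle_disjoin_1chrom(sets, 1e5)
    expect_equal(seg$start, oracle$start)
    expect_equal(seg$end, oracle$end)
    expect_equal(seg$in_a, oracle$V1)
    expect_equal(seg$in_b, oracle$V2)
    expect_equal(seg$in_c, oracle$V3)
  }
})

test_that("reduce merges overlapping and bookended intervals", {
  book <- data.frame(chrom = "chrT", start = c(0, 100), end = c(100, 200))
  expect_equal(reduce_domains(book),
               data.frame(chrom = "chrT", start = 0, end = 200))
  disj <- data.frame(chrom = "chrT", start = c(0, 300), end = c(100, 400))
  expect_equal(reduce_domains(disj), disj)

  set.seed(7)
  for (i in 1:50) {
    d <- data.frame(chrom = "chrT",
                    start = s <- sample(1000, 8),
                    end = s + sample(200, 8))
    red <- reduce_domains(d)
    # sweep-line union oracle on bp labels
    lab <- logical(1300)
    for (j in 1:8) lab[(d$start[j] + 1):d$end[j]] <- TRUE
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    expect_equal(red$start, (ends - r$lengths)[r$values])
    expect_equal(red$end, ends[r$values])
  }
})

test_that("segment enrichment averages bins per condition", {
  tr_const <- make_track(rep(4, 10))
  seg <- data.frame(chrom = "chrT", start = c(0, 300), end = c(300, 800))
  out <- segment_enrichment(seg, list(x = tr_const), pseudocount = 0)
  expect_equal(out$mean_x, c(4, 4))
  expect_equal(out$log2_x, c(2, 2))

  tr <- make_track(c(1, 2, 4, 8))
  out <- segment_enrichment(data.frame(chrom = "chrT", start = 100,
                                       end = 300),
                            list(x = tr), pseudocount = 0)
  expect_equal(out$mean_x, 3)  # bins valued 2 and 4

  set.seed(30)
  tr2 <- make_track(runif(10))
  segr <- data.frame(chrom = "chrT", start = c(0, 200, 500),
                     end = c(200, 500, 1000))
  out <- segment_enrichment(segr, list(a = tr, b = tr2)[2],
                            pseudocount = 0.01)
  direct <- vapply(1:3, function(i) {
    bins <- (segr$start[i] / 100 + 1):(segr$end[i] / 100)
    mean(tr2$values$chrT[bins])
  }, numeric(1))
  expect_equal(out$mean_b, direct)
  expect_equal(out$log2_b, log2(direct + 0.01))
  expect_error(
    segment_enrichment(data.frame(chrom = "chrT", start = 50, end = 200),
                       list(x = tr)), "not aligned")
})

test_that("k-means clustering recovers planted blobs and relabels by change", {
  set.seed(40)
  lo <- matrix(rnorm(60 * 3, 0, 0.05), ncol = 3)
  lo[, 3] <- lo[, 3] - 3        # strong loss trajectory
  hi <- matrix(rnorm(60 * 3, 0, 0.05), ncol = 3)
  hi[, 3] <- hi[, 3] + 3        # strong gain trajectory
  seg <- data.frame(chrom = "chrT", start = seq(0, by = 100,
                                                length.out = 120),
                    end = seq(100, by = 100, length.out = 120),
                    width = 100)
  feats <- rbind(lo, hi)
  seg$log2_t0 <- feats[, 1]
  seg$log2_t1 <- feats[, 2]
  seg$log2_t2 <- feats[, 3]
  out <- cluster_segments(seg, k = 2, seed = 5)
  expect_equal(out$cluster, rep(c(1, 2), each = 60))

  # relabel rule: cluster k has the largest mean last-minus-first change
  change <- out$log2_t2 - out$log2_t0
  expect_gt(mean(change[out$cluster == 2]),
            mean(change[out$cluster == 1]))

  # permutation of rows does not change the labels
  perm <- sample(nrow(seg))
  out_p <- cluster_segments(seg[perm, ], k = 2, seed = 5)
  expect_equal(out_p$cluster, out$cluster[perm])

  ident <- seg
  ident$log2_t0 <- 1; ident$log2_t1 <- 1; ident$log2_t2 <- 1
  expect_error(cluster_segments(ident, k = 2, seed = 1), "distinct")
})

test_that("boundary-change classification follows the four-way taxonomy", {
  ref <- data.frame(chrom = "chrT", start = 1000, end = 2000)
  # identical boundaries -> one "same" segment
  seg <- classify_change(ref, ref)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$category, "same")

  # extension past the reference boundary -> spreading + same
  seg <- classify_change(data.frame(chrom = "chrT", start = 800,
                                    end = 2000), ref)
  expect_equal(seg$category[order(seg$start)], c("spreading", "same"))
  expect_equal(seg$start[order(seg$start)], c(800, 1000))

  # no reference overlap -> new (the abandoned reference is shrinking)
  seg <- classify_change(data.frame(chrom = "chrT", start = 5000,
                                    end = 6000), ref)
  expect_equal(seg$category[order(seg$start)], c("shrinking", "new"))

  # retraction -> reference-only bp is shrinking
  seg <- classify_change(data.frame(chrom = "chrT", start = 1200,
                                    end = 2000), ref)
  expect_equal(seg$category[order(seg$start)], c("shrinking", "same"))

  # reference domain with no treated overlap at all -> shrinking
  seg <- classify_change(data.frame(chrom = "chrT", start = 5000,
                                    end = 6000),
                         data.frame(chrom = "chrT",
                                    start = c(1000, 5000),
                                    end = c(2000, 6000)))
  expect_equal(seg$category[seg$start == 1000], "shrinking")

  # a domain can shrink on one side and spread on the other
  seg <- classify_change(data.frame(chrom = "chrT", start = 500,
                                    end = 1800), ref)
  expect_setequal(seg$category, c("spreading", "same", "shrinking"))
})

test_that("every bp of the two-set union gets exactly one category", {
  set.seed(88)
  for (i in 1:50) {
    treated <- random_domains(1e5)
    reference <- random_domains(1e5)
    seg <- classify_change(treated, reference)
    expect_false(anyNA(seg$category))
    expect_true(all(seg$category %in% c("same", "shrinking", "spreading",
                                        "new")))
    expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
    expect_equal(reduce_domains(seg[, 1:3]),
                 reduce_domains(rbind(treated, reference)))
    # reference-only bp is always shrinking; shared bp always same
    expect_true(all(seg$category[seg$in_treated & seg$in_reference] ==
                      "same"))
    expect_true(all(seg$category[!seg$in_treated] == "shrinking"))
  }
})

test_that("category bp summaries aggregate per cluster", {
  seg <- data.frame(chrom = "chrT", start = 0, end = 1000, width = 1000,
                    category = "new", cluster = 6)
  out <- category_bp_summary(seg)
  expect_equal(out$pct_new, 100)
  expect_equal(out$bp_new, 1000)

  seg2 <- rbind(seg, data.frame(chrom = "chrT", start = 2000, end = 2500,
                                width = 500, category = "same",
                                cluster = 6))
  out <- category_bp_summary(seg2)
  expect_equal(out$pct_new + out$pct_same + out$pct_shrinking +
                 out$pct_spreading, 100, tolerance = 1e-9)
  expect_equal(out$pct_new, 100 * 1000 / 1500)

  expect_error(category_bp_summary(data.frame(chrom = "chrT", start = 0,
                                              end = 1, width = 1,
                                              category = NA,
                                              cluster = 1)),
               "classified")

  # randomized planted scenario matches direct aggregation
  set.seed(91)
  cats <- sample(c("same", "shrinking", "spreading", "new"), 40, TRUE)
  cl <- sample(1:3, 40, TRUE)
  w <- sample(100:900, 40, TRUE)
  segr <- data.frame(chrom = "chrT", start = 0, end = w, width = w,
                     category = cats, cluster = cl)
  out <- category_bp_summary(segr)
  for (k in 1:3) {
    expect_equal(out$bp_new[out$cluster == k],
                 sum(w[cl == k & cats == "new"]))
  }
})

test_that("feature containment and reference overlap percentages", {
  seg <- data.frame(chrom = "chrT", start = c(0, 1000, 2000),
                    end = c(500, 1500, 2500), width = 500,
                    cluster = c(1, 1, 2))
  inside <- data.frame(chrom = "chrT", start = c(100, 1100, 2100),
                       end = c(200, 1200, 2200))
  ff <- feature_fraction(seg, inside)
  expect_equal(ff$pct_with_feature, c(100, 100))
  none <- feature_fraction(seg, inside[0, ])
  expect_equal(none$pct_with_feature, c(0, 0))

  # brute-force pairwise overlap check on random placements
  set.seed(17)
  feats <- data.frame(chrom = "chrT", start = fs <- sample(2400, 30),
                      end = fs + sample(50, 30, TRUE))
  ff <- feature_fraction(seg, feats)
  manual <- vapply(seq_len(nrow(seg)), function(i)
    any(feats$start < seg$end[i] & feats$end > seg$start[i]),
    logical(1))
  expect_equal(ff$n_with_feature,
               c(sum(manual[1:2]), sum(manual[3])))

  ov <- overlap_bp_with_reference(seg, seg[, 1:3])
  expect_equal(ov$pct_overlap, c(100, 100))
  far <- data.frame(chrom = "chrT", start = 9000, end = 9500)
  expect_equal(overlap_bp_with_reference(seg, far)$pct_overlap, c(0, 0))

  ref <- data.frame(chrom = "chrT", start = c(250, 1250),
                    end = c(350, 2250))
  ov <- overlap_bp_with_reference(seg, ref)
  # per-bp oracle: cluster1 = (100 + 250) / 1000, cluster2 = 250 / 500
  expect_equal(ov$overlap_bp, c(350, 250))
  expect_equal(ov$pct_overlap, c(35, 50))
})

test_that("center-anchored signal matrices index the track directly", {
  tr <- make_track(rep(2.5, 100))
  doms <- data.frame(chrom = "chrT", start = c(2000, 5000),
                     end = c(3000, 6000))
  m <- signal_matrix_around_centers(doms, tr, flank = 500)
  expect_equal(dim(m), c(2, 11))
  expect_true(all(m == 2.5))

  # near-edge domain rows are NA-padded
  edge <- data.frame(chrom = "chrT", start = 0, end = 200)
  m <- signal_matrix_around_centers(edge, tr, flank = 500)
  expect_true(anyNA(m[1, ]))

  # self-ratio: 0 inside domains by arithmetic, 0 outside by the zeroing
  r <- ratio_matrix_around_centers(doms, tr, tr, flank = 500)
  expect_true(all(r == 0))

  set.seed(12)
  tr2 <- make_track(runif(100))
  m <- signal_matrix_around_centers(doms[1, ], tr2, flank = 300)
  center_bin <- floor(2500 / 100) + 1
  expect_equal(unname(m[1, ]),
               tr2$values$chrT[(center_bin - 3):(center_bin + 3)])
})
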