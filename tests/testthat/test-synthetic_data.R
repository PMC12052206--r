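test_that("truth sets honor scenario mix, disjointness and determinism", {
  cfg <- sim_config(chrom_sizes = c(chrT = 2e6), seed = 42)

  expect_equal(nrow(make_truth_set(cfg, 0)), 0)

  tr <- make_truth_set(cfg, 4, c(same = 0.5, new = 0.5))
  expect_equal(as.vector(sort(table(tr$scenario))), c(2, 2))
  expect_equal(sum(tr$scenario == "same"), 2)
  # pairwise disjoint union footprints
  tr <- tr[order(tr$start), ]
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))

  tr2 <- make_truth_set(cfg, 4, c(same = 0.5, new = 0.5))
  expect_identical(tr, tr2)
  cfg2 <- sim_config(chrom_sizes = c(chrT = 2e6), seed = 43)
  tr3 <- make_truth_set(cfg2, 4, c(same = 0.5, new = 0.5))
  expect_false(all(tr3$start == tr$start))
})

test_that("scenario intervals are consistent with their labels", {
  cfg <- sim_config(chrom_sizes = c(chrT = 4e6), seed = 5)
  tr <- make_truth_set(cfg, 10, c(same = 0.2, shrinking = 0.2,
                                  spreading = 0.2, new = 0.2, lost = 0.2))
  for (i in seq_len(nrow(tr))) {
    sc <- tr$scenario[i]
    if (sc == "same") {
      expect_equal(tr$treated_start[i], tr$reference_start[i])
      expect_equal(tr$treated_end[i], tr$reference_end[i])
    } else if (sc == "shrinking") {
      expect_true(tr$treated_start[i] > tr$reference_start[i])
      expect_true(tr$treated_end[i] < tr$reference_end[i])
    } else if (sc == "spreading") {
      expect_true(tr$treated_start[i] < tr$reference_start[i])
      expect_true(tr$treated_end[i] > tr$reference_end[i])
    } else if (sc == "new") {
      expect_false(tr$reference_present[i])
      expect_true(tr$treated_present[i])
    } else {
      expect_true(tr$reference_present[i])
      expect_false(tr$treated_present[i])
    }
  }
})

test_that("placement fails loudly when the genome is too small", {
  cfg <- sim_config(chrom_sizes = c(chrT = 50000), seed = 1)
  expect_error(make_truth_set(cfg, 10), "could not place")
  expect_error(make_truth_set(cfg, 2, c(bogus = 1)), "unknown scenario")
  expect_error(
    make_truth_set(cfg, 2, c(same = 0.6, new = 0.5)), "sum to 1")
})

test_that("fragment counts are conserved and streams are deterministic", {
  cfg <- sim_config(chrom_sizes = c(chrT = 1e6),
                    n_target_fragments = 5000, n_spike_fragments = 700,
                    n_igg_fragments = 900, seed = 9)
  tr <- make_truth_set(cfg, 2, c(same = 1))
  fr <- simulate_fragments(tr, "treated", cfg)
  expect_equal(nrow(fr$target), 5000)
  expect_equal(nrow(fr$spike), 700)
  expect_equal(nrow(fr$igg), 900)
  expect_true(all(startsWith(fr$spike$chrom, "spike_")))
  expect_true(all(fr$target$end <= 1e6 & fr$target$start >= 0))

  fr2 <- simulate_fragments(tr, "treated", cfg)
  expect_identical(fr, fr2)
  # byte-identical files on rerun
  f1 <- tempfile(); f2 <- tempfile()
  write_fragments_bed(fr$target, f1)
  write_fragments_bed(fr2$target, f2)
  expect_identical(readLines(f1), readLines(f2))
  # replicates differ but are reproducible
  fr_r2 <- simulate_fragments(tr, "treated", cfg, replicate = 2)
  expect_false(identical(fr$target, fr_r2$target))

  expect_error(simulate_fragments(tr, "nosuch", cfg), "reference")

  cfg0 <- sim_config(chrom_sizes = c(chrT = 1e6), n_target_fragments = 0,
                     n_spike_fragments = 10, n_igg_fragments = 10,
                     seed = 2)
  fr0 <- simulate_fragments(tr, "treated", cfg0)
  expect_equal(nrow(fr0$target), 0)
  expect_equal(nrow(fr0$spike), 10)
})

test_that("fold-1 fragments are uniform genome-wide", {
  cfg <- sim_config(chrom_sizes = c(chrT = 5e5),
                    n_target_fragments = 50000, enrichment_fold = 1,
                    seed = 31)
  tr <- manual_truth("chrT", 100000, 150000, 100000, 150000)
  fr <- simulate_fragments(tr, "treated", cfg)
  mids <- floor((fr$target$start + fr$target$end) / 2)
  counts <- tabulate(floor(mids / 100) + 1, nbins = 5000)
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted enrichment matches its closed-form expectation", {
  # one domain covering 10% of the genome at fold 9:
  # in-domain midpoint fraction = 9*0.1/(9*0.1 + 0.9) = 0.5
  cfg <- sim_config(chrom_sizes = c(chrT = 1e6),
                    n_target_fragments = 100000, enrichment_fold = 9,
                    seed = 17)
  tr <- manual_truth("chrT", 400000, 500000, 400000, 500000)
  fr <- simulate_fragments(tr, "treated", cfg)
  mids <- (fr$target$start + fr$target$end) / 2
  frac_in <- mean(mids >= 400000 & mids < 500000)
  expect_equal(frac_in, 0.5, tolerance = 0.02 / 0.5)

  # in/out midpoint density ratio converges to the fold
  dens_in <- sum(mids >= 400000 & mids < 500000) / 1e5
  dens_out <- sum(mids < 400000 | mids >= 500000) / 9e5
  expect_equal(dens_in / dens_out, 9, tolerance = 0.1)
})

test_that("fragment lengths respect the configured clip window", {
  cfg <- sim_config(chrom_sizes = c(chrT = 1e6),
                    n_target_fragments = 20000, seed = 8)
  fr <- simulate_fragments(make_truth_set(cfg, 1, c(same = 1)),
                           "reference", cfg)
  len <- fr$target$end - fr$target$start
  expect_true(all(len >= 50 & len <= 600))
  # window spans both retention cutoffs so filters exercise both branches
  expect_true(any(len < 120) && any(len > 120))
})

test_that("mixture sampler matches its stated moments", {
  expect_length(simulate_log2_mixture(c(1, 0, 0.3, 1, 1, 0.3), 0), 0)
  expect_error(simulate_log2_mixture(c(1, 0, -1, 1, 1, 0.3), 10),
               "widths")

  # single component: sample mean -> A1 within 3 SE
  v <- simulate_log2_mixture(c(1, 0, 0.3, 0, 1, 0.3), 10000, seed = 3)
  se <- (0.3 / sqrt(2)) / sqrt(10000)
  expect_lt(abs(mean(v) - 0), 3 * se)

  # equal-weight mixture of means 0 and 1: mean ~ 0.5
  v <- simulate_log2_mixture(c(1, 0, 0.3, 1, 1, 0.3), 20000, seed = 5)
  expect_equal(mean(v), 0.5, tolerance = 0.02 / 0.5)

  expect_identical(simulate_log2_mixture(c(1, 0, 0.3, 1, 1, 0.3), 100,
                                         seed = 7),
                   simulate_log2_mixture(c(1, 0, 0.3, 1, 1, 0.3), 100,
                                         seed = 7))
})

test_that("truth and fragment writers emit valid BED", {
  cfg <- sim_config(chrom_sizes = c(chrT = 2e6), seed = 12)
  tr <- make_truth_set(cfg, 3, c(spreading = 1))
  f <- tempfile(fileext = ".bed")
  write_truth_bed(tr, "treated", f)
  lines <- read.table(f, sep = "\t")
  expect_equal(nrow(lines), 3)
  expect_true(all(grepl("spreading", lines$V4)))
  expect_true(all(lines$V3 > lines$V2))

  fr <- simulate_fragments(tr, "treated", cfg)
  f2 <- tempfile(fileext = ".bed")
  write_fragments_bed(fr$target, f2)
  back <- read_fragments_bed(f2)
  expect_equal(back$start, fr$target$start)
  expect_equal(back$end, fr$target$end)
})
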