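# k27domains

Broad H3K27me3 domain calling, cross-condition comparison, and dynamics
statistics for spike-in normalized chromatin profiling (CUT&RUN,
CUT&Tag, ChIP-seq).

H3K27me3 — the repressive mark deposited by PRC2 — forms broad,
multi-kilobase facultative-heterochromatin domains. When cell state
changes (longer G1, PRC2 perturbation, the H3K27M oncohistone), these
domains spread, shrink, appear, or persist. `k27domains` implements the
full analysis chain for quantifying such dynamics from fragment-level
data:

* **Normalized binned coverage** — fragments are length-filtered
  (120–500 bp CUT&RUN, 120–1000 bp CUT&Tag, coordinate-deduplicated),
  counted in 100-bp windows and scaled by `N = 10000 / spike-in
  fragments` (spike-in mode) or `N = 2.8e9 / mapped reads` (depth
  mode); replicates are summed and smoothed with a ±1,000 bp running
  average.
* **Percentile domain calling** — the domain cutoff is the smallest bin
  value greater than the values of `F`% of genome-wide windows
  (default `F = 95`); runs of qualifying bins are linked across gaps of
  up to 750 bp whose bins all stay ≥ 0.75 × cutoff, and domains are
  kept only with log2 enrichment > 2 (4-fold) over an IgG control.
* **Unique-segment comparison** — multi-condition domain sets are
  decomposed (disjoin) into atomic segments; treated-vs-reference
  changes are classified `same` / `shrinking` / `spreading` / `new`;
  segment trajectories are clustered with reproducible k-means and
  relabeled from strongest loss (cluster 1) to strongest gain.
* **Bimodal log2-ratio model** — per-segment log2 ratios are fitted
  with `y = A0·exp(−((x−A1)/A2)²) + A3·exp(−((x−A4)/A5)²)` by nonlinear
  least squares on the histogram density, and segments partitioned into
  three groups at the component crossing (`cut_high`) and one width
  below the left mean (`cut_low`).
* **Statistics** — hypergeometric overlap enrichment/depletion between
  two segment clusterings with Benjamini–Hochberg correction, exact and
  approximate Mann–Whitney rank-sum tests, and per-cluster gene
  fold-change comparisons.
* **Synthetic data** — a generator plants domains with known change
  scenarios (including boundary truth), emits target + spike-in + IgG
  fragment sets, and samples from the two-component mixture, so every
  stage of the pipeline is verifiable without sequencing data.

## Worked example

A bundled two-condition demo (reference vs G1-extended "treated",
planted spreading/new/shrinking/same/lost domains, 3 replicates of
60,000 fragments on a 4.4-Mb toy chromosome):

```r
library(k27domains)
bundle <- run_domain_diff(demo_config(seed = 1))
sapply(bundle$domain_sets, nrow)
#> reference   treated
#>        11        10
bundle$category_summary[, c("cluster", "total_bp", "pct_same",
                            "pct_shrinking", "pct_spreading", "pct_new")]
#>   cluster total_bp pct_same pct_shrinking pct_spreading pct_new
#> 1       1    96800  0.00000           100      0.000000       0
#> 2       2   127100 96.85287             0      3.147128       0
#> 3       3    24900  0.00000             0    100.000000       0
#> 4       4    63500  0.00000             0      0.000000     100
run_report(bundle)   # heatmap, category bars, fit curve as PNG
```

Reading the summary: the k-means trajectory clusters separate cleanly
by change type — cluster 1 (strongest H3K27me3 loss) is entirely
shrinking bp, cluster 4 (strongest gain) entirely de novo domain bp,
and the stable cluster 2 is >96% boundary-identical ("same") bp, with
the residual 3% reflecting single-bin boundary wobble of the calls.
The run directory additionally contains bedGraph tracks, domain and
segment BED files, a category TSV and a line-delimited JSON provenance
log of every cutoff, factor and seed.

Individual stages are exported (`bin_coverage()`,
`smooth_running_average()`, `domain_cutoff()`, `link_domains()`,
`igg_filter()`, `disjoin_segments()`, `classify_change()`,
`cluster_segments()`, `fit_bimodal()`, `partition_groups()`,
`hypergeom_overlap()`, `rank_sum()`, ...), and a thin CLI wrapper lives
at `inst/cli/k27ds` (subcommands `simulate`, `coverage`, `calldomains`,
`run`, `report`).

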