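# krtgauge

Single-cell RNA-seq analysis of the limbal–corneal epithelium built around
one idea: the corneal-specific cytokeratin **Krt12** gauges how far an
epithelial cell has progressed along the limbus-to-cornea differentiation
path, so sorting basal cells by their normalised Krt12 expression — instead
of clustering them — lays the whole population out on a single
differentiation axis. `krtgauge` implements that workflow as a tested R
package for anyone who wants to apply, probe or extend a marker-gauge
ordering analysis.

The pipeline, stage by stage:

1. **Ingest & purge** — read genes×cells UMI counts (CSV or MatrixMarket);
   remove cells carrying melanocyte markers (DCT, TYR, TYRP1, MLANA — any
   nonzero count, which also removes epithelial–melanocyte duplets),
   Langerhans, blood and conjunctival (AQP5) cells; require at least one of
   KRT5/KRT14/KRT12.
2. **MGC trim & normalisation** — the mean gene count of a cell is its
   total UMIs divided by the number of probed genes; cells outside
   0.5 < MGC < 2.5 (decaying cells and duplets) are dropped and the rest are
   scaled to MGC = 1, giving expression in arbitrary units (A.U.).
3. **Gauge ordering & domain segmentation** — cells are sorted by Krt12;
   the gauge-negative block is domain D0 and the remaining boundaries of
   D1–D4 are fitted by continuous piecewise-linear least squares with
   non-decreasing slopes (a reproducible stand-in for reading inflections
   off the plotted curve; a manual mode accepts published boundaries).
4. **Constancy QC** — mitochondrial (MT-) and ribosomal (RPS/RPL) family
   ratios across domains check cell health and normalisation; their most
   extreme between-domain ratio calibrates the fold-change gate
   (1.35×, reciprocal 0.741, in the source study).
5. **Differential expression** — per-gene Welch tests between domain
   groups over the top-expressed gene universe, Benjamini–Hochberg
   adjustment per comparison, DEG = BHp < 0.01 plus the ratio gate; top
   tables ranked by expression ratio R (or 1/R), not BHp.
6. **Cohorts & correlation** — genes classified as continuously down/up
   regulated across the informative transitions or changing only at the
   onset of gauge expression; quantile-binned gene–gauge correlations and
   cross-sample intersections of high correlators (CC > 0.90).

Because the study's count matrices are not publicly deposited, the package
ships a negative-binomial simulator (`sim_config()`, `simulate_sample()`,
`sim_study()`) that reproduces the study's structure — contaminant loads,
decaying cells, a stepwise gauge with a steep corneal ramp, planted
fold-change modules, constant families — together with full ground truth,
so every stage is testable end to end.

## Worked example

```r
library(krtgauge)

study <- sim_study(seed = 7, n_genes = 2000,
                   n_cells = c(2900, 1100, 1000), d4_step_frac = 0.49)
panel <- marker_panel(blood = c("PTPRC", "CD52"), langerhans = "CD207")
res <- run_pipeline(lapply(study, `[[`, "cm"), out_dir = "bundle",
                    panel = panel, universe_size = 1500,
                    post_d3_gap = 50, window = 600)
res$dp$sizes
#>   D0   D1   D2   D3   D4
#> 1061  465  321  148 1323
deg_summary(res$degs)[c(1, 6, 7), c("comparison", "down_all", "up_all")]
#>    comparison down_all up_all
#>         D0-D1       76     66
#>    D123-D4i.1       43     45
#>   D4i.1-D4i.2       44     46
attr(res$cohorts, "counts")
#> continuous_down   continuous_up  d0d1_only_down    d0d1_only_up  other
#>              42              44              34              21   1359
```

Reading the output: 1,061 of the 3,318 kept cells are Krt12-negative (D0,
the compartment expected to hold the stem/precursor cells); the three
intra-limbal domains D1–D3 hold another ~930 cells before the steep
corneal ramp of D4. The D0–D1 comparison recovers the planted
down-modules and up-modules (40 + 30 down and 40 + 20 up at the
simulator's default one-log2-unit fold change, plus a handful of
borderline calls), and the trajectory classifier assigns 129 of the 130
planted cohort genes their true label.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end on a
full-scale synthetic dataset (three replicates, 10,058 cells, 8,000 genes)
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # replicate study + ground truth
Rscript analysis/02_preprocess.R  # purge, trim, normalise, accounting
Rscript analysis/03_domains.R     # gauge ordering + domain segmentation
Rscript analysis/04_qc.R          # family ratios, gate calibration, sentinels
Rscript analysis/05_diffexp.R     # DEG tables and summaries
Rscript analysis/06_cohorts.R     # trajectory cohorts + correlations
```

On the default seed the amalgam holds 6,671 kept cells of which 60% fall
in D0–D3, the family ratio means span 0.994–1.014, and GPHA2/KRT75 peak in
the first D4 quantile — the early-peak signature of the
precursor-adjacent corneal window.

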