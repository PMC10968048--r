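---
title: "Methods: marker-gauge ordering and domain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-gauge ordering and domain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`krtgauge` analyses basal limbal–corneal epithelial cells under one
biological hypothesis: differentiation in this lineage is a single linear
path, and the expression level of the corneal-specific cytokeratin Krt12
is a monotone gauge of progress along it. Instead of clustering cells in
a high-dimensional embedding, the pipeline sorts cells by their
normalised Krt12 expression and treats positions on that sorted axis as
differentiation stages. All downstream statements — domain boundaries,
differential expression between stages, trajectory cohorts, gene–gauge
correlations — are statements about this ordered axis.

The assumptions this rests on, and where they matter:

* **Monotonicity of the gauge.** If Krt12 expression were not monotone in
  differentiation stage, the ordering would interleave stages and
  between-domain contrasts would be diluted. The pipeline does not test
  this; it inherits it as the design premise.
* **Comparable calibration across cells.** Normalising every cell to a
  mean gene count (MGC) of one makes expression values (A.U.) comparable
  across cells and samples, at the cost of making the data compositional:
  a transcript gained somewhere must be lost elsewhere. The constancy QC
  (below) probes whether that distortion is material.
* **A single lineage.** Marker-based purging must remove non-epithelial
  cells first, since melanocytes, immune and conjunctival cells would
  otherwise be sorted into the low-gauge end and masquerade as
  precursors.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `detection_threshold` | 1 | UMI counts | a marker is "expressed" at any nonzero count ("and/or" purge semantics) |
| `mgc_low`, `mgc_high` | 0.5, 2.5 | MGC (counts per probed gene) | strict bounds; below = decaying cells, above = duplets |
| `probed_gene_count` | assay-specific (33,531 for the source assay) | genes | MGC denominator; all probed rows, not detected rows, so MGC is depth-comparable across samples |
| `n_domains` | 5 | — | D0 (gauge-negative) plus four fitted domains |
| `interface_trim` | 10 | cells | cells dropped on each side of the D1/D2 and D2/D3 interfaces, those comparisons only |
| `post_d3_gap`, `window` | 100, 1000 | cells | the two corneal analysis windows D4i.1/D4i.2 at the start of D4 |
| `universe_size` | 6647 | genes | top genes by summed normalised expression; testing below this depth mostly yields noise (see the expression–yield analysis) |
| `alpha` | 0.01 | — | BHp threshold of the DEG definition |
| `rho` | 1.35 | fold | ratio gate; calibrated as the most extreme invariant-family ratio, rounded up to 2 decimals (reciprocal 0.741) |
| `n_quantiles`, `cells_per_quantile` | 20, derived | — | bins of the correlation analysis (230-cell bins at full scale) |
| `cc_min` | 0.90 | — | high-correlation threshold for cross-sample intersections |

The MGC bounds are strict on both ends: the trim keeps `low < MGC < high`,
excluding boundary cells symmetrically. Marker purging applies a fixed
priority (melanocyte > Langerhans > blood > conjunctival >
not-epithelial) so each cell carries exactly one exclusion reason;
melanocyte markers purge even keratin-positive columns because those are
epithelial–melanocyte duplets.

## Domain segmentation

The source procedure identifies domains graphically, by reading
inflections off the plotted sorted-gauge curve. The package substitutes a
reproducible fit:

1. D0 is *defined*, not fitted: exactly the cells with gauge expression
   zero. Adding or removing gauge-negative cells shifts no other
   boundary.
2. On the positive part, boundaries are the breakpoints of a continuous
   piecewise-linear least-squares fit in (cell rank, gauge value), with
   segment slopes constrained non-negative and non-decreasing (the hinge
   parameterisation makes the constraint a non-negative least-squares
   problem; the unconstrained solution is used whenever it already
   satisfies the constraint).
3. Because the final ramp spans hundreds of A.U. while the intra-limbal
   structure lives below ~5 A.U., a joint fit would spend all its
   breakpoints inside the ramp. The search is therefore hierarchical,
   mirroring the two-scale graphical procedure: a 2-segment fit locates
   the takeoff of the final ramp, the earlier boundaries are fitted on
   the zoomed-in low range, and a stride-1 coordinate-descent pass
   (±10 ranks, last boundary first) polishes the joint solution.
   Breakpoint search is coordinate descent over integer ranks with a
   multi-resolution grid and two starts (equal-rank and equal-value).
4. Manual mode accepts published domain end indices; a boundary that
   would split a tie block of equal gauge values is snapped to the block
   end, so D0 always remains exactly the zero block.

On noiseless piecewise-linear curves the fit recovers the true
breakpoints exactly; with Gaussian noise at 10% of the smallest
per-domain rise it stays within ±5 ranks in at least 90% of runs (both
are tested). A known limitation: with UMI counts, gauge levels of 1–5
A.U. are realised as 1–5 counts divided by a continuous per-cell MGC, so
the sorted curve's kinks at the D1/D2 and D2/D3 interfaces are smeared
over a window of roughly (count quantisation SD)/(local slope) ranks —
hundreds of cells at full scale. This is a property of the data, not of
the fit; the interface trims and the D123 pooling in the analysis
design exist precisely because those boundaries are soft. The
takeoff into D4 and the D0 boundary are sharp and recovered to within a
few ranks.

## Differential expression

The underlying test is Welch's unequal-variance two-sided t-test on
normalised values (vectorised over genes; cross-checked against
`stats::t.test` in the test suite), with a Mann–Whitney alternative
behind a flag. The test statistic behind the source analysis is not
recorded, so absolute p-values are not reproducible in principle; the
package treats the ratio arithmetic and the synthetic-data operating
characteristics (null false-positive control, planted-effect
sensitivity) as the meaningful contract instead. Benjamini–Hochberg
adjustment (`stats::p.adjust`) is applied per comparison over exactly
the tested universe. Ratios are ratios of group means of normalised
expression — not medians, not log space, no pseudocounts; a zero
denominator yields an infinite-ratio sentinel excluded from ranked
tables rather than a shifted value, which would distort the printed
ratio scale. Degenerate rows (zero variance in both groups) get p = 1
when the means agree and p = 0 otherwise.

"Down" always means higher in the less-differentiated group of the
comparison. Top tables are ranked by R (or 1/R), not BHp, because BHp is
driven as much by expression level as by effect size — the
expression–yield analysis (`bhp_yield_by_expression`) quantifies that
decay.

Trajectory cohorts: *continuous* labels require a same-direction
BHp-only (ungated) call at all three informative transitions (D0–D1,
D123–D4i.1, D4i.1–D4i.2; the D1–D2 and D2–D3 contrasts yield essentially
nothing and would veto every gene). The *onset-only* labels (change at
D0–D1, nothing afterwards) use ungated calls for membership, with the
gated sub-count (ratio beyond 1.35×) reported alongside — the source
lists are structured that way (a membership count plus a gated subset),
and "no call afterwards" treats absence of evidence as absence of
change, a documented limitation at low power.

## The synthetic-data generator

Because the study's matrices are not deposited, the generator is the
package's ground truth. It emulates:

* three replicate samples (5843/2234/1981 cells) sharing one gene panel,
  with per-sample melanocyte loads (10%/6.4%/2%), a fifth of
  melanocyte-marker columns as duplets, and trace Langerhans, blood and
  conjunctival cells;
* decaying cells (24% of epithelial, library scale drawn so expected
  MGC < 0.5) and duplet-like high-count cells (4%, above 2.5), with
  margins exceeding the realized-total sampling noise so the MGC trim
  recovers the planted partition exactly;
* a gauge that is exactly zero in 32% of kept cells, rises linearly
  within D1–D3 (ceilings 1.77/3.18/5.32 A.U.; the D0–D3 ceiling and the
  3:1 ratio of the D23 to D1 maxima are the anchored values, the D2/D3
  split is chosen so successive slopes rise by ≥2.5×, the visibility
  condition the graphical identification relies on), then ramps linearly
  in rank to ~200 A.U. across D4;
* negative-binomial counts (size 2 by default) around log-normal
  baselines scaled so a unit-scale cell totals the probed-gene count,
  with no single free gene above 0.5% of cell mass;
* planted modules stepping by one log2 unit at each informative
  transition, mass-balanced between up- and down-modules because
  unit-MGC normalisation is zero-sum — an unbalanced design would leak
  planted folds into every constant gene;
* constant MT-/RPS/RPL families (12/34/44 genes), invariant sentinels,
  gauge-tracking sentinels, and an early-D4-peak module (GPHA2/KRT75
  shaped).

Axis positions inside D4 are defined on the gauge-value scale, not
within-sample rank, so planted structure survives amalgamation of
replicates with different sizes. The gauge count is emitted as
`round(target × library scale)` (floored at 1 outside D0): the sorted
normalised curve reproduces the planted axis up to count quantisation.

What the generator does **not** emulate: ambient RNA, batch effects
beyond library scale, gene–gene correlation beyond the planted modules,
zero inflation beyond NB sampling, or the long right tail of real
top-expressed genes (capped at 0.5% of cell mass). Passing tests
therefore certify the pipeline's arithmetic and operating
characteristics under the stated model, not robustness to artefacts the
model excludes.

## Problem sizes in tests and scripts

Unit tests run on compact instances (600–2000 genes, samples of
400–3000 cells, window geometry scaled with the cell counts). The
end-to-end property suites use full-size replicate studies
(10,058 cells) with 1,500-gene panels — 20 seeds for recovery and
constancy, 50 for the null — and the analysis scripts use an 8,000-gene
panel at full cell counts. These sizes were chosen so each suite
completes in minutes on a single CPU while the per-group cell counts
match the study's (1000-cell windows, ~2100-cell D0).

## Degenerate inputs and tie-breaks

* Duplicate gene symbols on ingest are suffixed `_2`, `_3`, … in order
  of appearance; symbols are upper-cased with a small alias map.
* Gauge ties sort stably (input order); manual boundaries never split a
  tie block.
* Universe ranking breaks total-expression ties by symbol order.
* `calibrate_ratio_gate` is invariant under swapping any ratio's
  numerator and denominator (it takes the max of each ratio and its
  reciprocal), and rounds *up* to 2 decimals so the gate always covers
  the observed extreme.
* An empty marker set disables its purge rule, except the epithelial
  requirement, which errors: silently keeping everything would
  contaminate D0.
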