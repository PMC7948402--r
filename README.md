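# polwave

Quantitative analysis of RNA polymerase II (RNAPII) behaviour from genomic
coverage tracks, for researchers studying transcription regulation with
ChIP-seq/CUT&RUN occupancy data and nascent-RNA (4sU-seq) time courses.

RNAPII pauses ~50–100 nt downstream of transcription start sites (TSS)
before being released into productive elongation. polwave implements the
two standard coverage-based readouts of this cycle, plus everything needed
to compute and validate them:

* **Pausing index** — per gene,
  `PI = log2((FPKM_TSS + 1) / (FPKM_body + 1))`, with the TSS region
  defined as −100 to +300 bp around the TSS and the gene body from +300 bp
  to the transcript end site. Higher PI means stronger promoter-proximal
  accumulation.
* **Elongation velocity from DRB/4sU clearance** — DRB blocks pause
  release; a 10-min 4sU pulse before harvest labels only newly made RNA.
  Binned `log2((signal_t + 1)/(signal_0 + 1))` profiles show a clearance
  wavefront whose position grows as `v · (t − label_duration)`; ordinary
  least squares of front position on effective time yields `v` in kb/min.
* Supporting modules: BED/bedGraph I/O with validation, the standard gene
  selection filters (FPKM > 5, no neighbouring transcript within a flank,
  length > 300 bp), library-size and spike-in normalization, metagene /
  anchored heatmap matrices with log2 fold-change maps and rankings, and a
  kinetic **simulator** (initiation–pause–release–elongation) that
  generates ground-truthed coverage fixtures for every stage.

## Worked example

Simulate a DRB time course (200 genes of 60–100 kb, true velocity
2 kb/min, 10-min label, DRB at 0/15/25/35 min), then recover the velocity:

```r
library(polwave)

p <- sim_params(n_genes = 200, length_range_bp = c(60000, 100000),
                v_kb_per_min = 2, seed = 1)
sim <- simulate_genes(p)
samples <- lapply(setNames(p$drb_times_min, p$drb_times_min), function(t)
  simulate_nascent(p, sim$truth, drb_min = t))
tc <- time_course(normalize_timecourse(samples, p$spike_reads))
cp <- clearance_profiles(tc, sim$genes, bin = 100, extent = 1e5)
fronts <- clearance_wavefronts(cp)
fronts
#>     0    15    25    35
#>     0 23900 44000 63800
estimate_velocity(fronts, label_duration_min = 10)
#> wavefront_fit: velocity 1.995 kb/min (intercept 13975 bp) from 3 time points (15, 25, 35 min)
```

The fronts advance ~20 kb per 10 min and the fitted slope recovers the
true 2 kb/min within 0.3%. The large intercept is expected: the rear of
the labelled zone is a ramp of width `v · label_duration`, so a fixed
log2 threshold crosses it at a constant offset that cancels in the slope
(see the methods vignette).

Pausing indices from a simulated occupancy track of the same genes:

```r
occ <- simulate_occupancy(p, sim$truth)
tab <- pausing_table(filter_min_length(sim$genes, 300), occ)
head(tab, 3)
#>   gene_id tss_fpkm body_fpkm pausing_index
#> 1   g0001   114.15     13.89         2.951
#> 2   g0002   291.34     27.68         3.349
#> 3   g0003    97.69     18.02         2.375
median(tab$pausing_index)
#> [1] 2.415
```

Halving the simulated pause-release rate raises the median PI by ~0.9
log2 units (`compare_distributions()` gives the rank-sum test), and genes
ranked into occupancy quartiles show strictly decreasing mean PI from the
highest- to the lowest-occupancy group — the qualitative signatures the
pipeline is designed to detect.

## Command line

`inst/cli/polwave.R` wraps the package for shell use:

```sh
Rscript inst/cli/polwave.R simulate      --seed 1 --n-genes 60 --min-len-bp 60000 --out-dir sim
Rscript inst/cli/polwave.R filter-genes  --bed sim/genes.bed --fpkm sim/fpkm.tsv --min-fpkm 5 --flank 5000 --out filtered.bed
Rscript inst/cli/polwave.R pausing-index --bed filtered.bed --track sim/occupancy.bedgraph --out pi.tsv
Rscript inst/cli/polwave.R compare-pi    --a pi_ctrl.tsv --b pi_depl.tsv
Rscript inst/cli/polwave.R metagene      --mode scaled --track sim/occupancy.bedgraph --regions filtered.bed --out mg
Rscript inst/cli/polwave.R clearance     --dir sim --bed filtered.bed --out cl
```

See `vignettes/pausing-and-clearance.Rmd` for the model, parameter
defaults, what the simulator does and does not emulate, and known
limitations.
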