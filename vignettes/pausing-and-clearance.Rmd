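---
title: "Quantifying RNAPII pausing and elongation from coverage tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNAPII pausing and elongation from coverage tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polwave)
```

## The biology and the two statistics

RNA polymerase II initiates at a gene's transcription start site (TSS),
pauses roughly 50–100 nt downstream, and is released into productive
elongation at a regulated rate. polwave quantifies two readouts of this
cycle from ordinary genomic coverage tracks:

**Pausing index.** From an occupancy track (total Pol II ChIP-seq or
similar), each gene's promoter-proximal accumulation is summarised as

$$\mathrm{PI} = \log_2\frac{\mathrm{FPKM}_{\mathrm{TSS}} + 1}
                           {\mathrm{FPKM}_{\mathrm{body}} + 1},$$

where the TSS region is 100 bp upstream to 300 bp downstream of the TSS and
the gene body runs from +300 to the transcript end site (TES). FPKM here is
coverage area per kilobase of region per million mapped reads; because the
index is a ratio of densities, the proportionality constant between
coverage area and read count cancels. The +1 pseudocounts keep the index
finite on empty regions but make it deliberately *not* invariant to track
rescaling — tracks must be depth-normalized before indices are compared
across samples.

**Clearance velocity.** In a DRB/4sU time course, DRB blocks pause release
while already-elongating polymerases run off, and a short 4sU pulse
(default 10 min) immediately before harvest labels only nascent RNA made in
that window. After `t` minutes of DRB, labelled signal is cleared from the
TSS-proximal gene body; plotting each time point's binned signal as
`log2((signal_t + 1) / (signal_0 + 1))` against distance from the TSS shows
a clearance front that advances with time. The front position is regressed
on *effective* time `t - label_duration`: during the final
`label_duration` minutes of labelling, the rear-most labelled polymerase is
one released exactly at DRB addition, which by harvest has moved
`v * t` bp but whose labelled portion starts at `v * (t - label_duration)`.
The slope of the regression, in kb/min, is the elongation velocity.

## Gene selection

All per-gene statistics are restricted by three filters mirroring standard
practice: expressed genes (FPKM strictly greater than 5 by default),
genes with no neighbouring transcript within a flank (5 kb for metagene
work, 1 kb for pausing indices), and genes longer than 300 bp (so the
gene body region is non-empty). Thresholds are strict inequalities.
Overlap filtering is strand-blind and symmetric — both members of a
conflicting pair are removed — which is the conservative reading of "no
overlapping transcripts". Because the published filter plausibly ran
against the full transcript annotation rather than the expressed subset,
`filter_nonoverlapping()` accepts an optional external `conflict_set`; the
default is the input set itself.

Coordinates are 0-based half-open (BED convention) throughout; BED12
records are reduced to their outer span because every statistic here is
span-based.

## Normalization

Two mutually exclusive modes, recorded on the track and applied at most
once:

* `library_size` — counts-per-million scaling (`1e6 / library_size`), for
  ChIP/CUT&RUN-style tracks compared within a sample.
* `spike_in` — scaling by `reference_spike / spike_in_reads`, for 4sU-seq
  time courses where absolute nascent output changes between samples. The
  reference count is a single constant shared by all samples of a
  comparison, so a global sequencing-depth factor cancels exactly; the
  choice of reference affects all samples by one common constant and no
  downstream ratio.

Directional 4sU libraries are represented as a plus/minus track pair and
gene-directed queries read the sense strand; a single unstranded track is
accepted wherever strand-specific data are unavailable, controlled simply
by what the sample list contains.

## Profile matrices

Metaplots and heatmaps are matrices of per-bin *mean* signal (averaging,
not summing, so bin-size changes do not rescale values). Point-anchored
windows use 10-bp bins by default (ChIP/CUT&RUN convention) and scaled
gene-body layouts use 2-kb flanks with 100 body segments; 100-bp bins suit
RNA-style tracks. The body partition uses boundaries
`floor(i * L / n)`, giving segments within 1 bp of each other that always
sum exactly to the gene length. Minus-strand rows are flipped so column 1
is always 5′. Windows running past the chromosome start are zero-filled
and masked out of column means rather than silently included. Log2
fold-change matrices use a pseudocount of 1 on normalized bin signal,
echoing the pausing-index pseudocount.

## The simulator

`simulate_nascent()` and `simulate_occupancy()` draw from an
initiation–pause–release–elongation model: Poisson initiation at rate
`alpha` (events/min), a pause site uniform in 50–100 nt, exponential pause
dwell with release rate `beta` (1/min), deterministic elongation at `v`
(kb/min), run-off at the TES. Expected coverage has closed forms:

* Nascent, no DRB: `alpha * label_min` per base everywhere in the gene
  (steady-state Poisson traffic).
* Nascent, DRB for `t > label_min`: zero on
  `(pause, v (t - label_min))`, rising linearly to `alpha * label_min` at
  `v t`, flat beyond. The ramp has width `v * label_min` because a position
  is labelled in proportion to the fraction of the label window during
  which pre-DRB releases could still traverse it. Promoter-proximal bases
  (TSS to pause) stay labelled at all times since initiation continues.
* Occupancy: body density `alpha / v` per base plus a pause peak of mass
  `alpha / beta` spread over a 50-bp kernel at the pause site, so halving
  the release rate doubles the peak at fixed body density.

The simulator emits the *expectation* of this process discretised at 50 bp,
multiplied by per-chunk lognormal noise (unit mean, CV 0.2 by default), a
per-sample depth factor, and accompanied by a spike-in read count that
scales with depth. This emulates: genes of varying lengths on both strands,
depth variation between samples, a fixed spike-in pool, and the full DRB
time-course geometry. It does **not** emulate read-level sampling noise,
mappability or GC artefacts, splicing, antisense/eRNA transcription, or
post-TES signal — so passing recovery tests demonstrates correctness of
the estimators under the kinetic model, not robustness to every artefact
of real libraries. Noise is keyed by `(seed, tag)` independently of the
depth factor, which is what makes depth-pair fixtures exactly proportional
and the spike-in invariance checkable to 1e-9. Fixed seeds give
byte-identical fixture files.

Default study conditions: 10-min label, DRB times {0, 15, 25, 35} min,
`v` = 2 kb/min, `alpha` = 2/min and `beta` = 1/min with 0.5 lognormal
spread, 12-kb inter-gene spacing (clear of the 5-kb overlap flank), 1e5
spike reads. Gene spacing can be overridden to construct deliberate
overlaps for filter tests.

## Wavefront detection and its offset

`wavefront()` smooths a profile with a centred running mean (width 5 bins)
and reports the first bin that rises above a threshold (default −0.5, a
half-clearance crossing on the log2 scale) and stays above it for a full
smoothing window. Because the labelled zone's rear is a linear ramp of
width `v * label_min` (see above), any fixed mid-amplitude threshold
crosses the ramp at a constant offset beyond the geometric rear edge —
with the defaults, roughly `0.7 * v * label_min`. The offset is identical
at every time point, so it lands in the regression intercept and leaves
the velocity (slope) unbiased; the intercept should therefore not be
interpreted as a pause position. The geometric rear edge itself — the
first bin with any labelled signal beyond the pause site — equals
`v (t - label_min)` to within one bin on noise-free runs, and that is the
quantity validated against the closed form in the test suite. The first
bin can be excluded from profiles (`drop_first_bin`) because residual
promoter-proximal labelling never clears.

Population-level fronts (bins averaged across genes before detection) are
the default, matching how published metaplots are read; genes used for
velocity estimation should be at least as long as the profile extent so
the front never exits a gene.

## Statistical choices

Condition comparisons of pausing indices use the two-sided
Mann–Whitney/Wilcoxon rank-sum test with normal approximation and tie
correction — distribution-free, appropriate for skewed indices; no claim
is made to reproduce any unnamed published test. Ranked groupings split
genes into `k` quantile groups whose sizes differ by at most one, ties
broken lexicographically by gene id for reproducibility, group 1 always
the top of the ordering.

## Problem sizes and numerical notes

The test suite validates counting against per-base loops (50 tracks × 20
regions), filters against O(n²) all-pairs scans (1000 genes), the rank-sum
test against full permutation enumeration (n = 10 vs 10), velocity
recovery on 200 genes of 60–100 kb (recovered within ±20% of 2 kb/min;
typically within 1%), the pausing response to a halved release rate on 500
genes, and byte-identical determinism of the whole pipeline. bedGraph
values are written with 17 significant digits so round-trips are exact.
Zero-coverage regions are implicit zeros and absent chromosomes count as
zero, so partial fixtures work without padding.

## A worked example

```{r example, eval = FALSE}
p <- sim_params(n_genes = 200, length_range_bp = c(60000, 100000),
                v_kb_per_min = 2, seed = 1)
sim <- simulate_genes(p)
samples <- lapply(setNames(p$drb_times_min, p$drb_times_min), function(t)
  simulate_nascent(p, sim$truth, drb_min = t))
tc <- time_course(normalize_timecourse(samples, p$spike_reads))
cp <- clearance_profiles(tc, sim$genes, bin = 100, extent = 1e5)
estimate_velocity(clearance_wavefronts(cp), label_duration_min = 10)
```

## Known limitations

* Velocity is a single population-level estimate; per-gene rate inference
  (changepoint or hidden-Markov approaches) is out of scope.
* The DRB-addition design is the only one supported; inhibitor-washout
  (release) designs have different geometry.
* The pausing index, like all traveling-ratio statistics, conflates pause
  occupancy and body output; interpretation across conditions requires the
  same normalization mode on both tracks.
* Coverage-area counting assumes roughly constant read length within a
  track.
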