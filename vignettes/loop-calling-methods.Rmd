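---
title: "Calling chromatin loops from Hi-C and chromatin accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin loops from Hi-C and chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A chromatin loop appears in a Hi-C contact matrix as a focal enrichment at
a pixel `(i, j)`: the two 10-kb bins touch more often than expected from
the strong decay of contact frequency with genomic distance. Loop anchors
are usually bound by CTCF/cohesin and sit in accessible chromatin, so a 1D
ATAC/DNase track carries complementary evidence: a true loop pixel has
*both* of its anchors in open chromatin, while most enriched background
pixels do not.

`loopcallr` classifies pixels with a small convolutional network over a
two-channel `w x w` window (default `w = 23` bins) centred on the pixel:

* **Contact channel** — the dense sub-matrix of raw contact values around
  `(i, j)`; cells below the matrix diagonal take the mirrored
  upper-triangle value, so windows straddling the diagonal remain
  consistent with a symmetric matrix.
* **Accessibility channel** — the outer product `A[r, c] = x_r * y_c` of
  the per-bin accessibility means over the window's rows and columns. The
  outer product is the natural 2D lift of two 1D signals: it peaks exactly
  where an accessible row anchor meets an accessible column anchor, i.e.
  at the centre of a window whose both anchors are open. Sum or minimum
  lifts would also mark the intersection but mix additive scales; the
  product keeps the channel bilinear in the two anchors and non-negative,
  so the same log-compression applies to both channels.

Each channel is normalized independently per window:
`M <- log10(1 + M)` then `M <- M / (1 + max M)`, with the maximum taken
over that window after the log step. The two steps are sequential; the
per-window maximum (rather than a chromosome-wide constant) makes every
window a self-normalized image in `[0, 1)` regardless of sequencing depth,
and an all-zero window maps to itself. The transform is rank-preserving
and not idempotent, which the tests exploit to catch accidental double
application.

### Network

Three blocks of `convolution (3x3, padding 1) -> batch normalization ->
ReLU -> dropout (rate 0.2) -> average pooling (2x2, stride 2)`, a flatten,
two fully connected layers of 64 units (each with batch normalization and
ReLU), and a single sigmoid output. With `w = 23` the spatial size shrinks
23 → 11 → 5 → 2, so the flattened representation keeps coarse position
information. This matters: an architecture that ends in one *global*
average pool is translation-invariant over the window and provably cannot
distinguish a loop at the centre from the same pattern a few bins off
centre — in early experiments such a model plateaued at validation PR-AUC
≈ 0.9 while misclassifying exactly the off-centre loop patterns, whereas a
linear probe on the centre pixels separated the classes perfectly.
Per-block local average pooling resolves the ambiguity (and cuts inference
cost roughly nine-fold); the network keeps one pooling stage per block, so
every block still ends in an averaging layer.

Default filter counts are 4/8/16 with a 64-unit FC width (about 10k
parameters). The inputs are small two-channel images and the training sets
of a desk-scale study hold on the order of 10²–10⁵ windows, so a compact
filter bank is proportionate; all counts are configurable through
`model_config()`.

### Training

The loss is binary cross-entropy (natural logarithm; predictions clamped
to `[1e-7, 1 - 1e-7]`), minimized with Adam (default betas, learning rate
0.001, batch size 128). The protocol is leave-one-chromosome-out: one
chromosome is held out for testing; the remainder are shuffled and split
80/20 into training and validation chromosomes (`loco_split()`, always at
least one validation chromosome when two or more remain). With very few
chromosomes — e.g. the three-chromosome synthetic study — a
chromosome-level validation set would consume half the training data, so
`run_study_pipeline()` instead holds out 20% of the pooled non-test
*windows* for validation; the test chromosome is never touched either way.

Two numerical choices depart from textbook defaults, both because a
desk-scale epoch contains very few optimizer steps:

* **Batch-norm calibration.** Inference-time batch-norm statistics are
  recomputed after every epoch by one dropout-free pass over the full
  training set, instead of a momentum running average. Running averages
  converge over hundreds of mini-batches; at small scale they lag far
  behind the parameters and made held-out predictions meaningless. The
  exact pass costs one extra forward per epoch and makes inference
  faithful to the training-time normalization at any dataset size.
* **Checkpointing.** The parameters with the best validation PR-AUC are
  kept, with exact PR-AUC ties broken by the lower validation loss.
  PR-AUC saturates within a few epochs once the classes separate, while
  the margin (and with it genome-wide transfer) keeps improving; the
  tie-break retains the later, better-calibrated checkpoint. Early
  stopping uses a patience of 15 epochs within a 100-epoch budget by
  default; the synthetic-study pipeline raises this to 800/150 with batch
  size 8, which gives its ~100-window training sets an optimizer-step
  count comparable to full-scale runs at batch 128.

Everything stochastic — initialization, shuffling, dropout masks — draws
from R's RNG under explicit seeds, so a full train/predict run is
bit-reproducible; the dropout uniforms are generated in R and passed to
the C++ kernels.

## Genome-wide calling

`call_loops()` composes four stages, each exposed separately:

1. `score_chromosome()` — every stored (non-zero) pixel with
   `min_dist <= j - i <= max_dist` and an in-bounds window becomes a
   candidate and receives a probability from the trained network, using
   the same window construction as training. Defaults `min_dist = 3`,
   `max_dist = 300` bins (30 kb–3 Mb at 10 kb) exclude self-ligation
   noise next to the diagonal while covering the distance range where
   experimentally supported loops live.
2. `filter_by_frequency()` — keeps candidates whose raw contact value
   strictly exceeds the per-chromosome mean over all candidates; highly
   contacting pixels are a priori more likely to be loops, and the filter
   removes the bulk of low-coverage background before thresholding.
3. `filter_by_probability()` — keeps `probability >= threshold`. The
   cutoff is a per-dataset operating point, not a constant: sequencing
   depth and training-set size move the classifier's score distribution.
   `calibrate_threshold()` picks the F1-maximizing cutoff on the
   *training* chromosomes against their own training interactions — no
   held-out information is used — which is the package's analogue of
   tuning thresholds to control call counts across datasets. The plain
   default is 0.5.
4. `pool_candidates()` — single-linkage clusters under Chebyshev distance
   `<= radius` (default 2 bins = 20 kb), each represented by its
   highest-probability pixel (ties: higher raw value, then smaller
   `(i, j)` lexicographically). Pooling is idempotent, and representatives
   of different clusters are more than the linking radius apart; the
   implementation is checked against a brute-force
   connected-components-plus-argmax oracle on hundreds of random sets.

The stage counts (candidates → after frequency → after probability →
pooled) are attached to the result and logged. The frequency and
probability filters commute — the final set is the intersection of the
two conditions — so their order is presentational.

For robustness studies, `downsample_map()` replaces each raw count by a
`Binomial(count, fraction)` draw, emulating a shallower sequencing run
without re-mapping; it refuses balanced (non-integer) input.

## Evaluation machinery

* `classification_metrics()` — precision, recall, F1 at a threshold plus
  PR-AUC by all-thresholds step integration (no interpolation), so the
  number is comparable across implementations and invariant under
  monotone transforms of the scores.
* `apa()` — aggregate peak analysis: the elementwise mean of the
  `(2 flank + 1)`-square raw windows over a loop set (default flank 10,
  a 21×21 aggregate), scored as centre value over the mean of the
  `corner x corner` block nearest the matrix diagonal (default 6×6).
  That corner is the short-distance side, where the decaying background
  is brightest, making the score a conservative enrichment measure; a
  uniform map scores exactly 1. Loops closer than `2 flank + 1` bins or
  with out-of-bounds windows are excluded and counted.
* `match_loops()` — exact mode requires both anchor bins to be equal;
  tolerant mode declares a match when, per anchor, the ±`tol` windows
  around the two anchor centres overlap (centre distance `<= 2 tol`,
  default `tol` = 10 kb). Counts are of matched elements per side, not of
  pairs, so one loop may support several matches on the other side.
* `distance_profile()` — proportions of loops per half-open genomic
  distance band.

## The synthetic study

`sim_params()`/`simulate_study()` generate the substrate for every
end-to-end test: per-chromosome contact maps, accessibility tracks and
BEDPE truth sets, written as sparse-triplet text, a cool-dialect HDF5
container, bedGraph and BEDPE, plus a JSON manifest. The generative model
and its defaults:

* **Background** — entry `(i, j)` at distance `d` is
  `Poisson(c (d+1)^-alpha)` with amplitude `c = 300` and exponent
  `alpha = 0.75`, simulated out to 40 bins. The shallow exponent is the
  sub-megabase, intra-domain regime of contact decay; the amplitude
  emulates a deeply sequenced map (hundreds of counts per near-diagonal
  pixel at 10 kb), which is the regime where loop calling is usually
  attempted. Zero draws are not stored.
* **Loops** — 30 per 2000-bin chromosome, arranged as an ordered array:
  anchor separations are drawn with probability ∝ 1/d on 3–35 bins
  (30–350 kb; short-range-heavy, as in experimentally supported loop
  sets), and consecutive loops are separated by more than the maximum
  simulated contact distance. The array layout guarantees that anchors of
  *different* loops never form a contacting pixel pair: in real data such
  anchor pairs are themselves plausible loops, and a 30-loop truth set
  cannot label them either way, so leaving them in the candidate space
  would make precision against the planted truth ill-defined. Each loop
  multiplies the local background mean by up to `s = 5` under a Gaussian
  kernel of width 1 bin.
* **Accessibility** — baseline 1.0 plus Gaussian peaks (height
  `5 x Uniform(0.5, 1.5)`, width 1 bin) at every loop-anchor bin, plus
  half-normal noise (scale 0.5); optional non-anchor "decoy" peaks
  (`acc_decoy_every`) are available to make the accessibility channel
  deliberately non-oracular, and are off in the default study.
* **Determinism** — each chromosome uses a seed derived from the master
  seed, so a bundle regenerates byte-identically (text artifacts) given
  the same parameters.

The default study sizes (3 chromosomes × 2000 bins at 10 kb, 30 loops
each) keep a full simulate–train–call–evaluate cycle around one to two
minutes on a single CPU while leaving ~75k candidate pixels per
chromosome, enough for the genome-wide stages to be exercised
realistically.

### What the simulation does and does not capture

It reproduces the features the method actually consumes: distance-decaying
Poisson counts, focal loop enrichments, accessibility peaks at anchors,
and truth interactions in the exact input formats. It does **not**
simulate TADs or compartments, coverage biases and matrix balancing,
inter-chromosomal contacts, anchors shared between loops, loop-extrusion
stripes, or the irregular peak shapes of real ATAC data. Consequently,
passing end-to-end tests demonstrates that the implementation is correct
and that the pipeline can recover planted signal under realistic noise —
it does not certify real-data performance, where label noise, confounded
anchor pairs and assay artifacts dominate. The threshold-calibration step
exists precisely because the classifier's operating point shifts with
data conditions.

## Degenerate inputs and tie-breaks

Empty candidate sets flow through every filter and the pooler unchanged;
an all-zero window normalizes to itself; windows that would overrun the
chromosome raise an error in the extractors and are skipped (and counted)
by the dataset builder and scorer; positives whose anchors share a bin
are dropped on BEDPE import with a message; duplicate mirrored triplet
entries are summed; APA refuses a loop set with no usable member;
downsampling refuses non-integer counts. Pooling ties are resolved
probability → raw value → lexicographic `(i, j)`; negative-sampler
distance buckets fall back to the nearest available distance with a
message when exhausted.

## Known limitations

* The cool reader/writer covers the single-resolution dialect (bins,
  pixels, optional weights); multi-resolution pyramids are out of scope.
* Dense per-chromosome matrices are materialized for window building and
  APA; at 10 kb this is comfortable up to a few thousand bins per
  chromosome and would need banding for full-genome mammalian
  chromosomes.
* The classifier's probabilities are not calibrated in the statistical
  sense; they order candidates well, but absolute cutoffs should be set
  per dataset (see `calibrate_threshold()`).
* Training at very small sample sizes (tens of windows) remains sensitive
  to the optimizer-step budget; the pipeline defaults are chosen for the
  bundled study sizes and scale up, not down.
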