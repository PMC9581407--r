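# loopcallr

Genome-wide chromatin loop calling from Hi-C contact maps combined with
accessible-chromatin landscapes.

Chromatin loops are point enrichments in a Hi-C contact matrix where two
distal loci (anchors, often CTCF/cohesin-bound) touch far more than the
distance-decaying background. `loopcallr` treats loop detection as binary
classification of contact-map pixels: each candidate pixel `(i, j)` at bin
resolution (10 kb by default) is represented as a two-channel 23×23 image —

* **channel 1**: the raw Hi-C sub-matrix centred on `(i, j)`;
* **channel 2**: the outer product `A[r, c] = x_r · y_c` of the binned
  accessibility signal (ATAC/DNase) over the window's row and column
  anchors, so that a pixel whose *both* anchors sit in open chromatin
  lights up at the centre.

Both channels are normalized per window as `M ← log10(1 + M)` followed by
`M ← M / (1 + max M)`. A compact convolutional network — three blocks of
`conv 3×3 → batch norm → ReLU → dropout(0.2) → average pool 2×2`, a
flatten, two fully connected layers of 64 units and a sigmoid — maps each
window to a loop probability. Training minimizes binary cross-entropy with
Adam (batch 128, learning rate 0.001) under a leave-one-chromosome-out
protocol; positive labels come from orthogonal interaction evidence
(ChIA-PET / HiChIP / Capture Hi-C anchors in BEDPE), and negatives are
sampled from non-zero pixels either matched to the positive distance
distribution or beyond its maximum. Genome-wide calling scores every
non-zero pixel in a distance band, keeps pixels above the mean contact
frequency and above a probability cutoff, and pools surviving neighbours
(single linkage, Chebyshev radius 2) into one representative call each.

The package also implements the surrounding evaluation machinery —
precision/recall/F1 and PR-AUC, aggregate peak analysis (APA) with a
centre-to-corner enrichment score, exact and ±10 kb-tolerant loop-set
matching, distance-band profiling, and binomial downsampling for
robustness studies — plus a synthetic-data generator that produces
contact maps with power-law distance decay, Poisson noise and planted
Gaussian loop enrichments, anchor-peaked accessibility tracks, and BEDPE
truth sets, so the complete pipeline runs and is tested without any
external download.

## Worked example

```r
library(loopcallr)

p <- sim_params(seed = 1)          # 3 chromosomes x 2000 bins, 30 loops each
pipe <- run_study_pipeline(p)      # simulate, train, calibrate, call
#> calling threshold: 0.9
#> chr1: 74347 candidates -> 25437 after frequency -> 389 after probability -> 30 loops
#> chr2: 74347 candidates -> 25421 after frequency -> 379 after probability -> 30 loops
#> chr3: 74347 candidates -> 25332 after frequency -> 381 after probability -> 30 loops

glance(pipe$model)
#> # A tibble: 1 × 6
#>   n_params trained epochs best_epoch best_val_prauc final_train_loss
#>      <dbl> <lgl>    <int>      <int>          <dbl>            <dbl>
#> 1    10237 TRUE       569        419              1          0.00806

pipe$call_metrics
#> # A tibble: 1 × 5
#>   n_calls n_truth precision recall    f1
#>     <int>   <int>     <dbl>  <dbl> <dbl>
#> 1      90      90         1      1     1

apa(pipe$study$maps$chr1, subset(pipe$study$truth, chrom == "chr1"))
#> <apa_result> 21x21 aggregate over 5 loops (25 excluded), APA score 2.644
```

The 90 pooled calls recover all 90 planted loops with no false positives;
the APA aggregate over the loops long enough for a 21×21 window shows a
2.6-fold centre enrichment over the short-distance corner background.
`write_loops(pipe$calls, 10000, "loops.bedpe")` exports the calls as
7-column BEDPE, `autoplot()` draws APA heatmaps and training curves, and
`tidy()`/`glance()` summarize fitted models. A command-line interface
with `simulate`, `gen-samples`, `train`, `call`, `apa`, `match`,
`profile`, `downsample` and `evaluate` subcommands is installed under
`inst/cli/loopcallr`.

Real data enter through the same readers used above: cool-dialect HDF5 or
sparse-triplet text for contact maps (`read_contact_map()`, optionally
balanced), bigWig or bedGraph for accessibility (`read_accessibility()`),
and BEDPE for training interactions (`read_interactions()`).

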