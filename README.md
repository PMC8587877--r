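# putsc — positive-unlabeled time-series labeling by self-training

`putsc` labels a large pool of unlabeled time series starting from a
handful of known positives — the *positive-unlabeled time-series
classification* (PUTSC) setting that arises when signals (ECG heartbeats,
sensor traces, spectra) are cheap to record but expensive to annotate.

It implements two self-training schemes plus the machinery around them:

* **`st-scc`** — classic 1NN self-training: repeatedly move the pool
  series with the smallest DTW distance to *any* labeled series into the
  labeled set, until the pool is empty.
* **`scc-center-dtw` / `scc-center-ed`** — barycenter-guided
  self-training: at each iteration recompute the *average sequence* of the
  labeled set (DTW barycenter averaging, or a pointwise Euclidean mean)
  and move the pool series closest to that average.  The average is more
  representative than any single member, so a seed positive sitting near
  the class boundary cannot drag the labeling into the wrong class — the
  failure mode that plagues the 1NN rule.

All similarity is unconstrained DTW with squared local cost
`d(x, y) = (x − y)²` and **no** final square root; the distance between
`A` and `B` is `D(m, n)` of the usual accumulated-cost recurrence

```
D(i, j) = (a_i − b_j)² + min{ D(i−1, j), D(i, j−1), D(i−1, j−1) }.
```

DBA refines a randomly initialized barycenter by pooling, per barycenter
position, the elements its optimal warping paths align with, and replacing
each position by the pooled mean (15 refinements by default).  After the
pool is exhausted, the **stopping-criterion confidence**

```
SCC(i) = |info(i) − info(i−1)| / Std(info(1..i)) × (|U| − (i−1)) / |U|
```

locates the positive/negative cut at `argmax SCC − 1`, where `info(i)` is
the minimum DTW distance from the series selected at iteration `i` to the
labeled set at that moment.  Evaluation reports F1 over the pool (seeds
excluded), with tie-averaged ranks for method comparison.

## Worked example

Generate the boundary-seeded two-class scenario (noisy Gaussian bumps
whose amplitudes encode the classes, with one seed positive deliberately
placed near the class boundary), then label its pool both ways:

```r
library(putsc)

ds  <- generate_boundary_scenario(seed = 42)   # 8 positives, 12 negatives
sp  <- boundary_pu_split(ds, seed = 43)        # PL = boundary seed + 2 interior
sp
#> <pu_dataset> |PL| = 3, |U| = 17 (5 hidden positives)

fit <- pu_label(sp, method = "scc-center-dtw", seed = 44)
fit
#> <pu_labeling> method = scc-center-dtw; stop = 2; |positive| = 5, |negative| = 15

score_labeling(fit, sp)[c("precision", "recall", "f1")]
#> $precision  [1] 1
#> $recall     [1] 0.4
#> $f1         [1] 0.5714286

score_labeling(pu_label(sp, method = "st-scc", seed = 44), sp)$f1
#> [1] 0
```

The barycenter-guided scheme selects the five hidden positives first (its
trace `fit$trace$order` begins `1 2 3 4 5` before any negative) and keeps
precision 1 even though SCC cuts conservatively at 2; the 1NN scheme is
pulled across the boundary by the mis-placed seed on its very first
selection and scores 0.  Averaged over 20 replicates
(`compare_boundary_methods(n_seeds = 20, seed = 7)`), mean F1 is 0.488 for
`scc-center-dtw` against 0.059 for `st-scc`.

A command-line interface wraps the same pipeline:

```sh
putsc simulate  --generator boundary --seed 1 --out demo.tsv
putsc label     --input demo.tsv --method scc-center-dtw --seed 1 --out demo
putsc benchmark --input demo.tsv --methods st-scc,scc-center-dtw \
                --n-pl-draws 5 --n-dba-reps 3 --seed 1 --out demo.csv
```

`label` writes the full `(iteration, selected-id, info, SCC)` trace and
the positive/negative assignment as CSV and logs the stop index; every
run logs its seed and canonical configuration so it can be reproduced
from the log alone.

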