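---
title: "Centroid query expansion for content-based medical image retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid query expansion for content-based medical image retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbirqe)
```

## The retrieval model

A feature database holds one record per image: a unique id, a class label,
and a fixed-dimension real feature vector (4096 activations of a CNN fully
connected layer for the deep descriptors this method was designed around, or
any other dense descriptor). Similarity is raw Euclidean distance — no
normalisation, centering or scaling is applied to the features, because the
method is defined on the extractor's raw output and a monotone rescaling
would silently change which neighbours tie.

Direct retrieval ranks the database by distance to the query vector. The
expanded search interposes automatic pseudo-relevance feedback:

1. **Rapid search** — one global ranking, filtered per class to the `k`
   nearest images of each class. This is mathematically identical to ranking
   each class separately (within-class relative order is preserved under
   filtering) but costs a single scan.
2. **Expansion** — each class's top-`k` members are averaged component-wise
   into a class centroid. The centroid is a denoised stand-in for "what the
   query would look like if it belonged to this class": averaging cancels
   per-image idiosyncrasies while keeping the class-typical activations.
3. **Selection** — the centroid closest to the original query wins. The
   assumption doing the work here is that the query's true class produces
   the nearest centroid; this holds whenever classes form compact clusters
   relative to their separation, and degrades gracefully (selection falls
   back to the nearest confusable class) when they do not.
4. **Final search** — the full database is ranked against the selected
   centroid and the top `N` images are returned. The final search is not
   restricted to the selected class by default, so a wrong selection can
   still surface correct-class images; `restrict_to_class = TRUE` exposes
   the restricted variant.

The whole pipeline is deterministic: given a database (whose row order is
fixed and meaningful) and a query, every stage breaks exact distance ties by
database record order, so two runs — or two machines — produce identical
rankings.

## Parameters

* `k` (rapid-search depth, default **10**): how many images per class feed
  each centroid. Classes with fewer than `k` images contribute all of their
  members — the centroid is defined for any member count, and a small
  worked example averaging five members behaves identically to the
  ten-member default. Small `k` makes centroids noisier; `k` much larger
  than the class-typical neighbourhood dilutes them with far-away members.
* `n` (result-list length, default **10**): the evaluation cutoff. Reports
  compute cutoffs `1..10` in one pass.
* `include_query` (default **TRUE**): whether a database image serving as
  its own query stays in the index. The whole-database evaluation protocol
  keeps it, which pins precision at cutoff 1 to 100 and makes the rapid
  search's own-class list start with the query itself. With `FALSE` the
  query's record is excluded from both stages. ARR denominators always use
  the full class size.
* `separation`, `sigma`, `seed` (synthetic generator): class-centre
  distance, within-class spread, and the reproducibility seed. The ratio
  `separation/sigma` is the single knob that moves the benchmark from
  chance-level (0) to perfectly retrievable (≥ 50).

## What the synthetic generator emulates — and what it does not

`simulate_feature_db()` draws each class from an isotropic Gaussian around
centres placed on scaled orthogonal axes, so every pair of centres is
exactly `separation` apart (this placement needs `dim >= n_classes`; random
centres with rejection would work for larger class counts but give only
approximate pairwise distances). Each class draws from its own RNG
substream (`seed + 7919 * class_index`), so adding a class never perturbs
earlier classes. Class sizes default in tests to uneven blocks like
`{75, 50, 58, 41}`, the shape of a small CT collection.

This emulates exactly the property the method exploits — compact,
equidistant class clusters in a dense feature space — and nothing else.
Real CNN features of CT/MRI slices have anisotropic, heavy-tailed,
correlated coordinates; class clusters overlap unevenly; and class
"centres" drift with acquisition protocol. Passing the synthetic benchmarks
therefore shows the pipeline is implemented correctly (oracle-equivalent
ranking, exact centroids, correct selection, correct bookkeeping), not that
the method attains any particular accuracy on real scanners. Published
accuracies on real CT/MRI databases require downloading those databases and
pretrained CNN weights, which this package deliberately does not do.

`simulate_image_tree()` plays the same role one level earlier: each class is
a texture family (distinct mean intensity plus a distinct oriented grating
frequency) with pixel noise, separable by the histogram descriptor, so
extraction → store → retrieval can be exercised end to end from actual
image files.

## Numerical choices

* All accumulation (distances, centroids, metric averages) is in double
  precision regardless of stored feature precision; the six-component
  worked example's centroid is exact at printed rounding because of this.
* Ties: stable everywhere. Ranking uses a stable order with the database
  row index as the tie key; centroid selection takes the first minimum in
  class order. Ties have probability zero for continuous features but occur
  in quantised descriptors, and untied behaviour must not depend on sort
  internals.
* Internal ranking could use squared distances; reported distances are true
  Euclidean values, so the straightforward `sqrt` form is used throughout —
  at the problem sizes this package targets the saving is irrelevant.
* `F`-score at `ARP = ARR = 0` is undefined (0/0); it is reported as 0 with
  a warning rather than `NaN`, so degenerate evaluations stay machine
  readable.
* Metrics are computed unrounded; reports print two decimals.
* The histogram descriptor clamps intensities to `[0, 1]` and bins gradient
  magnitudes over the fixed range `[0, sqrt(2)]` (the maximum for
  unit-range images), so bin edges never depend on image content and the
  descriptor is bit-stable.

## Design choices that were genuinely open

* **Deep extractor backends.** The 4096-feature CNN extractors are exposed
  as named specs that raise an instructive error unless the user registers
  an inference function via `register_extractor()` or loads features
  computed elsewhere. A silent fallback to the toy descriptor was rejected:
  a retrieval result should never be mistaken for a deep-feature result.
  Preprocessing for a registered deep backend (resize to the backbone's
  native input, grayscale replication to three channels, the backbone's
  channel normalisation, and for CT data rescale-slope/intercept followed by
  per-slice min–max scaling) is documented guidance for the plug-in author;
  the package does not claim bit-level equivalence with any particular
  published feature set.
* **Image formats.** PNG and TIFF are read natively. JPEG and DICOM have no
  reader among this package's dependencies and error with a clear message;
  the recommended route for DICOM collections is converting slices to
  16-bit PNG/TIFF, or computing features in whatever toolchain reads them
  and loading the store with `read_feature_db()`.
* **Store format.** A greppable UTF-8 TSV manifest plus an Apache Arrow
  IPC (Feather) file for the matrix, rather than one opaque blob: records
  stay diffable, and the matrix round-trips doubles bit-exactly.
* **CLI.** `cbir_cli()` is an exported function returning an exit code,
  with a thin Rscript under `inst/exec/`; tests drive the function
  in-process, so the command surface is covered without spawning shells.

## Problem sizes

The test suite and the acceptance script run on databases of 45–240 records
with 6–64 feature dimensions, oracle comparisons on 200 records, recovery
checks over five seeds, and property loops of up to 1000 random triples —
sizes at which every check is exact or statistically stable while the whole
suite completes in well under a minute. These are the package's chosen desk
scale; nothing in the implementation depends on them.

## Known limitations

* No approximate nearest-neighbour indexing: every search is a full scan,
  fine up to tens of thousands of records, not for millions.
* One round of expansion only; no iterated expansion or learned expansion.
* Alternative metrics (Manhattan, chi-square) are not implemented; the
  pipeline is defined on Euclidean distance.
* The soft superiority of the expanded search over direct search is checked
  only as a logged non-inferiority property on synthetic clusters; claims
  about real medical databases are outside what this package can verify
  self-contained.
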