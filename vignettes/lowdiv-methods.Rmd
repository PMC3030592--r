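---
title: "Methods: cluster resolvability and deferred cluster calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster resolvability and deferred cluster calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowdiv)
```

## The problem

Genome Analyzer class instruments locate clusters on the flow cell from
the images of the first few sequencing cycles (four in SCS v2.5/2.6,
five in v2.8) and reuse those coordinates for every later cycle. When a
library is *low-diversity* in its initial bases — an in-line barcode, or
the restriction-site remnant common to every fragment of an e4C or
reduced-representation bisulphite library — nearby clusters look
identical during exactly the cycles used to tell them apart. Pairs that
would be separable by their sequence divergence later in the read are
merged or discarded by the purity filter, and the lane yields a fraction
of its potential data.

This package provides (i) a simulation and a closed-form model of that
loss as a function of cluster density and initial-sequence diversity,
and (ii) the rescue workflow — *deferred cluster calling* — that renames
the image stack so cluster identification runs on diverse post-barcode
cycles, together with the read-level bookkeeping (barcode rotation,
demultiplexing, quality summaries, window-level coverage comparison)
needed to use and evaluate the rescued data.

## The resolvability model

A tile is a rectangle of `width_px` by `height_px` imaged pixels
(defaults 1888 and 2048, one GAIIx tile). `n` cluster centres are placed
independently and uniformly at random, and each receives an
initial-sequence tag drawn from a *diversity profile*: tags
$t_1 \dots t_k$ with proportions $p_1 \dots p_k$. The probability that
two random clusters share their cluster-calling bases is the *match
probability* $\sum_i p_i^2$ — the single statistic through which
diversity enters the model.

Resolvability is a two-radius geometric proxy for the instrument's
image analysis and purity filtering:

* any pair of centres at Euclidean distance $\le r_\mathrm{hard}$
  (default 1 pixel) is non-resolvable regardless of sequence;
* a pair at distance $\le r_\mathrm{soft}$ (default 2.5 pixels) is
  non-resolvable only if the two clusters carry the same tag.

Both members of a colliding pair are rejected: the merged spot either
fails the purity filter outright or produces a mixed signal once the
sequences diverge, so counting it as one usable cluster would be
optimistic. Distance ties are collisions (closed balls), which is
deterministic and conservative. Chains (A near B near C) are handled by
applying the pairwise rule independently per cluster; no transitive
merging is attempted.

An *unbiased* library is represented by a sentinel profile with match
probability 0: every cluster gets a distinct pseudo-tag and only hard
collisions occur. This models effectively unlimited diversity; for the
finite-alphabet alternative (all $4^L$ tag sequences equally likely,
match probability $4^{-L}$) use `enumerate_unbiased()`. With $L = 4$ the
two differ by at most a $1/256$ same-tag thinning and are
indistinguishable at realistic densities.

### Closed form

Under a homogeneous Poisson process of intensity
$\lambda = \mathrm{density}/(W \cdot H)$ per px², with tags assigned by
independent thinning, the survival probability of a tag-$i$ cluster is
exact:

$$ s_i = e^{-\lambda \pi r_\mathrm{hard}^2}\;
   e^{-\lambda p_i \pi (r_\mathrm{soft}^2 - r_\mathrm{hard}^2)} $$

(no point of any tag in the hard disc, no same-tag point in the soft
annulus; both are Poisson void probabilities). The usable fraction is
$\sum_i p_i s_i$. The simulation places a fixed count $n$ rather than a
Poisson count, a difference of order $a/A \approx 10^{-5}$ in the
survival probability, far below Monte-Carlo noise at the repetition
counts used.

Edge effects are ignored in the closed form. The simulation therefore
offers two boundary modes: `rectangle` (a physical tile; clusters near
an edge have fewer neighbours, so the simulated fraction sits slightly
above the analytic curve at high density) and `periodic` (torus
distances; matches the closed form without any edge correction, and is
what the calibration tests use).

```{r analytic}
predict_sweep(c(125000, 300000), lapply(c(1, 4), equal_profile))[,
  c("density_per_tile", "k", "match_probability", "mean_usable_fraction")]
```

### Simulation parameters

* **Density grid**: 125,000–300,000 clusters per tile (step 25,000 by
  default) — the plausible operating band of a GAIIx flow cell.
  Densities are clusters per tile, converted internally to intensity
  per px².
* **Repetitions**: 10 by default. At these densities a tile holds
  $\ge 10^5$ clusters, so the per-repetition standard error of the
  usable fraction is already $\sim 10^{-3}$; 10 repetitions estimate the
  Monte-Carlo error well enough for 3-standard-error comparisons.
* **Seeding**: every placement takes an explicit seed; `simulate_tile()`
  derives per-repetition seeds as
  $\mathrm{seed} + 7919\,r \bmod (2^{31}-1)$, so extending `reps` never
  changes earlier repetitions, and the caller's RNG stream is never
  touched.
* **Lane extrapolation**: expected usable clusters per lane is the
  per-tile count times `tiles_per_lane` (default 120, configurable) —
  an expectation, not a re-simulation.

`classify_resolvable()` bins clusters into a grid of cell size
$\ge r_\mathrm{soft}$ (C++), scanning the 3×3 neighbourhood; this is
exactly equivalent to the all-pairs evaluation, and the test suite
asserts identity against an independently written brute-force oracle on
a hundred seeded fields in both boundary modes.

## Deferred cluster calling ("bareback" processing)

For an $N$-cycle run with $b$ biased leading cycles, the remap sends
original cycles $1..b$ to $N\!-\!b\!+\!1..N$ and re-designates cycles
$b\!+\!1..N$ as $1..N\!-\!b$; with $N = 40$, $b = 4$, original cycle 1
becomes cycle 37. The mapping is a bijection with an exact inverse, so a
remapped run directory can always be restored.

```{r remap}
build_remap(40, 4)
```

On disk the remap is executed as a two-phase rename plan over the image
manifest (`C<cycle>.1/s_<lane>_<tile>_<channel>.tif` by default; the
template is configurable since run-folder layouts varied between
pipeline versions): phase 1 moves every file to a unique temporary name,
phase 2 to its final name, so no intermediate state has two files
contending for a path, each move is a single atomic rename, and an
interrupted phase 1 is detectable (leftover `*.remap-tmp` names) and
resumable. Dry run is the default; execution requires an explicit flag
because the operation rewrites a run directory. Only image files are
touched — no pixel data are read, and no base calling is performed.

The default $b = 4$ matches the four cluster-calling cycles of SCS
v2.5/2.6; $b = 5$ covers the v2.8 convention. $b$ is recorded in output
metadata because a rotated FASTQ is meaningless without it.

At the read level, the same transformation appears as a rotation: the
barcode, sequenced last after deferral, trails the read. `rotate_read()`
/ `rotate_fastq()` move the first $b$ bases (and qualities, in lockstep)
to the end, and `unrotate_read()` inverts exactly. Rotation rather than
trimming is deliberate: the barcode is preserved and remains usable for
demultiplexing.

## Demultiplexing and yield arithmetic

`demultiplex()` assigns a read to the unique tag within `max_mismatch`
Hamming distance of its barcode window (leading bases, or trailing bases
after rotation). The default is exact matching; mismatch tolerance is
opt-in and validated against the tag set — the tolerance must be below
the minimum pairwise Hamming distance, otherwise assignment could be
ambiguous. The standard four-tag set CATT/GTAT/ACGT/TGCT has minimum
distance 3, so one mismatch is always safe. Ties and non-matches are
unassigned; the partition is complete by construction.

Yield arithmetic follows printed-table conventions: group means and
percent-of-baseline are half-up rounded to integers, pairwise percent
increases and barcode percentages to one decimal. Base R's banker's
rounding is deliberately not used. Significance testing is a fixed-
effects one-way ANOVA (via `stats::aov`) followed by pooled-variance
pairwise $t$ tests with Bonferroni correction
(`stats::pairwise.t.test`), under the usual normality and
equal-variance assumptions; the test suite checks the $F$ statistic
against a hand-written sums-of-squares oracle and the two-group identity
$F = t^2$.

```{r yields}
yield_report(example_yield_table("ibs_groups"), baseline_group = "0 IBS")
```

## Quality summaries

Per-cycle mean/median/quartiles and the per-read mean-quality histogram
are computed in Phred space from a declared encoding offset (33 or 64;
the Genome Analyzer era used 64). Auto-detection is deliberately
omitted — many quality strings are valid under both conventions — so the
offset is explicit, and converting between encodings leaves every
Phred-domain statistic unchanged. Median and quartiles use the
lower-interpolation convention (an order statistic), keeping them
integers in Phred space; plotting tools interpolate differently, so
quartile values here are documented rather than matched to any
particular tool. Reads with Phred 2 at every position (quality character
'B' under offset 64) carry the instrument's read-segment QC indicator
and are counted separately.

## Window counting and comparison

Reads are counted into 100-bp windows (default) by their 5′ start
coordinate — for minus-strand input intervals the 5′ end is the interval
end. Windows tile each chromosome without overlap by default; a `step`
below the width gives true sliding windows (each read then lands in
`w/step` windows). The default is the tiling grid because it is
reproducible and the sliding variant is a superset of it.

Outlier windows — typically mapping artefacts — are removed by a
nearest-rank percentile filter: the threshold is the
$\lceil p/100 \cdot n \rceil$-th order statistic of all window counts
(zero-count windows included in the distribution), and windows strictly
above it are masked. Two tracks over the same grid are compared on the
intersection of their unmasked windows with Pearson correlation of
$\log_{10}(\mathrm{count}+1)$ and Spearman rank correlation; both are
reported since the choice between raw and log scatter is a matter of
presentation.

## Synthetic fixtures

The generator emulates the study conditions end to end: 40-cycle reads
with 4-base in-line barcodes CATT/GTAT/ACGT/TGCT in equal proportions
(a single `CATG` tag emulates an NlaIII restriction-digest library);
Phred qualities from a linear decay model (start mean 34, 0.25 per
cycle, Gaussian noise s.d. 3) clamped to [2, 41]; optional barcode
corruption (two substitutions, ground truth recorded) and injected
all-Phred-2 reads; placeholder image trees whose file contents
fingerprint their origin; and mapped-read positions from a flat
background plus configurable fold-enrichment peaks. All outputs are
byte-reproducible from the seed.

What it does **not** emulate: cluster brightness, point-spread functions,
phasing/pre-phasing, sequencing errors in template bases, chastity-score
distributions, or real image content. Passing tests therefore
demonstrate the correctness of the bookkeeping and the internal
consistency of the geometric model — not that the two-radius proxy
reproduces any particular instrument's purity-filter yields, which
depend on optics and software versions.

## Problem sizes and numerical choices

The test suite simulates tiles at up to 300,000 clusters (the upper end
of the operating band) with 10 repetitions per grid point, checks
exact-oracle equivalence on fields up to 2,000 clusters, and round-trips
10,000-read FASTQ files and 320-file image trees; the whole suite runs
in well under two minutes on one core. Degenerate inputs are defined
explicitly: an empty tile has usable fraction 1, an empty FASTQ rotates
to an empty FASTQ, a zero-yield baseline group and an all-constant ANOVA
table are errors rather than NaNs.

## Limitations

* The two-radius resolvability rule is a stated proxy, not Illumina's
  (undocumented) purity-filter formula; absolute usable fractions should
  be read as model predictions, relative behaviour (density and
  diversity trends) as the robust output.
* The rectangle-mode simulation exceeds the closed form slightly at high
  density (edge effects); calibration comparisons use periodic mode.
* Index-read (separate-read) demultiplexing, adapter trimming and
  alignment are out of scope; mapped positions are consumed, not
  produced.
* The manifest covers image files only; sidecar metadata files, where a
  pipeline version produced them, are not renamed.
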