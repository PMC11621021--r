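---
title: "Methods: artifact QC for highly multiplexed tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: artifact QC for highly multiplexed tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplexqc)
```

## The problem

Cyclic multiplexed imaging (CyCIF, CODEX, mIHC and relatives) measures
20–100 protein channels over repeated stain–image–bleach rounds and, after
segmentation, yields a *spatial feature table*: one row per cell with its
centroid, nuclear area and per-channel mean intensities. Every such image
also contains artifacts — tissue folds, antibody aggregates, autofluorescent
fibers, illumination aberrations, cross-cycle tissue loss and segmentation
errors. Cells under these artifacts carry intensities that reflect the
artifact, not biology; they seed spurious clusters, merge genuine
populations, and bias frequency comparisons. `mplexqc` removes such cells
before phenotyping, audits the removal, and keeps a replayable record of
every decision.

The pipeline runs the stages in a fixed order, each touching only cells
still retained when it runs:

1. polygonal ROIs (negative or positive mode, file-driven),
2. automated artifact masks (morphology + flood fill),
3. a nuclear-intensity gate (Gaussian mixture),
4. a segmentation-area gate (Gaussian mixture),
5. a cross-cycle DNA-ratio gate for lost cells,
6. log10 transform of protein channels,
7. per-channel percentile outlier pruning,
8. a clustering-based audit (metaQC) that can reinstate or further drop
   cells.

Every drop or reinstatement is appended to a redaction log with the
parameters in force; replaying the log over the raw table reproduces the
final status column exactly, which the output writer asserts before writing.

## The automated artifact detector

The detector works per channel on a downsampled 8-bit rendering.

**Rendering.** The channel is block-mean downsampled (default factor 4) and
mapped to `[0, 255]`. The default map is min–max of *log10* intensity.
Fluorescence dynamic range is multiplicative: in one channel the tissue
autofluorescence floor may sit at 10² AFU, biological signal at 10³, and a
precipitated antibody aggregate at 10⁴. A linear 8-bit map devotes almost
all grey levels to the bright end, so a doubled floor — the signature of a
tissue fold — collapses into one or two levels and any tolerance-based fill
leaks. The log map gives the floor, the signal and the near-saturated
artifacts distinguishable grey bands. Linear min–max and robust percentile
maps remain available via `artifact_config(rescale=)`.

**Transform.** Erosion, local mean smoothing, then dilation, all with a
disk kernel. Erosion removes structures smaller than the kernel, smoothing
levels residual texture, and dilation restores the spatial extent of
surviving artifact-scale features. Because compact near-saturating
artifacts (aggregates, diameter ~15–30 px full resolution) and extended
faint ones (folds, hundreds of px, visible only as a doubled floor) live at
different scales, the default runs two kernels — diameters 3 and 7
downsampled px — and unions the masks. The large kernel must span a few
cell diameters so that confluent nuclear texture erodes away; the small one
must be smaller than an aggregate so its core survives.

**Seeds.** Local maxima within an expanded kernel (`seed_kernel_scale = 2`)
gated against background: a seed must exceed `median + 5·MAD` of the
transformed image (MAD floored at one grey level). In a multi-scale run the
8-bit value 100 splits responsibility: small kernels accept only seeds at
or above it (under the log map, roughly the geometric midpoint of the
channel's range — residual biological plateaus stay below it after
erosion), the largest kernel only seeds below it (anything still bright
after a cell-scale erosion is compact and belongs to the small-kernel
pass). Larger kernels also may not re-seed inside regions a smaller kernel
already claimed, since a bright compact artifact leaves a faint halo at
coarser scales that would otherwise be flooded at fold scale.

**Flood fill.** From each seed, the 8-connected region of pixels within the
tolerance of the seed value, bounded below by `median + 5·MAD` (a fill may
not descend into background texture — the automated stand-in for a human
adjusting the tolerance per region). The default tolerance is *relative*,
0.4 of the seed value, so a 250-level aggregate plateau and a 60-level fold
floor are filled on comparable footing; an absolute 8-bit tolerance mode is
available. Components smaller than `min_region_area` (10 px) are discarded.
Masks are upscaled by block replication and cells whose centroid falls
inside are dropped (`any_pixel` membership is available when the
segmentation mask is supplied).

These defaults were developed on phantom specimens (see below) and then
validated on held-out phantom seeds; on the held-out set the fold mask
reaches pixel IoU 0.76–0.88 against ground truth and the aggregate mask
0.65–0.87, with cell-level false drops below 1.5%. The residual false
positives are clumps of genuinely bright cells — acceptable for a tool
whose masks are intended for human review.

## Intensity and area gates

`fit_gmm_thresholds()` fits a univariate Gaussian mixture (default K = 3,
accommodating dim-debris / valid / oversaturated trimodality) and takes the
largest-weight component as the valid population; the gate is that
component's (0.5%, 99.5%) normal quantiles. Unequal variances are tried
first; heavily tied data (small-integer pixel areas) can degenerate the
unequal-variance EM, in which case an equal-variance fit is used and
recorded. Thresholds may always be overridden manually, and the full
mixture parameters go to the QC log. The nuclear gate uses first-cycle DNA
only.

A note on what the (0.5%, 99.5%) quantile gate is and is not: when the dim
and valid components overlap moderately (log10 sd ≳ 0.13 at a 0.7
separation, i.e. a CV of 30–50% on the linear scale, typical for mean
nuclear stain in tissue), the lower quantile of the valid component lands
within ±0.1 log10 of the posterior decision boundary between components.
For nearly disjoint components the two notions legitimately diverge — but
there any threshold between the modes gates identically.

## Cross-cycle stability

For each cell, r = log10(DNA₁/DNAₙ) from the first and last imaging cycles.
Stable cells sit near 0; cells lost to tissue movement or detachment form a
discrete peak at positive r (a loss to 5% of the original intensity puts
the peak at 1.3). Cells with non-positive last-cycle DNA get r = +∞ and
always fail. Default bounds are the (0.5%, 99.5%) quantiles of the
largest-weight component of a two-component mixture on the finite ratios.

## Log transform and pruning

Protein channels are replaced by log10(v + ε) with ε the smallest positive
value of the channel, keeping zero-background cells finite; DNA channels
stay linear (the ratio gate consumes them raw). Percentile pruning then
drops cells outside per-channel (p_lo, p_hi) cutoffs — default
(0.1, 99.9) — channel by channel in panel order, quantiles by linear
interpolation between order statistics, per sample on request.

## metaQC

Redaction, human or automated, makes mistakes in both directions. The audit
samples equal numbers of redacted and retained cells (uniformly, seeded,
capped at 10⁵ per class), embeds and clusters the pool exactly as the
phenotyping module does, and computes per cluster the fraction f of
retained members. If f ≥ 0.75 the cluster vouches for its redacted members
(reinstated); if f ≤ 0.25 it indicts its retained members (dropped);
between the two — the dead zone — nothing happens, and unclustered cells
are never touched. The audit runs once by default; iteration to a fixed
point is a flag.

The dead zone is load-bearing: artifact classes that *preserve* marker
ratios (a uniform fold gain; dim truncated nuclei whose marker vector is
untouched) co-cluster with clean cells of their own type and pull f toward
parity, and the audit deliberately takes no action there rather than guess.
The recovery scenario used in validation therefore redacts the
profile-corrupting classes (aggregates, fibers, cell loss) as backdrop,
flips 5% of clean cells at random, and requires ≥80% of the flips
reinstated with ≤2% of clean retained cells newly dropped; measured
recovery is 85–100% with no false new drops.

## Phenotyping and review

**Components.** Horn's parallel analysis compares the eigenvalues of the
observed correlation matrix with the 95th percentile of eigenvalues from
column-permuted copies; the count of exceedances, clamped to 2–3, selects
the principal components worth keeping ahead of embedding.

**Embedding and clustering.** UMAP (or t-SNE) on the log channels, then
HDBSCAN on the 2-D embedding, matching the way clusters are drawn and
reviewed on the embedding; clustering on raw channels is an option.
HDBSCAN is implemented from its standard construction — core distances
from k nearest neighbours, mutual-reachability distances, the
single-linkage dendrogram (equivalent to the minimum spanning tree), a
condensed tree in which splits below `min_cluster_size` fall out as noise,
and excess-of-mass cluster selection by stability, with the root never
selectable so structureless data yields no clusters. Labels are contiguous
from 0 in decreasing size order; −1 marks unclustered cells. Distances are
computed densely, suiting the embedding sizes this package clusters (up to
a few thousand cells per run); all seeds are explicit and embeddings are
computed single-threaded so repeated runs are bit-identical.

**Review surfaces.** Silhouette scores (computed in embedding space by
default) flag misassigned cells; cluster mean-intensity profiles are
min–max normalised row-wise across clusters in [0, 1] (a constant row maps
to zeros) with a population-sd z-score variant; average-linkage Euclidean
agglomeration of the cluster mean vectors yields meta-clusters cut at a
chosen k or height. Per-condition cluster frequencies are compared with a
two-sided Welch t-test on logit(f + ε) (ε = 10⁻⁶, clamped so the logit
stays finite when a cluster is absent from a sample), Benjamini–Hochberg
adjusted across clusters — a pragmatic choice for few samples, guarded in
the test suite by a permutation oracle. Thumbnail galleries draw seeded
random cells per cluster and cut 20 × 20 µm windows centred on the
reference nucleus — 2·round(10/pixel size) px per side, i.e. 30 px at
0.65 µm/px — zero-padded at borders, compositing the cluster's three most
expressed markers (largest entries of its normalised profile column) as
green/red/blue under contrast limits taken once from a reference image and
applied batch-wide.

## The phantom

The generator emulates the four per-specimen inputs with known ground
truth. Nuclei are placed by seeded Poisson-disk sampling (default 0.006
cells/px², 8 px minimum spacing, radius ~N(4, 0.35) px at 0.65 µm/px); six
cell types over a six-marker panel get log-normal intensities around
type-specific log10 means (sd 0.12), producing the right-skewed histograms
of real channels; per-cycle nuclear stains carry a small cycle-to-cycle
jitter (sd 0.02 log10). Tissue autofluoresces: the in-tissue floor is
100 AFU (sd 10), about 10% of nuclear signal — this floor, doubled by a
fold along with everything else, is precisely what makes folds visible in
every channel. Bare glass (10 AFU) appears only where tissue has detached.

Artifacts are composited per plan: folds multiply all channels by 2 inside
a blobby polygon; aggregates are 10–16 px disks at 10^4.2 AFU in one
channel; fibers are random-walk polylines bright in a few channels;
aberrations add a smooth Gaussian gradient (peak 2000 AFU, σ 120 px) in one
channel; cell loss scales post-loss-cycle DNA to 5% and returns post-loss
marker channels to glass; over/undersegmentation split nuclei in two or
merge adjacent pairs (with a bridging blob, giving merged instances ~2.2×
modal area) in the mask only. The feature table is computed from the final
rendered image and final mask, so table and image are mutually consistent
by construction, and the whole phantom is a pure function of its seed.

What the phantom does **not** model: real tissue texture and morphology,
optics (PSF, depth of field), spectral spillover between channels, lateral
spillover from imperfect segmentation, batch effects, or the long tail of
rare artifact morphologies. Passing tests therefore demonstrate that each
stage does what it claims under controlled, known-truth conditions — not
that any particular real dataset will be cleaned perfectly; on real data
the thresholds are starting points for review, which is how the workflow is
meant to be used.

## Validation scenarios and scoring conventions

The acceptance script and the test suite score the stages against phantom
ground truth under fixed conventions:

- Detector IoU is computed per class against the union of per-channel
  masks over the channels in which the class can physically occur — folds
  against all channels (they are bright everywhere), aggregates against
  antibody channels only — and averaged over three phantom replicates.
- Cell-loss gating: recall is measured on cells whose centroid lies in the
  loss region; false drops are measured on cells whose segmentation
  instance does not touch the region at all. Boundary straddlers are
  half-detached — their measured ratio is genuinely elevated — and
  dropping them is correct behaviour.
- The end-to-end scenario mirrors the full workflow: an operator-emulated
  negative ROI over the visible illumination aberration (the artifact
  class the workflow assigns to human lasso selection; the phantom's map
  stands in for the operator's eye), then the automated stages at
  defaults, then clustering of the retained cells. The adjusted Rand index
  against true types is compared before and after QC; the aberration halo
  left in place otherwise splits whichever phenotype its channel defines.
- Problem sizes: 600 × 600 px phantoms (~2,200 cells), metaQC pools of
  ~1–2 × 10³ cells, Horn's analysis at n = 500 × 10 channels × 100
  permutations — sizes chosen so the full validation runs on a laptop in
  minutes while every population is large enough for stable mixture and
  density estimates.

## Degenerate inputs and numerical conventions

Constant channels rescale to all-zero 8-bit images (no artifacts
detectable) and are dropped from parallel analysis with a warning; a pool
of identical cells is one degenerate cluster, not noise; zero-variance
gate fits and mixtures with more components than distinct values error
out; quantiles are type-7 (linear interpolation) throughout; images are
indexed (row, col), tables store x = column and y = row, 0-based at full
resolution, with half-open pixel boxes; polygon containment is even-odd
and boundary-inclusive; flood fill and component labelling are
8-connected. Marker names are reconciled by an explicit mapping in the
manifest, never fuzzily.

## Known limitations

The detector's masks err toward review, not autonomy: bright compact
biology (dense clumps of strongly positive cells) can be flagged, and very
faint extended artifacts below the background gate are missed. metaQC
cannot adjudicate ratio-preserving artifacts (see above). The HDBSCAN
implementation is dense (O(n²) memory) and intended for embedded pools and
per-run subsamples, not millions of cells at once — subsample first, as the
pipeline does. Lateral spillover between adjacent cells is out of scope and
shows up downstream as implausible marker combinations in otherwise clean
clusters.
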