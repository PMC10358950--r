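---
title: "Quantifying leaf venation as a network: methods and design notes"
author: "venation package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf venation as a network: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(venation)
```

## The phenotyping problem

Dicot leaf veins form hierarchical reticulate networks: a spanning tree-like
backbone of major veins overlaid with loops (areoles) whose relative
frequency — the *loopiness* — varies across species and environments. This
package treats a leaf's venation as an undirected graph whose nodes are vein
intersections and termini and whose edges are the vein segments linking
them, and summarizes each graph by a 28-dimensional vector of egonet-based
network statistics. Species can then be classified from these features
alone, and a morphospace of venation phenotypes reconstructed by principal
component analysis.

The processing chain is:

1. (optional) frame rectification and area calibration from square
   fiducial markers (`estimateHomography`, `rectifyImage`,
   `estimateAreaScale`);
2. (optional) vein segmentation of a grayscale image through an
   overlap-tile harness with a pluggable per-tile segmenter
   (`segmentImage`);
3. skeletonization of the binary vein mask and conversion to a graph
   (`skeletonize`, `extractGraph`);
4. per-node features and their aggregation into the 28-vector
   (`computeNodeFeatures`, `aggregateFeatures`, `featureVector`);
5. cross-validated random-forest classification and PCA morphospace
   (`classifyCV`, `fitPCA`, `egonetHistogram`).

A seeded synthetic venation generator (`generatePlanarGraph`,
`rasterizeGraph`, `degradeImage`, `toyPattern`) supplies ground-truthed
inputs for every stage, so the whole chain is testable without any image
downloads.

## Skeletonization

The vein mask is thinned to 1-pixel-wide curves by sequential deletion of
*simple* border pixels — pixels whose Yokoi 8-connectivity number equals 1 —
with endpoints (pixels with a single foreground neighbor) preserved.
Deletions run in four directional sub-passes (north, south, east, west
borders). Two properties follow by construction:

* every single deletion preserves the number of 8-connected components and
  the cycle rank $\beta_1$ of the foreground, so the skeleton is
  homotopy-equivalent to the mask;
* each sub-pass collects its candidate border pixels *before* deleting any
  of them (re-checking simplicity at deletion time), which prevents
  deletions from cascading along the scan order and eroding open curves
  end-to-end — a failure mode we observed with the naive one-phase variant.

The thinning is minimal rather than strictly medial: pixels that are
redundant for connectivity (e.g. the corner pixel of a right-angle bend, or
the center of a T whose arms are diagonally connected around it) are
removed. Graph extraction is invariant to this, and `skeletonize` is
idempotent from the second application onward.

## From skeleton to graph

Node pixels are classified by their 8-neighborhood: an *endpoint* has
exactly one vein neighbor; a *branching point* has three or more. For the
branching rule two readings are implemented (`criterion` argument):

* `"count"` (default): three or more foreground neighbors;
* `"runs"`: three or more maximal runs of adjacent foreground neighbors in
  the circular 8-neighborhood (a crossing-number rule).

We default to the count rule because the run rule provably misses
*degenerate trifurcations*: junctions whose two departing arms are mutually
adjacent at the base form only two runs, so no pixel of the junction is
flagged and a genuine vein connection is silently merged away. The count
rule flags such pixels; its occasional extra flags sit next to real
junctions and are absorbed by the next step. Adjacent node pixels (8-connected
components of the union of endpoint and branch pixels) merge into single
nodes with mean-pixel centroids; ids follow raster-scan order, which makes
extraction deterministic.

Edges are traced by decomposing the non-node skeleton pixels into
8-connected segments and walking each one with a fixed neighbor probe order
(N, NE, E, SE, S, SW, W, NW), starting from the raster-smallest segment
end. Every skeleton pixel is consumed by exactly one walk. Where a walked
pixel touches a node component the walk is split, yielding edges with
$\sqrt2$-weighted path lengths. The bookkeeping distinguishes three
degeneracies rather than dropping them: paths that leave and re-enter the
same node are *self-loops*; repeated node pairs fold into edge
*multiplicity*; node-free cycles are *orphan cycles*. With these terms the
identity

$$\beta_1(\text{simple graph}) + (\text{multiplicity excess}) +
  (\text{self-loops}) + (\text{orphan cycles}) = \beta_1(\text{skeleton})$$

holds exactly on every fixture, and is tested against an independent
Euler-characteristic oracle (2×2 quad counts). For dense networks, a 2×
nearest-neighbor magnification followed by re-thinning (`magnify2x`)
separates branch points that would otherwise merge; it preserves component
count and $\beta_1$.

### Artifact cleanup

Pixel-level tracing of rasterized strokes leaves three artifact classes with
no counterpart in the underlying network: thinning spurs (short endpoint
tails at junctions), split junctions (one intersection of degree > 3 thinned
into nearby branch points), and pinch self-loops. `cleanGraph` removes
them to a fixed point: self-loops shorter than 16 px, endpoint edges shorter
than 8 px, and branch–branch pairs closer than 16 px (minimum of traced
length and centroid distance) are pruned, contracted or dropped, and
degree-2 nodes arising along the way are spliced out. The thresholds are
chosen to sit strictly below the smallest genuine structures the synthetic
generator can produce (anchor spacing is at least 8 stroke widths = 24 px at
the default stroke of 3) and below the toy patterns' smallest features; on
such inputs cleanup can only remove artifacts. For real images the
thresholds are exposed and should be kept below the finest vein spacing at
the working resolution, or disabled (`clean = FALSE`).

## The 28-dimensional descriptor

For every node, seven features: degree; local clustering coefficient
$2t/(d(d-1))$; mean neighbor degree; mean neighbor clustering; and three
one-hop egonet quantities — edges induced on the ego together with its
neighbors, edges leaving that set, and the number of distinct outside nodes
adjacent to it. The egonet *includes* the ego: an endpoint's egonet has two
member nodes, and a degree-3 ego in a triangle-free trivalent neighborhood
has six egonet neighbors; these worked values anchor the implementation and
require the ego-inclusive reading. Tree-like venation concentrates
egonet-neighbor counts at two (endpoint egos), loopy venation at six.

Each feature column is aggregated by mean, standard deviation, skewness and
kurtosis, giving $7\times4 = 28$ values in the fixed `featureNames()`
order. Moment conventions (the quantity names alone do not pin them down)
default to population moments ($1/n$) with Fisher *excess* kurtosis
($m_4/m_2^2 - 3$), and a zero-variance column gets skewness = kurtosis = 0;
`sdType` and `kurtosisType` expose the alternatives. With population
moments the descriptor is exactly invariant under disjoint replication of a
graph — the size-invariance that makes leaves of different sizes
comparable — which would fail with $1/(n-1)$ moments.

## Segmentation harness

Large leaf images are processed as 512×512 tiles. Merging uses an
overlap-tile rule that excludes the outer 16 px of interior tile boundaries:
tiles are placed at stride $512 - 2\cdot16 = 480$ on a canvas
reflection-padded by the 16 px margin (and clamped at the far edge), and
each un-padded pixel is owned by exactly one tile's interior region. The
stride and padding scheme are our choices (only the tile size and the 16-px
exclusion are fixed by the protocol); they make the exclusion rule cover the
image exactly once, and the tile-then-merge roundtrip is bit-exact for any
image size.

The segmenter itself is pluggable: any shape-preserving function from a
grayscale tile to per-pixel vein probabilities in [0, 1]. A learned model
trained per `trainingConfig()` (Dice loss, Adam at 0.001, rotation/gamma/
noise augmentation, residual-network-18 encoder) satisfies the same
contract; training is out of scope here, as no deep-learning backend is
required at analysis time. `referenceSegmenter()` is a deterministic
classical stand-in: per-tile min–max normalization, an Otsu threshold, and
the signed distance below threshold mapped to [0, 1], so probability ≥ 0.5
exactly on the dark (vein) set. Per-tile adaptive equalization (CLAHE) is
available but off by default: re-deriving the Otsu threshold after local
equalization can violate the contract that darkening a pixel never lowers
that pixel's vein probability. Training-mask generation
(`makeTrainingMask`) does use CLAHE followed by a fixed or Otsu threshold,
with clip limit 2 and an 8×8 tile grid as exposed defaults.

## Calibration

Rectification uses a single 3×3 homography estimated from ≥ 4 detected
marker-corner correspondences by the normalized direct linear transform;
fiducial decoding is delegated to whatever detector produced the
correspondences. The area scale pools all square markers: with $k$ markers
of 1 cm² each covering $N$ pixels, the scale is $k/N$ cm²/px. Pooling
(rather than averaging per-marker estimates) weights markers by their pixel
area and is invariant to marker position; whether the original protocol
averaged instead is unknown, and at equal marker sizes the two coincide.
Leaf area is foreground pixel count times the scale.

## The synthetic generator and what it does (not) emulate

`generatePlanarGraph` seeds `nAnchors` points uniformly in the image (inset
by twice the stroke width), Delaunay-triangulates them, keeps a minimum
spanning tree, and retains each remaining triangulation edge independently
with probability `loopiness` — 0 gives a tree, 1 the full triangulation,
and the expected number of extra edges is exactly
$p\,(E_{\text{delaunay}} - (V-1))$. Two RNG streams (anchors: `seed`;
retention: `seed + 1`) keep the retention draw replayable regardless of how
many rejection draws placement needed; at fixed anchor seed the retained
edge sets are nested along the loopiness axis.

Three geometric validity rules make every sample *resolvable at its stroke
width*, i.e. guarantee the rasterized image is homotopy-equivalent to the
graph and junctions stay compact (a generator whose stated ground truth
disagrees with its own image would be useless as ground truth):

* anchor spacing > 8 stroke widths — areoles are much wider than the veins
  bounding them (real spacing-to-width ratios are an order of magnitude);
* no anchor within 3 stroke widths of a non-incident Delaunay edge —
  prevents strokes of distinct edges from touching (pinch cycles) and face
  interiors from filling in;
* at least 15° between consecutive Delaunay edges at a vertex — two strokes
  leaving a junction at angle $\theta$ stay fused for $\sim w/\sin\theta$
  pixels, so shallow fans would smear one junction into a chain of distant
  branch points.

Violating anchors are re-drawn from the seeded stream until the
triangulation is valid (with an iteration cap). Rasterization draws each
edge as the union of its Bresenham line and a disc-swept stroke, then fills
enclosed background pockets smaller than `strokeWidth`² px — pure
quantization pepper, since genuine faces have inradius far above the stroke
radius. Under these rules, graph extraction recovers the generator's node
count, edge count and cycle rank exactly in 100/100 seeded samples across
the full loopiness grid (30 anchors, stroke 3, 512×512), which is the
package's strongest correctness check.

`degradeImage` emulates backlit untreated-leaf imaging: dark veins (0.2) on
a lighter textured background (0.8 ± smooth noise), square gap defects
approximating lost vein connectivity, dark speckles, and Gaussian blur, all
deterministic given a seed. The generator does **not** emulate vein width
hierarchies or tapering, leaf outlines, curved veins, or the spatially
correlated contrast failures of real backlit tissue — so passing tests
demonstrate the correctness of the graph/feature machinery, not
segmentation performance on real leaves.

## Classification and morphospace

`classifyCV` runs stratified $k$-fold (default 5) cross-validation of a
random forest (500 trees, $\lfloor\sqrt p\rfloor$ variables per split —
standard defaults, fixed seed for fold assignment and fitting) and pools
out-of-fold predictions into one confusion matrix, from which accuracy,
per-class recall and precision, and a per-cell Jaccard index
$C_{ij}/(r_i + c_j - C_{ij})$ are derived. `fitPCA` centers (and by default
unit-scales — the 28 features have heterogeneous scales) the feature matrix
and uses the singular value decomposition; zero-variance columns are left
unscaled and get zero loadings, and each component's sign is fixed by
making its largest-magnitude loading positive, since the sign of a
principal axis is otherwise arbitrary.

As a desk-scale stand-in for multi-species classification, two synthetic
classes at loopiness 0.05 vs 0.95 (50 leaves each, seeds fixed) pushed
through the full image → graph → features → forest chain reach ≥ 0.95
cross-validated accuracy; `scripts/acceptance.R` recomputes this end to
end.

## Numerical choices and degenerate inputs

* Coordinates are 1-based (row, col); 8-connectivity for foreground,
  4-connectivity for background/hole analysis.
* Empty masks and node-free skeletons warn and return empty objects rather
  than erroring; a mask that is all one cycle yields an empty graph with
  `orphanCycleCount` 1.
* Component selection keeps the most nodes, breaking ties by most edges,
  then lowest minimum node id.
* Parallel edges store the shortest trace in `length_px` and the summed
  length in `length_total_px`, so total skeleton length is conserved to
  within 2% (tested).
* Problem sizes in the test-suite and acceptance script (100 recovery
  samples and 100 end-to-end leaves at 512×512; 200 oracle graphs at
  $n \le 30$) were chosen as the smallest sets that exercise the full
  loopiness grid with stable rates.

## Known limitations

* The cleanup thresholds assume vein spacing well above the skeleton
  artifact scale; very dense real networks at low resolution should use
  `magnify2x` and/or `clean = FALSE` plus manual thresholds.
* The reference segmenter is a contrast-based stand-in; on real untreated
  leaves a trained tile segmenter is expected to be substantially better,
  and none is bundled.
* Lens distortion beyond a single homography is not modeled.
* Features are computed on the simple graph view; multiplicities and
  self-loops are audit fields, not feature inputs.
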