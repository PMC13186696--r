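---
title: "Methods: quantitative glycan atlassing from DNA-PAINT localizations"
author: "glycoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative glycan atlassing from DNA-PAINT localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model behind
each stage, the parameters that matter (with units and defaults), the
numerical choices, what the synthetic generator does and does not emulate,
and the known limitations.

## The measurement model

DNA-PAINT images each target species in sequential rounds: dye-labelled
imager strands bind transiently to docking strands on lectin labels, so a
single binding site produces a cloud of localizations accumulated over a
20,000-frame stack (100 ms/frame). Each localization is the fitted position
of one blink, displaced from the true site by an isotropic Gaussian error
with standard deviation σ (the localization precision). The analysis
operates entirely on these per-channel tables; coordinates are converted
from camera pixels to nanometres at load time (default effective pixel size
130 nm), stored as 64-bit reals with the image convention (origin top-left,
y down), and frames are 0-based.

## Registration

Gold nanoparticles blink in essentially every frame and are orders of
magnitude more persistent than any docking site. Detection exploits exactly
this: the field is hashed on a `link_radius_nm` grid (default 500 nm), grid
regions whose distinct-frame occupancy is compatible with a persistent
emitter become candidates, and within each region the localization nearest
the region centroid is linked per frame (at most one per frame). Tracks
covering less than `min_presence_fraction` (default 0.5) of the stack are
discarded. This detector is designed for bright, sparse, persistent beads;
it is not a general-purpose tracker.

Drift at frame *t* is estimated as the mean over tracks of (position(t) −
track mean), linearly interpolated across frames a track misses with end
values held, and re-centred to zero mean; correction subtracts the trace.
With *m* fiducials of jitter σ~f~ the corrected per-fiducial spread is
σ~f~·√(1−1/m), so even three beads restore a drifted track to its jitter
scale. Channel alignment matches track means greedily by proximity (500-nm
pairing radius) and fits a least-squares transform — translation by default,
since sequential imaging on one objective has negligible rotation; a rigid
(Kabsch) mode is available. Fiducial localizations are removed before any
downstream analysis.

## Region of interest

Manual polygon picks delimit the cell. Boundary points count as inside
(closed-region semantics, so membership tests are exact and deterministic);
the polygon must be simple with positive shoelace area, which also serves
as the µm² normalizer for class densities. Point-in-polygon tests use
`pracma::inpolygon`.

## Localization precision (NeNA)

A blink usually spans adjacent frames, so the distance from each
localization to its nearest neighbour in the next frame is dominated by
same-molecule pairs. If each position errs with precision σ, the
same-molecule distance is Rayleigh with density d/(2σ²)·exp(−d²/4σ²).
Unrelated neighbours contribute a background that rises linearly at small
distances (the small-d limit of the CSR nearest-neighbour law), modelled as
2d/D² on the analysis window D = `max_d_nm` (default 100 nm — far above any
plausible precision, below typical inter-site spacing). The two-component
mixture is fitted to the 1-nm-binned histogram by bounded
Levenberg–Marquardt least squares (`minpack.lm`), with σ constrained to
(0, D/2). An estimate whose fitted background weight exceeds 50% is flagged
unreliable, and the pipeline falls back to a configured σ (default 5 nm).
The fitted σ sets the clustering radius downstream at 2σ.

## Binding-site calling

Clustering groups repeated localizations of one docking strand: clusters
are the connected components of the graph linking localizations at distance
≤ 2σ, with a minimum of two localizations. Connected components are the
minimal assumption-free reading of a radius-plus-minimum-size rule
(equivalent to DBSCAN with `min_samples = 2` where every point is core),
they are order-independent by construction, and they admit an exact
brute-force oracle — which the test suite exercises on random scenes.

The temporal filter rejects unspecific sticking: the stack is partitioned
into consecutive bins of 1% of its length (200 frames for 20,000), anchored
at frame 0, and a cluster is rejected iff one bin holds **more than** 90% of
its events. The rule is applied verbatim, including its literal corner
cases: a 2-event cluster with both events in one bin is rejected. Note the
anchored partition gives the rule a blind spot — a sticking event whose
duration straddles a bin boundary splits its mass and evades rejection; the
synthetic generator therefore plants sticking windows aligned to the bin
grid, the canonical signature the filter is designed for, and the straddling
case is a documented limitation of the published rule rather than of this
implementation. Surviving cluster centres (unweighted coordinate means,
with event-count and first/last-frame bookkeeping) are the lectin binding
sites.

## Nearest-neighbour analysis

For every ordered channel pair (source, target), including self-pairs with
self-exclusion, the first-NN distance of each source site is histogrammed
on [0, 200) nm in 1-nm bins. For peak finding only, counts are smoothed by
a centred moving average (default window 5 bins, truncated at the edges);
the peak is the centre of the global-maximum smoothed bin. Among tied
smoothed maxima the bin with the larger raw count wins, then the smaller
distance: a plateau created by smoothing a sharp mode thus resolves to the
true mode, while genuinely equal separated modes resolve to the smaller
distance. The K×K matrix of peaks (5×5, or 6×6 with DBCO) is the first
feature set; undefined pairs (empty channel, singleton self-pair) are
flagged missing and imputed by the cross-sample feature mean at embedding
time, never invented as distances. The matrix is deliberately kept ordered
(not symmetrized): (i,j) and (j,i) answer different questions when
densities differ.

**Estimator variance.** The Rayleigh NN density of CSR sites is flat at its
mode 1/√(2πλ), so the argmax of a binned histogram wanders with noise
~ (counts·window)^(−1/4). At desk-scale site counts (10³–10⁴ per channel) the
5-bin default under-smooths: validation analyses therefore scale the window
to ~0.35 of the expected mode (21–41 bins) and size synthetic fields for
10⁴–10⁵ sites, which brings the mode estimate within a few percent of the
closed form. The bias a wide window introduces is common to all samples of
a panel and cancels in the embedding. Package defaults are unchanged; the
window is an explicit parameter of every run.

## GlyCo classes

Binding sites of all channels are pooled in the aligned frame and grouped
by single-linkage connected components at a 5-nm cut-off — at or below this
distance two sites are assumed to belong to the same glycan
(sub)structure. Same-channel and cross-channel pairs both count. Each
component of ≥2 sites is one instance of the class named by the multiset of
member channels, canonically sorted and joined with `+` (`AAL+WGA+WGA`);
singletons carry no class and are only counted. Components were chosen over
any splitting rule because the underlying threshold statement provides no
assignment rule, the closure is the unique deterministic completion, and it
is exactly testable against a brute-force oracle; whether large chained
components should instead be split (e.g. complete linkage) is left open.
Class tables carry counts, densities per µm² of ROI and instance centroids
for spatial maps; conservation (Σ count·size + singletons = total sites)
is asserted in tests.

## State embedding

Per-sample features are one of: the K² flattened peak matrix, the union of
class densities (absent class = 0), or the concatenated per-pair NN
histograms each normalized to sum 1. Features are z-scored across samples —
they mix units (nm, µm⁻²), and reporting loadings as correlations
presupposes standardized inputs — then decomposed by SVD (`prcomp`).
Zero-variance columns are dropped; component count is capped at
min(samples−1, features, rank); each component's sign is fixed so its
largest-magnitude loading is positive, making test assertions reproducible.
Separation between conditions is the mean silhouette width of the condition
labels on the first two PC scores; conditions with one sample are excluded
with a warning.

By default all classes enter the GlyCo feature set (a `top_n` display
option exists separately): restricting to the most frequent classes is a
display convention, not a modelling choice.

**Permutation nulls at small n.** With 6 samples per condition, 7.8% of
label permutations are 5/1-concordant splits; empirically their silhouette
is ≈0.45× the true-label silhouette. Any embedding that separates two
6-sample conditions with silhouette >0.5 therefore leaves those
permutations above ≈0.22, capping the fraction of permutations with
|silhouette| < 0.2 at ~92–94%. A permutation calibration demanding 95%
below that threshold is attainable only at larger sample counts; the
package reports the permutation pass fraction as measured.

## The synthetic scene generator

`scene_spec()`/`generate_scene()` emulate the acquisition with full ground
truth. Defaults: 10×10 µm field (full-field rectangular ROI), the
five-lectin panel, 20 sites/µm² per channel, 20,000 frames, Poisson(10)
events per site at uniform frames, σ = 5 nm per channel, no drift, no
fiducials, no sticking. Motif instances plant classes: members of a channel
multiset placed 1–4 nm (uniform) from a common anchor, below the 5-nm
cut-off so planted classes are recoverable by construction; a minimum
anchor separation (off by default, 50 nm in recovery tests) emulates the
well-separated regime. Event times are uniform over the stack — the
temporal filter only distinguishes spread from confined, so Markov on/off
kinetics are unnecessary; `mean_event_frames > 1` (geometric-like
durations) emulates bright times longer than the frame time and produces
the adjacent-frame pairs NeNA needs. Drift is linear or random-walk,
accumulated per frame; fiducials emit every frame with 2-nm jitter and are
placed outside the ROI when the ROI is smaller than the field; sticking
artifacts emit Poisson(30) events inside one 200-frame window aligned to
the anchored bin grid. Identical seeds give bit-identical scenes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: optical image formation (PSF shape, camera
noise, spot-fitting failures), z-dimension effects, label/imager chemistry
(binding-site occupancy, multiple dockings per lectin), spatially varying
density within a cell, and non-rigid chromatic distortions between
channels.

## Validation scales

Synthetic validation runs at desk scale, chosen for estimator power rather
than realism of full cells: oracle-equivalence checks use 100 random scenes
up to 2,000 points; NeNA recovery uses 50,000 pairs; filter characteristics
use 1,000 genuine plus 1,000 sticking clusters; site calling ~1,600 planted
sites; CSR closed-form checks 2×10⁴–8×10⁴ sites; the two-state panel uses 6
samples per condition at ~5,000 sites/channel. The two synthetic states
differ by a collective remodelling — SNA+WGA class density ×2, WGA spacing
×1.5, PSA density ×1.4, PHA-L ×0.7 — mirroring the observation that state
shifts redistribute many glycan features at once rather than altering a
single one.

## Known limitations

- The peak (mode) reduces each NN histogram to one number; the
  full-distribution feature mode retains more information at the cost of
  K²·200 features.
- The temporal filter's anchored bins miss boundary-straddling sticking
  events, and a sticking artifact whose localization cloud merges with a
  genuine site's cluster cannot be rejected by a per-cluster rule.
- Single-linkage chaining can in principle join distinct glycans through
  intermediate sites at high density; at the 5-nm cut-off and realistic
  densities this is rare but untested against alternatives.
- The fiducial detector presumes beads brighter and more persistent than
  any biological signal; dense bright clutter would defeat it.
- Channel alignment is rigid; chromatic or field-dependent warps are out of
  scope.
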