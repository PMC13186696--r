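# glycoatlas

Quantitative "glycan atlassing" of the cellular glycocalyx from multiplexed
DNA-PAINT single-molecule localization data.

The glycocalyx — the layer of glycosylated molecules coating every mammalian
cell — is imaged by DNA-PAINT with a panel of lectin labels (WGA, SNA,
PHA-L, AAL, PSA) plus an optional metabolic DBCO channel for azido-tagged
sialic acids. Each channel yields a table of single-molecule localizations
(frame, x, y, photons) over a 20,000-frame stack. `glycoatlas` turns those
tables into quantitative descriptors of nanoscale glycan organization and
embeddings that separate cellular states. It is written for microscopists
and computational biologists who have Picasso-style localization tables
(CSV + YAML sidecar) and want a reproducible, fully scripted analysis.

## The pipeline

1. **Registration** — residual drift correction and channel alignment from
   90-nm gold fiducials: per-frame drift is the track-mean displacement of
   the fiducials; channels are aligned by a least-squares rigid transform of
   matched fiducial positions. Fiducial localizations are removed before
   analysis.
2. **ROI segmentation** — a manual polygon confines the analysis to the
   cell; its shoelace area normalizes densities per µm².
3. **Localization precision (NeNA)** — for each channel, distances between
   localizations in adjacent frames are fitted with the mixture
   p(d) = w·d/(2σ²)·exp(−d²/4σ²) + (1−w)·2d/D², giving the experimental
   precision σ per channel.
4. **Binding-site calling** — localizations are clustered as fixed-radius
   connected components (radius 2σ, minimum 2 localizations). A cluster
   whose events concentrate >90% in one 200-frame bin (1% of the stack) is
   rejected as a sticking artifact; surviving cluster centres are the
   lectin binding sites.
5. **NN peak matrix** — for every ordered channel pair (i, j), the first
   nearest-neighbour distance histogram from channel-i sites to channel-j
   sites; its peak (smoothed mode) fills entry (i, j) of the K×K matrix.
6. **GlyCo classes** — sites of all channels within a 5-nm cut-off are
   grouped (single-linkage components); each group of ≥2 sites is a class
   named by the multiset of its member channels (e.g. `SNA+WGA`), with
   counts, densities per µm² and spatial maps.
7. **State embedding** — per-sample feature vectors (flattened peak
   matrices, class densities, or full NN distributions) are z-scored and
   decomposed by PCA; loadings report the correlation of each glycan
   feature with each component, and a silhouette score quantifies
   condition separation on PC1–2.

A synthetic scene generator (`scene_spec()` / `generate_scene()`) emulates
the acquisition — planted sites and class motifs, Poisson blinking over the
stack, Gaussian localization noise, drift, fiducial tracks and sticking
artifacts — with full ground truth, so every stage is validated without
experimental data.

## Worked example

```r
library(glycoatlas)

spec <- scene_spec(
  field_nm = c(5000, 5000), site_density_per_um2 = 30,
  motifs = list(list(channels = c("SNA", "WGA"), weight = 1)),
  motif_fraction = 0.3, mean_events = 10, mean_event_frames = 3, seed = 7)
scene <- generate_scene(spec)

wga <- scene$channels$WGA
wga
#> <loc_table> channel WGA: 24576 localizations over 20000 frames (nm units)

nena_precision(wga)
#> <precision_estimate> WGA sigma = 5.00 nm (n = 16403 pairs, background 1%)

sites <- lapply(names(scene$channels), function(ch)
  call_sites(scene$channels[[ch]],
             sigma_nm = nena_precision(scene$channels[[ch]])$sigma_nm))
names(sites) <- names(scene$channels)
sites$WGA
#> <binding_sites> channel WGA: 774 sites
#>   clusters raw 775, rejected by temporal filter 1

round(unclass(peak_matrix(sites)), 1)
#>        WGA  SNA PHA-L  AAL  PSA
#> WGA   74.5  1.5  78.5 66.5 73.5
#> SNA    1.5 75.5  87.5 70.5 99.5
#> PHA-L 81.5 93.5  81.5 72.5 46.5
#> AAL   66.5 70.5  82.5 82.5 67.5
#> PSA   73.5 85.5  89.5 83.5 71.5

glyco <- glyco_classes(sites, roi_area_um2(spec$roi), cutoff_nm = 5)
top_classes(glyco, 3)
#>         label size count density_per_um2
#> 1     SNA+WGA    2   474           18.96
#> 2 AAL+SNA+WGA    3     4            0.16
#> 3   PHA-L+PSA    2     3            0.12
```

Reading the output: NeNA recovers the planted 5-nm precision from 16,403
adjacent-frame pairs, so clustering runs at a 10-nm radius. The WGA↔SNA
entries of the peak matrix sit at 1.5 nm — the planted sub-5-nm motif —
while intra-channel peaks (≈70–80 nm) reflect the ~30 µm⁻² site density
(Rayleigh mode 1/√(2πλ) ≈ 73 nm). GlyCo recovers the planted `SNA+WGA`
class at 18.96 µm⁻², three orders of magnitude above the sparse chance
classes.

Multi-sample runs are orchestrated by `run_pipeline()` from a `run_config()`
(or YAML file), writing per-sample sites, matrices, class tables, PCA
outputs and a manifest. A thin command-line wrapper with `simulate`,
`register`, `precision`, `cluster`, `nn`, `glyco`, `embed` and `run`
subcommands is installed at `inst/cli/glycoatlas.R`.

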