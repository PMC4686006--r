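# fcseg

Feature-based fuzzy connectedness segmentation for B-mode ultrasound, in R.

Ultrasound images of layered anatomy — the motivating application is the
adipose (fat) ring around the muscle in fetal-arm cross-sections — defeat
intensity-based region growing: gain varies between scans, strong
multiplicative inhomogeneities cross the tissue of interest, and acoustic
shadows behind bone cut the object into pieces. `fcseg` addresses this
with:

* **Monogenic-signal features** — local amplitude, phase and orientation
  from a DC-free Gaussian-derivative bandpass
  `B(u) = |u| exp(−|u|²σ²)` plus the Riesz transform. Phase and
  orientation are invariant to image gain and offset.
* **Feature asymmetry edges** — a multi-scale measure
  `FA = (1/N) Σ_s ⌊|odd| − |even| − T_s⌋ / sqrt(even² + odd² + ε)`
  that highlights step edges, thinned by all-direction non-maximal
  suppression into an edge map `E`.
* **Absolute fuzzy connectedness** — pairwise affinity
  `μ(c,d) = ω₁(1 − E(c,d)) + ω₂ exp(−max{|φ(c)−m_o|, |φ(d)−m_o|}² / 2σ_o²)`
  on the 4-connected grid; each pixel receives the max-min path strength
  (strongest path, weakest link) to the seed set, computed exactly by a
  widest-path Dijkstra in compiled code, and the object is the superlevel
  set at `T_FC = 0.85`.
* **Shadow-gap completion** — convex-hull boundary, c-scale chords and
  inward normals, a thickness profile whose zero runs locate the shadow
  gaps, and straight-sided polygon fills (the bridge clinicians draw
  across a shadow).
* **Mean curvature flow** — level-set smoothing of the completed boundary.
* **Quality and evaluation** — regional entropies with the interface
  scores `S_ab`, `S_am`; TPAF/1−FPAF, Dice, repeatability precision, and
  symmetric contour distances (MSD/ASD/RMSD).
* **A deterministic speckle phantom** of a fetal-arm cross-section (bright
  fat annulus, dark muscle, bone with a shadow wedge, speckle and
  inhomogeneity) so the whole chain is testable without clinical data.

## Worked example

```r
library(fcseg)

ph <- makePhantom(phantomSpec(seed = 7))   # image + labels + true fat ring

# one-off training of the object phase statistics on a disc spanning the
# fat layer at the first seed (sd inflated x3, as in the clinical defaults)
cfg <- defaultConfig()                      # under-30-weeks preset
pm  <- phaseMaps(monogenicSignal(ph$image, cfg$phase$sigma))
st  <- fitObjectStats(pm, fcseg:::discMask(dim(ph$image), c(42, 128), 13))
cfg$fc$m_o <- st$m_o; cfg$fc$sigma_o <- st$sigma_o

res <- runPipeline(ph$image, seeds = c(42, 128), cfg,
                   truth = ph$truth, spacing = 0.2)
round(unlist(res$metrics), 4)
#>        tpaf        fpaf specificity        dice         msd         asd
#>      0.9591      0.0258      0.9742      0.9664      2.4083      0.1804
#>        rmsd
#>      0.3892
```

The final mask is a single closed ring (one component, one hole): the
fuzzy-connectedness stage segments the visible fat, the completion stage
fills the bone-shadow gap, and curvature flow rounds the fill. Running the
pipeline again from a different seed inside the ring returns a
bit-identical mask (`maskPrecision` = 1), the repeatability the fixed
affinity field guarantees.

Per-stage functions are exported individually (`monogenicSignal`,
`featureAsymmetry`, `modifiedNMS`, `featureAffinity`, `afcConnectivity`,
`completeObject`, `mcfSmooth`, `qualityScores`, `areaOverlap`,
`contourDistances`, …), and `inst/cli/fcseg.R` is a thin command-line
wrapper with verbs `segment | complete | smooth | features | quality |
eval | phantom` operating on PNG/TIFF images, JSON seed lists and YAML
configs.

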