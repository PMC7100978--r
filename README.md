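# qmosaic

Quantitative mosaic analysis of clonal tissue images.

Mosaic experiments in *Drosophila* imaginal discs use mitotic
recombination to generate clonal patches carrying zero, one, or two copies
of a gene of interest within one otherwise uniform tissue, with an
RFP-tagged clonal marker reporting each cell's dosage through its nuclear
fluorescence. Comparing a reporter between clones then tests whether the
perturbation regulates it — but only after someone segments thousands of
nuclei, removes spectral bleedthrough between channels, and labels every
nucleus with its gene dosage. `qmosaic` automates that workflow for
developmental biologists, and ships a synthetic clone-growth simulator so
every stage can be validated against known ground truth.

The package provides:

* **Segmentation** — Otsu thresholding of the smoothed, CLAHE-equalized
  nuclear stain; watershed on the Euclidean distance transform seeded at
  its local maxima; per-nucleus mean intensities per channel. Any external
  segmenter's output is accepted as a plain CSV measurement table
  (`cell_id, x, y, ch0, ...`).
* **Bleedthrough correction** — the target-channel background is modeled
  as *B* = Σₖ αₖ *F*ₖ + β over the other channels; coefficients are fitted
  with a gamma GLM (identity link) on background pixels resampled to a
  flat source-intensity histogram, then subtracted per nucleus.
* **Unsupervised annotation** — a K-component bivariate lognormal mixture
  (diagonal covariance, EM, BIC selection over K = 3…8) over each cell's
  log marker level *X* and its spatial context *Y*; components map to
  dosages {0, 1, 2} by k-means on their means e^μ. Context comes from the
  correlation decay length of *X*, refined by Infomap communities on a
  Delaunay graph weighted by expression similarity
  (w = exp(−|Xᵢ−Xⱼ|/⟨|ΔX|⟩)), and posteriors diffuse over that graph via
  the Katz-style solve p̂ = (I − αW)⁻¹(1−α)p. Labels with confidence
  below 80% fall back to the context-free marginal classifier.
* **Curation & statistics** — Delaunay-based clone-border flagging,
  polygon/x-window region-of-interest filters, two-sided Mann–Whitney U
  comparisons (exact for small tie-free groups).
* **Simulation & benchmarking** — stochastic clone growth with windowed
  recombination and force-directed repositioning; dosage-conditioned
  lognormal fluorescence (ln x ~ N(ln 2ⁿ⁻¹, σ²α)); image rendering; MAE
  benchmarking of the full versus marginal classifier across clone-size ×
  ambiguity grids.

## Worked example

Grow a synthetic mosaic culture, sample marker fluorescence, annotate
every cell, and compare the (here dosage-tracking) marker between the
homozygous clones:

```r
library(qmosaic)

cu  <- grow_culture(final_size = 512, recombination_start_size = 8,
                    recombination_duration = 8, seed = 42)
cu
#> Synthetic culture: 530 cells, 40 generations, 13 clones
#>   dosage counts: 0: 158, 1: 271, 2: 101
#>   mean clone size: 40.8 cells

tab <- synthesize_measurements(cu, sigma_alpha = 0.25, seed = 43)
ann <- annotate(tab, marker_channel = "ch1", seed = 44)
table(truth = tab$dosage_true, label = ann$dosage)
#>      label
#> truth   0   1   2
#>     0 148  10   0
#>     1  21 250   0
#>     2   0  22  79
mae(tab$dosage_true, ann$dosage)
#> [1] 0.1

ann$border <- flag_borders(cbind(ann$x, ann$y), ann$dosage)
compare_clones(ann, "ch1", 0, 2)
#> Mann-Whitney U (normal approx.): dosage 0 (n=27) vs 2 (n=11)
#>   U = 0, two-sided p = 1.901e-06
```

At σα = 0.25 the dosage distributions already overlap noticeably; 90% of
the 530 cells are labeled correctly (MAE 0.10), errors sit on clone
borders where context is genuinely ambiguous, and the marker difference
between 0- and 2-copy clones is detected at p ≈ 2·10⁻⁶ after border
exclusion. With the benchmark's standard 2048-cell cultures and σα = 0.1
the annotation is essentially perfect (accuracy ≥ 99.9%).

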