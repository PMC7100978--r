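---
title: "Methods: quantitative mosaic analysis with qmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative mosaic analysis with qmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mosaic analysis perturbs gene dosage in clonal patches of an otherwise
wildtype tissue: mitotic recombination in a heterozygous (one-copy) cell
produces daughters carrying two and zero copies of a fluorescently tagged
clonal marker, so clones are distinguished by low, medium, or high nuclear
marker fluorescence. Comparing a reporter of interest between clones then
reveals whether the perturbation affects its expression. `qmosaic`
automates the quantitative steps of that workflow for multichannel
confocal images of epithelial tissues such as *Drosophila* imaginal discs:
nuclear segmentation, spectral bleedthrough correction, unsupervised
per-nucleus dosage annotation, curation, and statistical comparison —
plus a synthetic-data generator and benchmark harness that make the whole
pipeline testable without microscopy data.

# Segmentation

The nuclear stain channel is smoothed (Gaussian, default sigma 2 px),
contrast-equalized (CLAHE, clip fraction 0.01 on 64 px tiles), and
thresholded by Otsu's method on the processed image; a Euclidean distance
transform of the resulting mask seeds watershed segmentation at its local
maxima (minimum seed separation 5 px). Segments under 10 px are treated as
speckle and dropped. These parameter values are package defaults — the
operators are standard but no canonical parameterization exists — and all
are exposed as arguments. Intensities are normalized to their maximum
before processing, so masks are invariant to linear rescaling (8- vs
16-bit acquisition). Segments touching the image border are kept;
exclusion is a curation decision. Every downstream stage accepts any
measurement table with `cell_id`, `x`, `y` and channel columns, so
third-party segmenters can replace this stage entirely.

# Bleedthrough correction

Fluorophores excited for one channel commonly emit into another, which
fabricates correlations between the clonal marker and the reporter being
compared. The background intensity of a target channel is modeled as a
linear superposition of the other channels plus an intercept,
\(B = \sum_k \alpha_k F_k + \beta\). The coefficients are estimated from
*background* pixels only: the nuclear foreground is dilated (3 px disc)
until its per-iteration growth falls below 1% (at most 20 iterations), the
remaining pixels are resampled so the source-channel intensity histogram
is flat across 10 equal-width bins (the raw background is heavily skewed
toward darkness), and a gamma-family, identity-link GLM of the target on
the source intensities is fitted to the resampled pixels, falling back to
ordinary least squares with a warning if the gamma IRLS fails. Each
nucleus is then corrected by subtracting
\(\widehat{B} = \sum_k \alpha_k \langle F_k\rangle + \beta\) from its
measured mean. Corrected values may be negative and are retained as such;
clipping here would bias the downstream rank tests, and the annotation
stage applies its own positivity floor (1% of the positive median) before
taking logarithms.

# Annotation

Each nucleus receives a dosage in {0, 1, 2}. Marker levels are modeled on
the log scale as a K-component mixture of normals — lognormal components
on the raw scale, consistent with multiplicative expression noise — over
two jointly distributed variables: the cell's own log level \(X\) and its
spatial context \(Y\), the mean \(X\) over a neighborhood. Covariances are
constrained diagonal. The model is fitted by EM (k-means initialization, 5
restarts, up to 500 iterations, relative log-likelihood tolerance
\(10^{-6}\), variance floored at \(10^{-6}\) of the data variance to
prevent component collapse) for K = 3…8, and the K minimizing
\(\mathrm{BIC} = \ln(N)\,q_K - 2\ln\hat L\) is kept, with
\(q_K = K-1+4K\) free parameters for the bivariate diagonal model.
Components map onto the three dosages by k-means clustering of their mean
levels \(e^{\mu_X}\) into three groups, ordered dimmest to brightest; when
K = 3 this reduces to rank order.

The neighborhood scale is chosen from the data: the radial correlation
\(\psi(\delta)\) of \(X\) is computed over 50 equal-count pair-separation
bins (pairs uniformly subsampled above \(5\times10^5\)), smoothed with a
5-bin moving average, and fitted with a least-squares exponential decay;
the decay length sets the context radius. At application time context is
refined further: cells become nodes of a graph whose edges come from
Delaunay triangulation (edges beyond the 95th length percentile dropped),
weighted by expression similarity
\(w_{ij} = \exp(-|X_i-X_j|/\langle|X_i-X_j|\rangle)\). Infomap community
detection — applied recursively within communities to build a hierarchy —
yields nested partitions, and the coarsest level whose mean community
spatial extent (twice the RMS member–centroid distance) stays below the
correlation decay length defines the communities; each cell's context is
its community mean. Component posteriors evaluated at \((X, Y^c)\) then
diffuse over the graph by the Katz-style closed form
\(\hat p = (I - \alpha W)^{-1}(1-\alpha)\,p\), with
\(\alpha = 0.9/\rho(W)\) (power-iteration estimate of the spectral
radius), which guarantees invertibility. The diffused posteriors are
renormalized per cell: the linear solve does not preserve the probability
scale, the argmax label is unaffected, but confidences require a
probability scale. Each cell takes the dosage of its most probable
component (ties to the lowest index, for reproducibility), with confidence
equal to the summed diffused posterior mass of that dosage. Labels whose
confidence falls below 0.80 are replaced by the marginal classifier's
label — the argmax over the X-axis marginal posteriors, which ignores
spatial context — a fallback that protects accuracy when clones are too
small for context to be informative.

Two scales of context coexist deliberately: radius-based during training,
community-based at application, following the algorithm's design; the two
agree when expression is locally homogeneous, which is exactly the regime
where context carries information. The number of labels is configurable
(2 for binary mutant/non-mutant schemes). One model is trained per image
by default; pooling across images is supported but couples all labels to a
single EM outcome.

# Curation and comparison

Cells with any Delaunay neighbor (same 95% edge-length filter, so
"neighbor" means the same thing as in the cell graph) of a different
dosage are flagged as clone borders and excluded from comparisons, since
diffusion-mediated signaling across clone boundaries blurs expression
differences there. Analyses can be restricted to a polygonal region of
interest (even-odd rule, boundary inclusive; supplied as vertices rather
than drawn interactively, so analyses are scriptable) and to an x-axis
window selecting cells of comparable developmental age. Reporter levels
between two dosage groups are compared by two-sided Mann–Whitney U test:
exact null distribution when both groups have at most 20 tie-free
observations, normal approximation with tie correction otherwise; the
reported U is the smaller orientation.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated. A culture grows from one heterozygous cell by synchronous
rounds in which every cell divides with probability 0.2; while the
recombination window is open, each dividing one-copy cell recombines with
probability 0.2, founding a two-copy and a zero-copy clone. The window
opens when the population first reaches `recombination_start_size` and
lasts `recombination_duration` rounds, which together tune clone number
and size (earlier onset, larger clones). Growth stops above a final size
of 2048 cells. After each round, cells are repositioned: Delaunay edges
(sliver triangles with interior angles above 150° lose their longest
edge, removing spurious hull connections), a 10% attraction bonus between
same-dosage neighbors so clones stay cohesive, and a fixed budget of 50
Fruchterman–Reingold iterations seeded from the current coordinates.
Node–node repulsion in the force-directed layout supplies the outward
pressure that keeps density approximately uniform as the population grows
— pure nearest-neighbor springs cannot, because opposing neighbor forces
cancel in the bulk interior, and re-deriving the rest length from the
current median edge each round lets newborn cells ratchet the culture
into collapse. The layout's natural equilibrium spacing sets the spatial
scale; nothing downstream depends on absolute units.

Marker fluorescence is sampled per cell from a lognormal conditioned on
dosage \(n\): \(\ln x \sim \mathcal N(\mu_n, \sigma_\alpha^2)\) with
\(\mu_n = \ln 2^{\,n-1}\), so the mean level doubles per gene copy
(medians 0.5, 1, 2). The *fluorescence ambiguity* \(\sigma_\alpha\)
controls how much adjacent dosage distributions overlap and is the
difficulty axis of every benchmark. Cultures can be rendered as
multichannel disk images (uniform stain disks, marker-shaded disks,
optional Gaussian read noise), and a control-experiment renderer adds a
dosage-independent reporter channel contaminated by a known pixel-level
bleedthrough coefficient over a smooth background gradient, which is what
makes the injected coefficient identifiable from background pixels.

What the generator does *not* emulate: irregular nucleus shapes and
z-overlap, spatially varying stain efficiency, cell death, and real
optics (PSF, shot noise). Passing benchmarks therefore demonstrate the
statistical machinery under the stated generative assumptions, not
segmentation robustness on difficult real images — which is why the
package accepts external segmentation output unchanged.

# Benchmarking

Annotation quality is scored by mean absolute error over the ordered
dosage labels, which penalizes 0↔2 confusions twice as heavily as
adjacent ones, alongside plain accuracy. The benchmark grid crosses
recombination onset (the clone-size control; realized mean cells/clone is
reported, as clone size is emergent) with fluorescence ambiguity, runs
independent replicates with a freshly trained model each (borders not
excluded, so scores are a lower bound), and compares the full classifier
against the marginal one via the per-condition log2 MAE fold-change, MAE
floored at one-cell resolution. Replicate failures are recorded, not
fatal.

Problem sizes in the shipped tests and acceptance script are chosen to
keep a full run in the range of minutes on one core: 2048-cell cultures
with 2–3 replicates for the headline regimes (the benchmark's stated
termination size), 512-cell cultures for trend checks (ambiguity
monotonicity, clone-size independence), and 20-seed loops for parameter
recovery. The high-ambiguity regime (\(\sigma_\alpha \ge 0.5\)) with few
clones is genuinely hard: when nearly all cells are heterozygous, the
three-way component mapping must still produce all three labels, and
absolute MAE can approach 1. The meaningful claim there — which the tests
assert — is relative: spatial context lowers MAE compared to the marginal
classifier, and the advantage grows with clone size.

# Numerical choices and edge cases

* EM degeneracy (vanishing variance or collapsed weight) triggers a
  jittered random restart; all restarts failing is an error, not a silent
  fallback.
* Coincident cell positions are deterministically jittered by \(10^{-3}\)
  before triangulation; collinear inputs raise a triangulation error.
* A culture whose recombination window closes without any event is a
  single clone; benchmark conditions that presuppose a mosaic use an
  8-generation window, making that outcome negligibly rare (< 1%).
* Infomap cuts that degenerate to singleton communities fall back to
  radius-based context.
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical cultures, fits, and benchmark tables.
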