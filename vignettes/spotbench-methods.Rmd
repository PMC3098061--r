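---
title: "spotbench: methods, models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotbench: methods, models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Fluorescently labeled subcellular objects — P-bodies, vesicles, boutons —
show up as bright, roughly Gaussian intensity peaks a few pixels wide on a
background that is anything but flat: cytoplasm autofluorescence, texture,
out-of-focus light. A detector must decide, per image and without manual
threshold fiddling, which local peaks are objects. `spotbench` implements
eleven such detectors behind one interface, plus the apparatus needed to
compare them honestly: ground-truth simulation, object- and pixel-level
precision/recall/F-score, whole-set grid-search tuning, and cross-method
similarity analysis.

All detectors share a few conventions. Images are 2-D non-negative real
matrices (`gray_image`); RGB input is collapsed with the standard luma
weights 0.2989/0.5870/0.1140, used exactly as printed (their sum is
0.9999; no renormalization). Coordinates are (row, col), 0-based, pixel
centers at integers. Filters pad borders by symmetric reflection —
zero-padding would manufacture spurious border detections. Detectors never
mutate their input and are deterministic given (image, parameters); the
one sampling-based method (HD) carries its seed in its parameter object.
An optional Gaussian low-pass prefilter (`lowpass_prefilter`, default off)
can be enabled per method and per dataset for methods that suffer from
noise-induced false detections; it is a data-level choice, not a tuned
grid axis.

# The detectors and their parameters

**BPF** — band-pass filtering. Four normalized cut-offs
`w1 < w2 <= w3 < w4` (1 = Nyquist) define pass band [w2, w3]. The filter
is realized as the difference of two separable windowed-sinc (Hamming)
low-passes with cut-offs at the transition-band midpoints; the order is
`round(4 / (w2 - w1))` rounded odd. Both low-passes have unit DC gain, so
DC is rejected exactly. The residual is binarized with Otsu's threshold.
Two guards matter: (i) reflective padding leaves border transients, so the
*signal-present* decision is made on the filter's fully supported
interior; (ii) if that interior residual's dynamic range is below 1% of
the input's, the image is declared signal-free and the mask is empty —
an automatic threshold must not hallucinate structure from a residual
dominated by numerical leakage.

**KDE** — Parzen smoothing with a circular window of radius `R` (pixels)
and kernel argument distance/`h`, normalized by the cardinality of the
in-bounds window set, then Otsu. Seven kernel families are available; at
image-set level the choice moves the tuned F-score by less than 0.05, so
`uniform` is a fine default.

**LC** — local comparison. A circular mean filter of radius `R >= 2` is
split into four quadrant filters (axis pixels joining the
counter-clockwise quadrant, center excluded, each renormalized to unit
sum). A pixel is an object iff `alpha * f` strictly exceeds the maximum
of the four direction-filtered values. `alpha` (around 1.1–1.5 in
practice) tunes the implied threshold. Because the decision is a ratio
against local means, a sizable camera baseline stabilises it; near-zero
backgrounds make the ratio noise-dominated (visible in the simulated
world when the baseline is removed).

**LEF** — matched filtering. The image mean is rescaled to
`target_mean = 100`, then a spot-likelihood is the ratio of the mean over
an inner disc (radius 2) to the mean over the rest of a 9×9 kernel
(epsilon 1e-6 in the divisor); threshold `th_s * sd(likelihood)`, with an
empty mask when the likelihood is essentially constant (sd < 1e-9). The
kernel geometry is deliberately fixed so `th_s` is the only free
parameter; the mean normalization plus ratio form make the mask invariant
under uniform intensity scaling.

**MW** — multiscale wavelet products. Undecimated B3-spline à trous
decomposition ([1/16, 1/4, 3/8, 1/4, 1/16] with 2^(i−1)−1 zeros inserted
at scale i); plane `W_i = A_{i-1} - A_i`; reconstruction
`A_0 = A_J + sum W_i` holds to machine precision. Each plane is
hard-thresholded at `3 * sigma_i`, `sigma_i = MAD(W_i)/0.67`, keeping
positive coefficients; the pixelwise product of the thresholded planes is
compared against the detection level `l_d`. Spots persist across scales;
noise does not survive the product.

**SE** — background-clipping detector. Per block (side `block_size`), the
intensity set is clipped to median ± 3 sd until stable; if the sd changed
by less than 20% in total the clipped mean is the background, else
`BG = 2.5 * Median - 1.5 * Mean`. (The 20% criterion is read as *total*
change from the unclipped sd.) Block values are bilinearly interpolated,
the background subtracted, the residual Gaussian-filtered, and pixels
above `th_detect * sigma + th_bg * BG` kept (`th_bg = 0` recovers the
original formulation). Merged detections are deblended by slicing each
component's intensity range into 30 levels top-down and splitting when at
least two branches each carry more than `deblend_min_contrast = 0.005` of
the component's integrated intensity — a single-pass version of the full
branch-tree scheme, sufficient for pairwise blends; the deblended labels
ride along with the mask and drive object counting.

**THE** — top-hat. Residual `f - (f open disc(r))`, binarized with
Kapur's maximum-entropy threshold (more conservative than Otsu on spot
images). Fully automatic apart from `r`, and therefore — as the
benchmarks show — at the mercy of its automatic threshold on images with
no objects at all.

**FPD** — feature-point detection. Restoration kernel = normalized
Gaussian (width `lambda_n = 1`) minus boxcar over the (2w+1)² window
(zero-mean by construction); candidates are strict window local maxima;
the brightest `r_pct` percent of candidates are kept (computed over
candidates, which keeps the per-image count roughly stable — the method's
signature behavior); locations are refined by intensity-weighted
centroid; candidates are discriminated in the (m0, m2) intensity-moment
plane by a squared-Mahalanobis cut at `T_s` against the candidate cloud.
The percentile rule makes the output invariant to intensity scaling.

**SPL** — sub-pixel localization. Candidates are pixels strictly brighter
than their 8 neighbors; the local background (mean, sd) comes from the
outer ring of the (4 sigma + 1) fit window. A candidate survives iff its
height exceeds the background sd times the Šidák-corrected quantile
`qnorm((1-alpha)^(1/9))` — a strict 3×3 maximum is the largest of nine
values, and the plain (1−alpha) quantile would run at ~9× the nominal
type-I rate. Survivors get a Gauss–Newton fit of a fixed-width 2-D
Gaussian (free amplitude, center, offset); a fit that diverges or walks
more than ~1 px from its seed keeps the integer location and is counted in
a log message.

**HD** — h-dome. The image is LoG-filtered at `sigma_L` (scale-normalized,
sign-flipped, zero-mean kernel: bright spots become positive peaks on a
subtracted background), and the dome of height `h` is extracted as
`H = F - R(F; F - h)` by grayscale reconstruction. The marker is anchored
to `F` at the image border: background is assumed to continue beyond the
field of view, so a plateau touching the border is background. (Without
anchoring, a constant image is its own dome of height exactly `h` — the
textbook identity — which floods the sampling map with a uniform
baseline.) `H^s` normalized is used as a probability map; `n_samples`
pixels are drawn (fixed seed), clustered by flat-kernel mean-shift at
bandwidth `sigma_M` (tolerance 1e-3 px, 200 iterations, modes merged
within `sigma_M`/2). A cluster is accepted iff it holds at least 1% of
the samples, its RMS spread is at most `sigma_M`, and the dome support at
its centroid (the 8-connected component of `H >= h/2`) exists with
equivalent radius at most `2 sigma_M` — a structure that did not rise `h`
above its surroundings, or whose dome is much wider than the allowed
object scale, is not an object under this model. Accepted clusters
contribute their dome support to the mask and their centroids to the
point list.

**MGI** — granulometric morphometry, parameter-free. The size density
G(d) over odd disc diameters uses the pattern-spectrum convention: the
loss attributed to diameter d is the intensity removed by the first
opening *larger* than d (an opening with a disc of the object's own size
still retains the object, so the naive successive-difference convention
registers every object two sizes too late). Discrete-disc opening sums
are not perfectly nested, so the theoretical monotone sieve property is
enforced (`cummin`) before differencing. The two highest peaks give
`d_low` (spot scale) and `d_high` (cell scale); the difference of the
corresponding openings isolates structures between the scales; a
2-cluster k-means mask of the original image (deterministic min/max
initialization) restricts to bright regions; and an integral threshold
keeps the brightest masked difference pixels until 95% of cumulative
intensity is covered. The opposite reading (keep the top 5% of mass) was
measured and rejected: it collapses recall on the benchmark scenes
(pooled F 0.37 vs 0.81). Fewer than two peaks in G — typical for empty
images — raises a scale-selection error that the detector converts to an
empty mask with a warning; this is the mechanism behind MGI's documented
fragility on near-empty frames.

# Evaluation conventions

Object matching is a maximal one-to-one assignment (Hungarian, via a
large-constant cost for infeasible pairs): a pair is feasible iff centroid
distance ≤ `match_radius` (point references; default 4 px, configurable)
or component overlap ≥ 1 pixel (mask references), with ties broken by
total distance. Greedy matching would make scores order-dependent.
Empty-denominator conventions: no detections but references present →
precision 0; detections but no references → recall 0; both absent →
p = r = F = 1, because an empty image correctly left empty is a perfect
result — this matters whenever empty frames are possible. `tp + fn`
always equals the reference count. Tuning pools TP/FP/FN over the image
set before scoring (micro-averaging): per-image F is ill-posed on empty
images, and pooled counts answer the question a screen actually asks.
Point-output detectors (FPD, SPL) are excluded from pixel-level scoring
by construction.

The count-distribution statistics use `kruskal.test` and pairwise
two-sided Wilcoxon rank-sum tests (exact enumeration up to n = 25 without
ties, normal approximation with tie correction beyond). Method similarity
is the Pearson correlation of per-image count vectors (Spearman by flag),
clustered with average linkage on 1 − correlation; both choices are
recorded in the output because the convention is not forced by anything
deeper than common practice.

# The synthetic world

`sim_config()` states the benchmark world once: 128-px frames (96 px in
the reduced test runs), 10 elliptical cells (6 in tests) with smooth
intra-cell texture, nuclei and spots on their own channels
(cytoplasm = red, spots = green, nuclei = blue, collapsed by the standard
luma conversion, which leaves spots slightly brighter than their
surroundings), 3 spots per cell with sigma 1.0–1.6 px, spot-channel peak
150, cytoplasm 30, nuclei 60, a baseline of 25 on every channel (sensor
bias plus diffuse autofluorescence — ratio-based detectors are genuinely
unstable on a near-zero baseline, and real CCD images do not have one),
additive Gaussian noise sd 5, and 25% of spots rendered with a 3× wider
PSF. Out-of-focus spots conserve integrated intensity (peak scaled by
1/blur²), stay visible, and are excluded from the truth: the in-focus
criterion is rendered sigma ≤ 1.5× nominal, mirroring annotation
protocols where only in-focus objects are marked. The truth mask is the
union of pixels where a spot's noiseless contribution exceeds half its
peak — pixel-level truth needs a crisp boundary, and full-width at half
maximum is the crispest defensible one.

Focal stacks reuse one latent spot field and apply a per-frame PSF
widening profile, so frames with factor > 1.5 contain only out-of-focus
objects and carry empty truth. Dose plates draw per-cell spot counts
Poisson with a planted per-dose mean; the low-dose level used in the
acceptance scenario is 0.5 spots/cell — few, not zero, as in real plate
data — with the genuinely-empty-image stress case living in the stack
scenario.

Randomness uses R's own Mersenne–Twister via `set.seed(seed)`, with the
seed recorded in every scene; R guarantees cross-platform stream
stability, which is the property a portable generator is meant to buy.

What the generator does **not** emulate: realistic PSF shapes beyond
Gaussians, depth-dependent aberrations, camera noise physics beyond
additive Gaussian, spot shape irregularity, touching cells, or the
specific textures of any published benchmark. A green test on this world
therefore establishes that a detector implements its model correctly and
behaves as the field reports under these controlled conditions — not that
it will reach the same scores on any particular real dataset.

# What the benchmarks show (and the tests assert)

On 20 benchmark scenes, all eleven tuned detectors exceed object-level
F = 0.5 (most 0.75–0.95), and every mask-based detector scores lower at
pixel level than at object level — finding an object is easier than
outlining it. On stacks with empty frames, THE and MGI keep high recall
on in-focus frames but accumulate false positives on the empty ones,
collapsing pooled precision — their automatic thresholds assume both
classes are present. On dose plates with a planted step, tuned BPF
(with the prefilter enabled for this set), SE, and SPL recover a monotone
step in median spots-per-cell. These are the package's own measurements,
computed by `tests/testthat/test-acceptance.R` on every run.

# Numerical choices and degenerate inputs

- Histogram thresholds (Otsu, Kapur) are computed over `nbins`
  equal-width bins on [min, max]; criterion ties break toward the lowest
  threshold (conservative foreground). A constant image raises
  "degenerate histogram"; detectors convert it to an empty mask.
- `kmeans2_binarize` initializes centers at the intensity minimum and
  maximum (deterministic farthest-point) and runs Lloyd to convergence,
  so MGI is reproducible; a constant image yields an all-zero mask.
- Grid search evaluates feasible points in `expand.grid` order and breaks
  F-score ties toward the first point; infeasible combinations
  (constructor errors, e.g. unordered BPF cut-offs) are excluded before
  evaluation. Grid points are independent, so concurrent evaluation
  cannot change the result.
- Shipped default grids are package-chosen (small integer lists for size
  parameters, geometric sequences for thresholds) and are meant as
  starting ranges, not as the study's original search spaces, which are
  not published.
- Sub-pixel refinements (FPD centroid, SPL fit) are constrained to stay
  within ~1 px of their seed maximum; a refinement that leaves this basin
  is treated as non-convergent.

# Known limitations

- SE deblending is single-pass (one split level per object), not a full
  recursive branch tree; heavily nested blends may under-split.
- The discrete Euclidean discs used by THE/MGI make granulometry bumpy on
  perfectly sharp synthetic shapes; the monotone-sieve repair removes
  sign violations but not the bumps themselves (real, optics-blurred
  structures are much better behaved).
- FPD's moment-space discrimination is a Mahalanobis cut against the
  candidate cloud, a documented stand-in for the original clustering
  procedure whose geometry is not restated in the accessible sources.
- File I/O covers uncompressed single-page TIFF (8/16-bit gray, 8-bit
  RGB), PNG, and CSV point lists; compressed or multi-page TIFF is out of
  scope.
- Frames are processed independently; there is no 3-D volume processing,
  tracking, or temporal averaging.
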