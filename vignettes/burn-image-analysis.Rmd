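---
title: "Methods: burn-wound image analysis with burnscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burn-wound image analysis with burnscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnscope)
```

# The problem

Burn-depth assessment from ordinary RGB photographs asks two questions per
sample: *which depth class* (superficial, dermal / superficial-dermal, or
deep-dermal / full-thickness) does each region of the wound belong to, and
*what fraction of the photographed sample* does each class occupy. burnscope
implements a full desk-scale pipeline for both questions and, because
clinical burn photographs are rarely shareable, ships a seeded phantom
generator so that every stage is testable end to end against known ground
truth.

The pipeline, in order: sRGB photographs are converted to CIE 1976 L\*u\*v\*;
the planes are Gaussian-smoothed; the luminance plane is contrast-enhanced by
an operator tied to a Tofts contrast-uptake simulation; two segmentation
algorithms produce label maps (fuzzy C-means with region-contrast summaries,
and a histogram-peak "reference region" labeler); co-occurrence texture
features summarize luminance and chroma; compact neural classifiers assign a
per-image depth class; and a report gives exact per-class area percentages of
the sample.

# Color model and smoothing

RGB input is assumed sRGB-companded under a D65 white point — the situation
for consumer cameras; no ICC handling is attempted. The conversion is the
standard sRGB → linear RGB → XYZ → L\*u\*v\* chain. The reference white is
taken as the row sums of the RGB→XYZ matrix itself so that neutral pixels map
to *exactly* u\* = v\* = 0 rather than to small residuals. Black pixels
(Y = 0), where (u', v') is undefined, are assigned u\* = v\* = 0. Round-trip
error against 8-bit RGB is at most one intensity level (tested).

Smoothing uses an explicitly normalized Gaussian kernel, default size 5 and
sigma 1.5 pixels — a balance between noise suppression and preservation of
lesion boundaries. Convolution pads by *reflection*: zero padding would
darken borders and bias both the histogram segmentation and the co-occurrence
features computed downstream. Each of L, u, v is filtered independently.

# Contrast kinetics and the enhancement operator

Tissue uptake follows the standard two-compartment Tofts model

$$C_t(t) = K^{trans} \int_0^t C_p(\tau)\, e^{-\frac{K^{trans}}{v_e}(t-\tau)}\,d\tau,$$

with transfer constant $K^{trans}$ (1/min) and EES volume fraction
$v_e \in (0,1]$. The integral is evaluated by trapezoidal quadrature in its
recursive (exponential-carry) form, which is algebraically identical to
quadrature of the full convolution but linear-time. Against the
constant-input closed form $c\,v_e(1-e^{-K^{trans}t/v_e})$ the relative error
is below $10^{-5}$ on a 1000-point grid (tested at $10^{-3}$ tolerance). The
plasma input can be constant or the usual biexponential decay; units are
deliberately unspecified, as only the *normalized* uptake enters the
enhancement below.

The enhancement operator applied to the luminance plane is

$$L' = 100\,(L/100)^{\gamma}, \qquad L' \leftarrow L' + g\,U\,(100 - L'),$$

where $U = C_t(t_{eval})/\max C_t \in [0,1]$ (1 when no curve is supplied).
It is a monotone pixelwise remap: ordering in L is preserved, u and v are
untouched.

**Operating regime and parameter defaults.** The binned-histogram entropy of
a smoothly-distributed plane changes under a monotone remap $f$ by
approximately $E[\log_2 f'(L)]$. Every mean-raising member of the family
above has $E[\log_2 f'] < 0$ on *bright* images (mean $L/100 > 1/e$): it can
only compress them. On *dark*, wound-dominated images — the regime of
under-exposed clinical burn photographs, and the regime this operator is for
— a gamma below 1 both raises the mean and spreads the histogram. The
defaults $\gamma = 0.85$, $g = 0.02$ were chosen in that regime: the gamma
term does the perceptual work, and the uptake gain is kept small because the
lift term $g\,U\,(100-L')$ always compresses dynamic range. On already
bright, well-exposed images the operator brightens but cannot add histogram
information; this is a documented limitation of the operator family, not of
its implementation.

`intensity_stats()` reports mean, population SD, Shannon entropy (base 2,
256-bin histogram over the plane's nominal range), Fisher–Pearson skewness
$m_3/m_2^{3/2}$ and *raw* (non-excess) kurtosis $m_4/m_2^2$ — the raw
convention is what makes heavy-tailed 8-bit imagery report kurtosis in the
hundreds. Constant planes are flagged degenerate with skewness and kurtosis
reported as 0.

# Region analysis: fuzzy C-means and contrast summaries

Segmentation clusters the enhanced L-plane intensities with Bezdek's fuzzy
C-means: memberships $u_{ik} = 1/\sum_j (d_{ik}/d_{ij})^{2/(m-1)}$, centers
$c_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m$, alternated until the largest
center shift drops below `tol`. Hyperparameter defaults are the standard
choices: fuzzifier $m = 2$, `tol` $10^{-5}$, 300 iterations maximum, and
k-means++-style *seeded* center initialization, which makes every run
reproducible. `ncluster` defaults to 4 (healthy plus three burn depths).
The objective $\sum_{ik} u_{ik}^m d_{ik}^2$ is recorded per iteration and is
nonincreasing (property-tested). Hard labels take the maximum membership,
ties resolving to the lower label; labels index centers in ascending
intensity order. Cluster levels map onto depth codes brightest-to-shallowest
(the brightest cluster is healthy skin, the darkest is deep burn), reflecting
that tissue damage darkens the wound.

Two different "pixel difference" summaries coexist deliberately because they
measure different things: `pixel_pdf()` is the pixelwise diagonal-neighbor
difference $|I(i,j) - I(i{+}1,j{+}1)|$ (an edge map), while the region-level
summary squares the differences of *adjacent region averages* $g$. Both are
computed and logged by the pipeline. The dispersion statistic
$\sum_{ii} (g(ii) - \bar g)^2$, with $\bar g$ the mean cluster center,
quantifies between-region contrast concentration.

An optional pre-stage unmixes the (L, u, v) planes by fixed-point ICA
(symmetric negentropy maximization, logcosh contrast) and clusters the most
non-Gaussian component instead of L. Components are sign-fixed to nonnegative
skewness and ordered by non-Gaussianity; data whose every component is
statistically indistinguishable from Gaussian (negentropy proxy below
$10^{-4}$) are flagged unidentifiable with a warning, since ICA cannot
separate Gaussian sources.

# The reference-region histogram labeler

The second segmentation path works on the 0–255 luminance histogram:

1. pixels below `zth` are discarded as dark background; the rest are
   quantized to `qlevels` uniform bins (bin-center values);
2. local maxima of the 256-bin histogram whose count exceeds the *mean count
   of nonzero bins* become candidate centers, visited in decreasing count
   order; a candidate closer than `dth` to an accepted center merges into it
   at the count-weighted mean position (re-merged until all gaps are at
   least `dth`); if no maximum clears the threshold, the global maximum
   becomes the single center;
3. pass one labels each pixel with its nearest center when the distance is
   within a similarity threshold `th`; pass two raises `th` to the largest
   minimum-center distance among still-unlabeled pixels and repeats, which
   makes labeling total by construction; discarded pixels and any degenerate
   leftovers receive label 1; equidistant pixels take the lower center.

Defaults `zth = 10`, `dth = 16`, `qlevels = 64` were chosen so that
histograms with the four phantom class modes resolve into four centers. The
acceptance threshold for peaks is in *count* units; the labeling similarity
threshold is in *intensity* units and defaults to `dth/2` (the natural
"half-gap" radius), overridable in `rr_params()`. The stop rule for center
collection is "no remaining local maximum above the count threshold"; the
per-label pixel shares always sum to exactly 100 because they are ratios of
integer counts.

# Texture features

`compute_glcm()` counts gray-level pairs at displacement `d` along 0°, 45°,
90° and 135°, symmetric and normalized by default. The "8×8" setting is read
as *8 quantization levels* (an 8×8 matrix, the default `G = 8`, `d = 1`),
not an 8×8 sliding window, because the feature stage computes whole-image
matrices. Contrast is $\sum (i-j)^2 P(i,j)$ and correlation the normalized
covariance of the pair distribution; a zero-variance (single-level) matrix
reports correlation 0 with a degenerate flag. The implementation is verified
*exactly* against brute-force pair enumeration over all angles and
distances.

The 10-value feature vector takes, for each of two source planes — luminance
L and chroma magnitude $\sqrt{u^2+v^2}$ (the natural rotation-invariant
summary of the two chrominance axes) — the offset-averaged contrast and
correlation of the plane and of its square, plus the plane mean. The squared
plane emphasizes bright-region texture; the means carry the absolute color
level that pure co-occurrence statistics discard. Offset averaging makes the
vector invariant to transposition (tested).

# Classifiers

Three architectures, written as a compact seeded backprop engine on base
matrix operations (He-normal initialization, Adam with learning rate
$10^{-3}$, batch size 8, shuffle per epoch, categorical cross-entropy):

* **cnn** — three 3×3 convolution blocks (32, 64, 128 filters, ReLU, 2×2
  max-pool), dropout 0.25 on the flattened features, a 128-unit dense layer,
  3-way softmax. Input: the L, u, v planes stacked as 3 channels. The
  *architectural* input size is 224×224; the package trains at a
  configurable size and the shipped experiments use 32×32, which preserves
  the phantom classes' color/texture separability at a desk-scale
  computational budget (the choice is a package decision, documented here).
* **fnn** — a dense 32/16 ReLU stack on the 10-value texture vector,
  standardized with training-set statistics stored in the model.
* **rnn** — a 64-unit tanh recurrence consuming the rows of the downsampled
  L plane as a 32-step sequence of 32 features. Sequencing an image this way
  is a stand-in (any row/column serialization is equally arbitrary) and is
  labeled as such.

The optimizer (Adam) and the hidden widths of the fnn are package choices —
reasonable modern defaults, configurable. Training epochs default to 50.
Augmentation draws, per image and epoch: rotation uniform in ±15° (nearest
neighbor, reflective fill), horizontal/vertical flips with probability 1/2,
multiplicative brightness in [0.8, 1.2] (clipped), and center zoom in
[0.9, 1.1]. On prepared model inputs the brightness factor applies to the
luminance plane only. All randomness (shuffling, dropout, augmentation) runs
under one seed; two runs with the same seed produce bitwise-identical
weights (tested).

Splitting follows a fixed rounding rule: train takes
$\lfloor 0.70\,n \rfloor$ items, validation round-half-up of $0.15\,n$, test
the remainder — at $n = 90$ exactly 63/14/13. Within splits, classes are
allocated by largest-remainder quotas, keeping every class within one item
of exact proportionality. Stratified k-fold (default 5) partitions are also
provided. For comparison with binary deep-vs-rest reporting,
`collapse_severity()` maps classes {superficial, dermal} to one severity
level and deep to the other.

# Burned-surface reporting

`tbsa_percentages()` treats the photographed sample as 100% and reports each
class's exact pixel share, always including the healthy class so the
percentages conserve to 100 — deliberately *not* the clinical rule-of-nines
TBSA, which needs whole-body context a single photograph cannot give. When
segmentation is bypassed with the ground-truth mask, reported percentages
equal the generator's area fractions exactly. Per-class luminance histograms
apply the same `zth` dark-bin suppression and `dth` peak merging as the
reference-region labeler. The report bundle is JSON plus a color-coded
overlay (yellow superficial, blue dermal, red deep, gray healthy) and an SVG
pie whose slice angles are proportional to the percentages.

# The phantom generator

`generate_phantom()` rasterizes one to three nested ellipses (superficial
ring outside, dermal, deep core) on a healthy background and paints each
class with a mean RGB plus correlated Gaussian noise:

| class | mean RGB | SD | texture scale (px) |
|---|---|---|---|
| healthy | (205, 170, 150) | 8 | 3.5 |
| superficial | (230, 160, 140) | 10 | 2.5 |
| dermal | (200, 90, 80) | 12 | 1.5 |
| deep | (120, 40, 35) | 10 | 0.8 |

The palette darkens and reddens with depth and the noise correlation length
shrinks (finer granularity), so that (a) intensity clustering can separate
the classes and (b) co-occurrence contrast orders them monotonically with
depth — the generator encodes the working premise that depth correlates with
color and texture. This is *synthetic* truth: phantoms have clean class
geometry, no specular highlights, no perspective or scale variation
(capture distance is not modeled), no camera noise or illumination gradients.
Tests passing on phantoms validate the pipeline's mechanics, not the
clinical claim. An `"exact"` geometry mode assigns pixel-exact class runs
for worked-percentage constructions (e.g. the 90% deep / 10% superficial
sample).

`generate_dataset()` draws n phantoms (default 90, the scale of a small
clinical collection) with balanced dominant classes; the dominant class gets
the largest lesion ring (fraction 0.25–0.35 vs 0.04–0.09). Everything is a
pure function of (spec, seed).

# Problem sizes and numerical choices

The shipped experiments use: 256×256 phantoms (64×64 in high-repetition
property tests), the 90-item dataset with the 63/14/13 split, 50 training
epochs, CNN input 32×32. Tolerances: FCM center shift $10^{-5}$; Tofts
quadrature tested at $10^{-3}$ relative; GLCM against brute force at
$10^{-12}$; membership row sums at $10^{-9}$. Tie-breaks are all "lower
index wins" (FCM level assignment, nearest-center labeling). Degenerate
inputs: constant planes quantize to level 0 and report degenerate
correlation; all-dark images are rejected by the reference-region stage with
an explicit error; Gaussian-only channels flag ICA unidentifiability.

# Known limitations

* The enhancement operator cannot increase histogram entropy on bright,
  well-exposed inputs (see above); it is designed for dark wound imagery.
* Phantoms do not model illumination, scale, or camera variation, so
  classifier accuracies on phantoms are upper bounds on clinical behavior.
* FCM runs on intensities only (no spatial regularization); thin lesion
  rings with overlapping intensity distributions can exchange labels.
* The RNN's row-sequencing of images is a documented stand-in architecture.
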