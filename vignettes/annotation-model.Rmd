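---
title: "Marker-guided semantic annotation of spatial transcriptomics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-guided semantic annotation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotanno)
```

## The problem

Spatial transcriptomics assays measure a gene-count vector at thousands of
barcoded capture locations ("spots") with known (x, y) positions. Most
analysis starts from unsupervised clustering, whose clusters must then be
matched to anatomy by hand. `spotanno` inverts this workflow: the user names
the tissue structures of interest ("patterns") and supplies as little as one
marker gene per pattern, and the package assigns every spot to a pattern —
semantic annotation, by analogy with semantic segmentation in computer
vision.

Annotation proceeds in two stages.

1. **Pattern detector.** Marker expression is rasterized into a multichannel
   pseudo-image and segmented with image-processing operators, yielding an
   initial per-spot labeling and a per-spot feature vector.
2. **Bayesian refinement.** Because the image operators (smoothing,
   sharpening, morphology) can distort biology, a probabilistic classifier is
   rebuilt on the *raw counts*: a Markov-random-field (MRF) prior over labels
   coupled to a negative-binomial observation model, fitted by
   expectation-maximization (EM), after which labels are renewed from the
   posterior.

## Stage 1: the pattern detector

**Pseudo-images.** The grid pitch is estimated as the median nearest-neighbor
distance; coordinates are shifted, pitch-normalized and rounded half away
from zero, mapping each spot to a pixel (several spots may share one).
Pixels with no spot form the background and carry the value 0 through every
stage. For pattern $r$ with marker set $M_r$, the channel value at a pixel is
the mean over its spots of the *median* denoised expression across $M_r$
(the median makes the fusion robust to one poor marker), followed by a 3×3
median filter restricted to tissue pixels.

**Segmentation.** Each channel is split into `n_thresholds` intensity
classes by multi-level Otsu thresholding (exact dynamic programming over a
256-bin histogram; the result provably equals exhaustive search). The top
class is the positive image. Cleaning then removes 8-connected components
smaller than `min_component_area`, and rejects false positives by exact 1-D
2-means over component mean intensities together with a negative anchor (the
largest component of the sub-threshold image); components clustering with the
anchor are dropped. The anchor guarantees two clusters even when only one
positive component exists. The surviving support is dilated with a discrete
disk (radius `dilation_radius`) and intersected with the tissue mask.

**Features and labels.** The feature channel is the raw channel masked by
the cleaned support, then unsharp-sharpened, Gaussian-smoothed and
TV-denoised at configurable strengths, and min-max rescaled to [0, 1]. When a
pattern has no markers (at most one may), an *undefined* channel
$F^{(u)} = \max(0,\, u - \bar F)$ is appended, where $\bar F$ is the mean
over pattern channels and $u$ is the uncertainty parameter. Every spot takes
the feature vector of its pixel and the label of the arg-max channel (ties to
the lowest index — a deterministic, documented rule).

**Detector parameters** (all in `detector_params()`):

| parameter | default | meaning |
|---|---|---|
| `n_thresholds` | 3 | Otsu classes (high/medium/low expression) |
| `min_component_area` | 2 | smallest surviving component, in pixels |
| `dilation_radius` | 2 | disk radius bridging small gaps, in pixels |
| `uncertainty` | 0.5 | undefined-channel score $u \in [0,1]$ |
| `sharpen_amount`, `sharpen_sigma` | 1, 1 | unsharp masking |
| `gaussian_sigma` | 0.5 | smoothing, in pixels |
| `tv_weight` | 0.02 | feature TV denoising strength |

**Hyperparameter search.** `autotune_detector()` scores a parameter set by
running the detector and building the *specificity matrix* $T$: entry
$(r, r')$ is the mean expression of pattern $r$'s initial markers among spots
labeled $r'$, min-max normalized within each row. The objective is the
Frobenius distance $\lVert T - I_R \rVert$ (0 for perfectly specific
markers), plus 1 for every pattern left without spots — the search must not
be rewarded for emptying a pattern, and the penalty keeps the objective
defined there. The built-in samplers are seeded random search and full grid
enumeration; ties go to the first-evaluated trial so results are
reproducible. Candidate markers for list expansion are ranked per pattern by
one-vs-rest Wilcoxon rank-sum z statistics (tie-corrected normal
approximation) on log-normalized counts.

## Stage 2: the Bayesian classifier

**Neighborhoods.** Each spot has transcriptomic neighbors (K = 15 nearest in
a 50-dimensional PCA embedding of the denoised matrix) and spatial neighbors
(k = 6 nearest by position, symmetrized by union). We use deterministic PCA
rather than a stochastic nonlinear embedding so that identical inputs give
identical graphs; any precomputed embedding can be injected. K = 15 is a
middle ground between very local (noisy label frequencies) and global
(diluted signal) neighborhoods.

**MRF prior.** The unary cost of label $r$ at spot $s$ mixes the
$\varepsilon$-smoothed frequencies of $r$ among the two neighbor sets:
$$\Phi(l_s = r) = -\big[\omega_1 \ln \hat p_U + (1-\omega_1) \ln \hat p_S\big],
\qquad \hat p = \frac{\#\{l_{s'} = r\} + \varepsilon}{|N| + \varepsilon R}.$$
The pairwise cost couples co-occurrence statistics with feature similarity:
$$\Psi(l_s = r, l_{s'} = r') = -\mathcal{D}(f_s, f_{s'}) \ln p_{rr'},\qquad
\mathcal{D} = \mathbf{1}\{r = r'\}\, e^{\lVert f_s - f_{s'}\rVert}
 + (1 - \mathbf{1}\{r = r'\})\,(1 + e^{-\lVert f_s - f_{s'}\rVert}),$$
so two spots that look identical on the feature image cost 2 to separate but
only 1 to keep together, while dissimilar spots are expensive to merge.
$p_{rr'}$ is the $\varepsilon$-smoothed joint frequency of neighbor label
pairs in the current annotation. Both components are min-max normalized over
the full (spot, pattern) table, combined as
$E = (1-\omega_2)\tilde\Phi + \omega_2\tilde\Psi \in [0,1]$, and converted to
a prior by a Gibbs distribution. We default to the Boltzmann orientation
$\pi_{sr} \propto e^{-\kappa E_{sr}}$ — the cost semantics of $\Phi$ and
$\Psi$ make low energy the preferred state — and expose the opposite sign
behind `gibbs_sign` for completeness, because the two orientations appear
inconsistently in the literature this model descends from and we prefer not
to guess silently. Defaults: $\omega_1, \omega_2$ initialize at 0.5 with the
recommended operating point (0.99, 0.01); $\kappa = 3$;
$\varepsilon = 10^{-2}$ (keeps every logarithm finite; the smoothing scale
matters only for labels absent from a neighborhood).

**Observation model.** Counts follow a spatial Poisson point process whose
Gamma-distributed intensity integrates to a negative binomial:
$$C_{gs} \mid l_s = r \sim \mathrm{NB}\big(\alpha_{gsr},\, \sigma_s \mu_{gsr}\big),
\qquad \mu_{gsr} = \beta^+_{gs} + \beta_{gr}\,\rho_{gr}\,\delta_{gr},$$
with $\sigma_s$ the library-ratio size factor, $\rho_{gr}$ the binary marker
indicator, $\beta_{gr}$ a fixed per-gene anchor, and $\delta_{gr} > 1$ the
overexpression factor. Only genes on the (expanded) marker list enter the
likelihood; the undefined pattern has $\rho \equiv 0$ and a baseline-only
mean. The inverse dispersion is a radial-basis expansion of the scaled mean,
$\alpha_{gsr} = \sum_{i=1}^{B} a_i e^{-b(\sigma_s\mu_{gsr} - x_i)^2}$
(B = 10 centers evenly spaced over the count range), clamped below at
$10^{-6}$ since free coefficients can drive the sum negative.

Three numerical/parameterization choices deserve explanation:

* *Positivity by reparameterization.* The baseline and overexpression are
  optimized on unconstrained scales through
  $\beta^+ = \mathrm{softplus}(\beta^{raw})$ and
  $\delta = 1 + \mathrm{softplus}(\delta^{raw})$, which keeps the NB mean
  valid and $\delta > 1$ without gradient clipping.
* *RBF width.* We read the width constant "twice the squared center spacing"
  as the Gaussian denominator, i.e. exponent coefficient
  $1/(2\,\Delta x^2)$ with $\Delta x$ the center spacing. Placing that
  constant as a multiplier instead would make adjacent basis functions
  essentially disjoint on count scales (α ≈ 0 between centers, always
  clamped), leaving the likelihood flat in the dispersion parameters.
* *Identifiability of $\delta$.* Two structural choices keep the
  overexpression factor meaningful rather than decorative. First, the anchor
  $\beta_{gr}$ defaults to the gene's tissue-wide mean raw count
  (`anchor = "tissue"`): an anchor computed from the pattern's own region —
  e.g. the skeleton average, available as `anchor = "skeleton"`, with
  skeletons computed by Zhang–Suen thinning of the pattern masks — already
  contains the elevation it is supposed to scale, which forces
  $\hat\delta \to 1$ for every gene regardless of the true fold. Second, the
  baseline is shared across spots per gene by default
  (`baseline = "gene"`); a free per-(gene, spot) baseline
  (`baseline = "spot"`) creates a flat likelihood valley in which own-pattern
  baselines absorb any marker elevation while residual off-pattern posterior
  mass pushes $\delta$ to its lower bound. With the defaults,
  $\hat\delta \approx \delta^{true} / (1 + \delta^{true}/R)$: compressed, but
  strictly increasing in the true fold, which is what rank-based downstream
  use needs. Per-spot scale differences are carried by the size factors.

**EM.** The E step is the exact posterior
$p_{sr} \propto \pi_{sr} \prod_g \mathrm{NB}(C_{gs})$, computed in log space
with per-spot max subtraction; a Dirichlet(0.01) hyper-prior enters as a
pseudocount on $\pi$. The M step runs Adam (learning rate 0.1) on the
expected complete-data objective with analytic gradients for
$\{\beta, \delta, a\}$. The prior field is a function of the initial
annotation and $(\omega_1, \omega_2)$; it is rebuilt during EM only when
$\omega$ is optimized (`update_omega`, off by default — a coarse grid over
both weights maximizing the expected log-prior). Convergence is declared
when the relative change of the evidence bound (expected complete-data
objective plus posterior entropy, the quantity EM is guaranteed not to
decrease) falls below `tol = 1e-4`; an absolute-scale mode is available via
`tol_mode`, since an absolute threshold is occasionally quoted for this
class of model but is dimensionally awkward — it depends on G, S and count
depth. The per-gene weighting of the prior terms inside the objective
follows the complete-data factorization over genes ("per-gene"); a
once-per-spot weighting is available via `prior_weighting`. The M step caps
at `max_inner = 200` Adam iterations with a relative-plateau stop at
$10^{-6}$: the objective is near-quadratic in the reparameterized
coordinates and plateaus within on the order of $10^2$ steps, so the large
iteration caps sometimes quoted for Adam are never binding; the cap is
configurable for pathological cases.

**Label renewal.** `"argmax"` takes the posterior mode per spot and
preserves fine detail (recommended for dispersed patterns and cell types).
`"imgbase"` rasterizes the posterior into a pattern-image stack and re-runs
the detector's segmentation stages on it, which suppresses salt-and-pepper
posterior noise and preserves the continuity of laminar structures; on noisy
posteriors it produces no more connected label fragments than arg-max (a
property the test suite checks by flood-fill counting).

## The synthetic-tissue generator

`simulate_tissue()` produces the study conditions every stage is tested
under: spots on an I×J grid partitioned into R patterns by one of three
layouts (laminar bands, mirroring layered cortex; concentric rings; dispersed
circular foci on a background), disjoint marker sets with own-pattern means
$\beta_g (1 + \delta^{true})$, log-normal per-gene baselines, NB counts with
inverse dispersion `alpha_true`, log-normal library-size factors, and
Bernoulli dropout. Defaults — 40×40 grid, R = 4, G = 200, 3 markers per
pattern, $\delta^{true} = 4$, $\alpha^{true} = 10$, baseline mean 1, dropout
0.05, library-size SD 0.2 — describe a clean mid-depth capture array:
fold-4 markers are strong but not trivial (detection from single spots is
unreliable; smoothing and the MRF matter), dropout and library variation are
mild. What the generator does **not** emulate: spatially smooth baseline
gradients within a pattern, bleed-over between adjacent spots, platform-
specific artifacts, segmentation errors at tissue boundaries, or markers
shared between patterns. Passing tests therefore demonstrate correctness of
the algorithms under the stated model, not performance on any particular
real tissue.

Test and check problem sizes are chosen to exercise each property at the
smallest scale where it is meaningful: oracle equivalences on ≤64×64 images
and ≤6-cluster tables where exhaustive search is exact; end-to-end recovery
on the default 40×40 laminar tissue; fold-change recovery at G = 100,
S = 1000, R = 4 over three seeds; moment checks at S = 2000 where standard
errors are tight.

## Degenerate inputs and tie-breaks

Constant expression rows min-max rescale to zero (no evidence) and return
`NaN` from Moran's I (excluded from ranking). Channels with fewer distinct
intensities than Otsu classes abort segmentation; inside the full detector
the channel then falls back to its raw support as mask and itself as
feature, so a re-run on near-one-hot posterior images cannot crash. An empty
negative image skips false-positive rejection with a warning; an empty
skeleton falls back to the pattern-wide mean, then the gene-wide mean. All
arg-max operations break ties toward the lowest index; the 2-means and
assignment solvers are exact and deterministic; every stochastic step
(initialization, sampling, search) flows from a single seed.

## Known limitations

* The detector assumes markers are *enriched*, not exclusive; heavy marker
  overlap between patterns degrades the specificity objective's guidance.
* The MRF prior is built from the initial annotation; a catastrophically
  wrong detector output can anchor the refinement (the EM sharpens, it does
  not restart).
* $\hat\delta$ is a compressed, rank-faithful estimate of the simulated
  fold, not an unbiased effect size.
* Runtime is dominated by the E/M array operations, which scale with
  G×S×R over marker genes; tens of thousands of spots are feasible, but the
  package targets desk-scale analyses and makes no attempt at batching or
  GPU execution.
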