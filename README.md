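# spotanno

Marker-guided semantic annotation of spatial transcriptomics spots.

Spatial transcriptomics assigns a gene-count vector to each barcoded capture
location ("spot") on a tissue section. The usual route to anatomy —
unsupervised clustering followed by manual cluster-to-structure matching —
is slow and irreproducible. `spotanno` is for analysts who already know
*which* structures they expect (cortical layers, tumor niches, cell-type
domains) and can name at least one marker gene per structure: it assigns
every spot to one of those named patterns directly.

## Method

Annotation runs in two stages.

**Pattern detector.** Spots are mapped to pixels (pitch-normalized
rounding), and each pattern's markers are fused (per-spot median, per-pixel
mean, 3×3 median filter) into a channel of a pseudo-image `P (I×J×R)`. Each
channel is segmented by exact multi-level Otsu thresholding; the top
intensity class is cleaned (small-component removal, 2-means false-positive
rejection against a negative anchor, disk dilation) into a mask `M⁽ʳ⁾⁺`,
from which a feature image `F` is extracted and post-processed. Spot `s`
gets feature vector `f_s` (its pixel of `F`, optionally with an undefined
channel `max(0, u − mean_r F)`) and initial label `argmax_r f_s`. A seeded
search can tune detector parameters against the marker specificity objective
`‖T − I_R‖` and the marker list is expanded by rank-sum statistics.

**Bayesian refinement.** On raw counts, spot labels get a high-order MRF
prior combining transcriptomic-kNN and spatial neighborhoods,

    Φ(l_s=r) = −[ω₁ ln p̂(r|N_U) + (1−ω₁) ln p̂(r|N_S)]
    Ψ(l_s=r, l_s'=r') = −D(f_s, f_s') ln p_rr',   E = (1−ω₂)Φ̃ + ω₂Ψ̃
    π_sr ∝ exp(−κ E_sr)

with counts modeled as `C_gs | l_s=r ~ NB(α_gsr, σ_s μ_gsr)`,
`μ_gsr = β⁺_gs + β_gr ρ_gr δ_gr` (δ > 1 the marker overexpression factor)
and `α` a radial-basis function of the scaled mean. EM alternates the exact
posterior with Adam updates of `{β, δ, a}`; final labels come from the
posterior argmax or, for laminar structures, from re-running the detector on
the posterior image (`renewal = "imgbase"`). A metric suite (Hungarian
mapping, ARI, ACC, macro P/R/F1, NMI, column-normalized confusion,
Jensen-Shannon divergence) and a synthetic-tissue generator with known
ground truth round out the package.

See `vignettes/annotation-model.Rmd` for the full model, parameter
reference, and design rationale.

## Worked example

```r
library(spotanno)

sim <- simulate_tissue(sim_config(I = 20, J = 20, R = 3, G = 60,
                                  markers_per_pattern = 2, seed = 7))
res <- annotate_spots(sim$counts, sim$coords, sim$markers, seed = 1)
res
#> <spotanno_result> 400 spots, patterns: P1, P2, P3
#>  P1  P2  P3
#> 120 139 141

annotation_metrics(res$spots$label, sim$truth$label)
#> # A tibble: 1 × 7
#>     ari   acc precision recall    f1   nmi     n
#>   <dbl> <dbl>     <dbl>  <dbl> <dbl> <dbl> <int>
#> 1 0.881  0.96     0.961  0.961 0.961 0.837   400

glance(res)
#> # A tibble: 1 × 6
#>   sweeps q_final n_spots n_genes n_patterns mean_max_posterior
#>    <int>   <dbl>   <int>   <int>      <int>              <dbl>
#> 1      5 -58320.     400      21          3              0.958
```

The simulated tissue has three laminar bands with two markers each; the
pipeline recovers them at ARI 0.88 / accuracy 0.96 against the generating
truth, using 21 likelihood genes (6 seeded markers plus rank-sum
expansions). `tidy(res)` returns the per-spot tibble with posteriors,
`tidy(res$fit)` the fitted per-marker overexpression factors, and
`autoplot(res)` draws the annotation. A command-line surface with
`simulate`, `detect`, `annotate`, `refine` and `evaluate` subcommands lives
at `inst/cli/spotanno.R`.

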