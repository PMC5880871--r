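# dcemoco

Motion correction for dynamic contrast-enhanced MRI (DCE-MRI) of the liver,
together with the landmark-based machinery needed to evaluate such
corrections on multi-case datasets.

A hepatic DCE-MRI exam acquires 4–5 volumes (native, arterial,
portal-venous, equilibrium, late-venous) under separate breath-holds, so the
liver sits in a slightly different respiratory state in every phase. Fusing
the phases — for per-voxel contrast dynamics, surgery planning or functional
analysis — requires registering the early phases onto a common target, here
the late-venous phase. The early phases are hard to register: the contrast
agent highlights different structures in every phase, so intensity-based
similarity measures fail and evaluation by visual alignment is misleading.

## Method

`dcemoco` implements a two-stage pairwise correction for each moving phase
*M* against the fixed late-venous phase *F*:

1. **Coarse liver segmentation** from contrast-agent accumulation: mean
   intensity projection over all phases, multiplication by a linear ramp
   that is maximal anterior-right (emphasizing liver over spleen),
   thresholding at the 90 % intensity quantile, morphological opening
   (10 mm), convex hull, dilation (5 mm).
2. **Rigid preregistration** (6 DOF, Nelder-Mead over a resolution pyramid)
   minimizing the *normalized gradient fields* (NGF) distance, with the
   distance evaluated only inside the liver mask. NGF compares local
   gradient directions and is therefore robust to contrast changes:

   D(F, M) = mean over x of  1 − (⟨∇F, ∇M⟩ + η²)² / ((‖∇F‖² + η²)(‖∇M‖² + η²))

   The edge parameter η suppresses low-gradient (noise) structures.
3. **Deformable registration** of a dense displacement field u on the fixed
   grid, minimizing

   J[u] = D(F, M ∘ (id + u)) + α · S[u] / V,   S[u] = ½ ∫ Σₗ (Δuₗ)² dx

   i.e. NGF plus curvature regularization (squared Laplacian of each
   displacement component), solved discretize-then-optimize with exact
   analytic gradients, L-BFGS, and a multi-level pyramid.

Variants: **FM** (full method), **RMwom** (unmasked preregistration),
**RMwop** (no preregistration).

The evaluation framework implements: a two-annotator annotation-scheme
planner (pair halving and swapping), confidence-interval sample sizing
N = ⌈(2·s/d)²⌉, landmark distances with the closest-of-two-annotators rule
(robust to gross "type B" mislabels), inter-observer distances, distribution
summaries (mean/median/min/q75/q90/q99/max), paired Wilcoxon signed-rank
comparisons, folding detection by splitting every grid cell into eight
equally sized corner tetrahedra and checking orientation reversal, time-cut
images (TCI) for qualitative review, and a two-stage (broad → focused)
grid search of (η, α).

Because no clinical data ship with the package, a synthetic phantom module
generates 5-phase abdominal series with known ground-truth motion,
tissue-specific enhancement curves, a ground-truth liver mask, and simulated
two-annotator landmark sets (small type-A noise plus occasional gross type-B
errors), so the entire pipeline is testable end to end.

## Worked example

```r
library(dcemoco)

# one synthetic case: 5 phases, known motion, two simulated annotators
case <- generate_phantom_case(phantom_config(seed = 7))
case$series
#> <dce_series> 5 phases (native, arterial, portal-venous, equilibrium,
#>  late-venous), fixed = late-venous

# full method: coarse liver segmentation, masked rigid, deformable NGF
res <- run_motion_correction(case$series, "FM")

# closest-of-two landmark distances before and after
lm <- case$landmarks
before <- landmark_distances(lm)
after <- unlist(lapply(names(res), function(p)
  landmark_distances(lm[lm$pair_id == p, ], res[[p]]$field)))
print(summarize_distances(before), digits = 3)
#>   mean median  min  q75  q90  q99  max  n
#> 1  8.7   8.62 3.85 10.7 11.9 12.4 12.4 40
print(summarize_distances(after), digits = 3)
#>   mean median   min  q75  q90  q99  max  n
#> 1 2.63    2.5 0.551 3.52 4.45 5.59 5.92 40

# deformation plausibility and annotation quality
sum(vapply(res, function(r) r$foldings, numeric(1)))
#> [1] 0
mean(inter_observer_distances(lm))
#> [1] 2.812537

# annotation-scheme sample sizing: pairs needed for a 95% CI of
# half-width d around the mean landmark distance
required_pairs(s_pooled = 1.9, d = ci_halfwidth(3.17))
#> [1] 23
```

The mean landmark distance drops from 8.7 mm to 2.6 mm on this case, the
deformation contains no folded tetrahedra (physically plausible), and the
simulated inter-observer distance (2.8 mm) stays below the typical clinical
voxel diagonal — the regime in which the closest-of-two evaluation is
meaningful.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/dce-mocomp.R phantom  --out data/ --n-cases 1 --seed 7
Rscript inst/cli/dce-mocomp.R register --series "p1.nii.gz,...,p5.nii.gz" --out reg/
Rscript inst/cli/dce-mocomp.R evaluate --landmarks landmarks.csv --fields reg/ --out table.csv
```

## Layout

- `R/`, `src/` — package code; compiled kernels for warping, NGF/curvature
  values and gradients, morphology, and folding detection.
- `tests/testthat/` — unit, property and end-to-end tests (all fixtures are
  generated in code).
- `vignettes/motion-correction-evaluation.Rmd` — the methods vignette:
  model, assumptions, parameter choices, what the phantom does and does not
  emulate, numerical choices, limitations.
- `inst/cli/dce-mocomp.R` — command-line front end.
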