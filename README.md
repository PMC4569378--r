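# handmorph

Surface registration, reproducibility analysis and statistical average shape
models for 3D scans of the human hand.

3D stereophotogrammetry can capture the surface of a hand in a fraction of a
second, without radiation. Before such scans can support clinical work in
hand surgery, two questions must be answered quantitatively: *how
reproducible is a repeat capture of the same hand* (subjects cannot keep
their fingers perfectly still between sessions), and *how should hands of
different people be brought into a common frame* so that an average hand —
and group contrasts such as male vs female — can be computed. `handmorph`
implements the full analysis for both questions, together with a parametric
articulated synthetic hand generator so that every stage can be exercised and
tested end to end without access to clinical scans.

## What it computes

**Rigid registration.** Corresponded point sets are superimposed with the
closed-form weighted least-squares (Kabsch) solution: with centred
coordinates, the rotation is `R = V diag(1, 1, det(VUᵀ)) Uᵀ` from the SVD
`UΣVᵀ` of the cross-covariance, which guarantees a proper rotation
(det R = +1). Surfaces are registered by iterative closest point (ICP):
alternate exact closest-point correspondences (source vertices onto the
target triangle mesh, accelerated by a uniform spatial grid whose results
equal the brute-force minimum) with a Kabsch update until the RMS
correspondence distance stabilises. No step anywhere estimates scale: hand
size is a finding, not a nuisance.

**Distance maps.** After registration, the per-vertex Euclidean distance
between the two surfaces (`dᵢ = min over target triangles`) forms an error
map, summarised by its absolute mean and 50th/90th percentiles in mm, for
the full hand and restricted to the palm region. Signed variants (positive =
outside the target surface) drive group comparisons.

**Groupwise landmark registration.** Cohorts of 24-landmark sets are
registered by two methods: *method 1*, generalized rigid Procrustes of the
complete landmark set (random reference, then the running average as
reference); *method 2*, an adapted ICP in which palm and each digit are
registered independently (Kabsch on the subregion's landmarks, refined by
surface ICP of the subregion's vertices), absorbing finger articulation.
The fitted `average_hand` model holds the mean configuration, per-landmark
covariances and variation ellipsoids with semi-axes `2·√eigenvalues` (two
standard deviations), plus a thin-plate-spline average surface. Model
precision is the pooled RMS landmark-to-mean distance; methods are compared
by a paired t-test on per-specimen RMS at the 5% level.

## Worked example

```r
library(handmorph)

# one synthetic hand, and a simulated repeat capture one week later
hand <- generate_hand(hand_params())
t1   <- simulate_repeat_acquisition(hand, acquisition_jitter(), seed = 2)

fit <- icp_register(t1$mesh, hand$mesh)
fit
#> ICP registration: rms 1.0045 mm after 22 iterations (converged)

reg <- apply_transform(fit$transform, t1$mesh)
summary(surface_distance_map(reg, hand$mesh))
#> Registration error (full, n = 1460): abs mean 0.50 mm, p50 0.17 mm, p90 1.47 mm
summary(surface_distance_map(reg, hand$mesh, regions = t1$regions, region = "palm"))
#> Registration error (palm, n = 830): abs mean 0.15 mm, p50 0.12 mm, p90 0.32 mm

# an average hand over a 10-subject synthetic cohort, both methods
cohort <- generate_cohort(n_per_sex = 5, seed = 3)
m1 <- average_hand(cohort, method = "procrustes", seed = 1)
m2 <- average_hand(cohort, method = "subregion",  seed = 1)
m2
#> Average hand model (subregion registration, 10 specimens, 2 passes)
#>   overall RMS error: 2.2288 mm
#>   mean largest ellipsoid semi-axis (2 sd): 3.826 mm
#>   average surface: 1839 vertices
paired_t_test(m1$run$per_specimen_rms, m2$run$per_specimen_rms)
#> Paired t-test: t = 6.5912, df = 9, p = 0.0001003, mean difference 1.0729 mm (significant at 5%)
```

Reading the output: the repeat capture differs from the first mostly at the
fingers (full-hand p90 1.47 mm) while the palm is nearly rigid (abs mean
0.15 mm) — the palm is the trustworthy region for longitudinal surface
comparisons. Registering palm and digits separately (method 2) roughly
halves the RMS of the average model relative to whole-hand Procrustes, and
the paired t-test confirms the improvement is systematic across specimens.

The full workflow — synthesis, repeat acquisitions, reproducibility
summaries, both averaging methods, the method comparison and the male/female
contrast — runs as one call:

```r
out <- run_pipeline(default_config(seed = 1))
out
```

## Documentation

The methods vignette (`vignettes/hand-shape-models.Rmd`) describes the
geometry of the synthetic hand, the registration algorithms and their
numerical choices, the statistical model behind the variation ellipsoids,
and the package's known limitations.
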