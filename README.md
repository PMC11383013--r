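# chanet

Connectivity hyperalignment (CHA) and its consequences for estimated brain
network topology, from the coarse parcel scale down to the vertex scale.

## The problem

Even after anatomical registration, the fine-grained functional topography
of the cortex differs across people: the vertex carrying a given signal in
one brain is not the same vertex in another.  Vertex-level quantities —
connectivity profiles, fine-scale graph metrics, features for predicting an
individual trait — are therefore not directly comparable across subjects.

CHA fixes this functionally rather than anatomically.  Each subject is
summarized by a **connectome** `C = cor(T, D)`: the Pearson correlations
between connectivity targets `T` (region-averaged time series of a
parcellation) and every vertex's time series in the data matrix `D`.
Column `v` of `C` is vertex `v`'s *connectivity profile*.  Local orthogonal
Procrustes transforms `R = argmin ||X R - Y||_F` (solved as `U V'` from the
SVD of `X'Y`) rotate each subject's vertex basis into a shared template
space — per region (**rCHA**) or per searchlight with aggregation into a
whole-cortex sparse mapper (**sCHA**).  Mappers fit on a training run are
applied to held-out runs, and the pipeline then asks what alignment does
to:

* the inter-subject correlation (ISC) of connectivity profiles,
* global/local graph metrics of density-thresholded networks at coarse
  (region × region) and fine (vertex × vertex within region) scales,
* multi-subject community structure via multilayer modularity with
  categorical interlayer coupling ω and resolution γ (allegiance,
  recruitment, integration),
* ridge prediction of a per-subject trait from fine-scale topological
  feature patterns, trained on run 1 and tested on the remaining runs,
  with a label-shuffle chance baseline.

Everything is exercised on synthetic multi-subject cohorts with known
ground truth (shared latent signal under subject-specific local orthogonal
misalignment, planted modules, trait-coupled fine-scale topology), so every
stage has an oracle.  See `vignettes/chanet-methods.Rmd` for the models,
conventions and design decisions.

## Worked example

Six simulated subjects whose region-level vertex bases are rotated by
unknown orthogonal transforms; rCHA is fit on run 1 and validated on the
held-out run 2:

```r
library(chanet)

cfg <- synth_config(n_subjects = 6, n_timepoints = 150, n_runs = 2,
                    n_regions = 4, vertices_per_region = 16,
                    noise_sd = 0.5, rotation_scope = "region",
                    trait_effect_size = 0, seed = 1)
cohort <- generate_cohort(cfg)
parc <- cohort$parcellation

connectomes <- function(run) lapply(cohort$timeseries, function(subj) {
  ts <- subj[[run]]
  make_connectome(ts, make_targets(ts, parc), zscore = TRUE)
})

mappers <- fit_rcha(connectomes(1), parc)          # fit on run 1
test <- connectomes(2)                             # validate on run 2
aligned <- lapply(seq_along(test), function(s)
  apply_mapper(mappers[[s]], test[[s]]))

round(c(isc_unaligned = isc_profiles(test)$mean,
        isc_aligned   = isc_profiles(aligned)$mean), 3)
#> isc_unaligned   isc_aligned
#>         0.182         0.602
```

The mean ISC of connectivity profiles on the held-out run rises from 0.182
to 0.602: the mappers learned on one run generalize, recovering the shared
functional space that the planted rotations had hidden.

## Analysis workflow

The `analysis/` scripts run the study end to end, each printing what it
found and writing tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | simulate the cohort, write it in plain-text formats |
| `02_connectomes_isc.R` | connectomes + baseline held-out-run ISC |
| `03_hyperalign.R` | fit rCHA/sCHA on run 1, validate ISC on run 2 |
| `04_network_metrics.R` | coarse/fine graph metrics, density sweep |
| `05_multilayer.R` | multilayer modularity, allegiance, recruitment/integration |
| `06_predict.R` | ridge trait prediction, chance baseline, condition comparison |

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_connectomes_isc.R && ...
```

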