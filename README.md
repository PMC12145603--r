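# osteosig

NMR-metabolomics marker discovery for mesenchymal stem cell
osteodifferentiation.

Human adipose-derived mesenchymal stem cells (hAMSC) committed to the
osteogenic lineage change their metabolism over a 21-day induction, both
inside the cells (endometabolome, measured in polar extracts) and in the
culture medium they condition (exometabolome, the metabolic
"footprint"). The practical obstacle to using those changes as markers
is donor-to-donor variability: a useful signature must move in the same
direction, at the same stage, in every donor. `osteosig` implements the
full discovery workflow for the standard design of 3 donors x 2 arms
(proliferating controls, CTR, vs osteoinduced, OI) sampled in triplicate
— cells on days 0/1/4/7/14/21, media on days 1/4/7/11/14/18/21 with
media exchanged at each media sampling.

The package provides, as composable functions:

- **Synthetic cohort generator** (`build_default_library()`,
  `simulate_cohort()`): ground-truth-annotated Lorentzian-multiplet
  spectra (or integral tables) reproducing the study design, donor
  confounders, media-exchange structure and stated effect magnitudes —
  so the entire pipeline is testable without any data download.
- **Preprocessing** (`reference_to_tsp()`, `align_segments()`,
  `exclude_regions()`, `normalize_total_area()`): TSP referencing,
  recursive segment-wise peak alignment, solvent-region exclusion,
  total-area normalization.
- **Media-exchange correction** (`correct_series()`,
  `correct_media_table()`): the blank-referenced recursion

  ```
  S[i,j]corr = mean(S[i-1]corr) + (S[i,j] - B[i-1]) / TA[i,j],   mean(S[0]corr) = 0
  ```

  turning repeatedly-exchanged media measurements into cumulative
  secretion (positive) / uptake (negative) trajectories, normalized by
  total spectral area TA as a cell-number proxy.
- **Quantification** (`integrate_windows()`, `compute_ratio()`): window
  integrals with exclusion-aware flags; marker ratios (Cho/PCho,
  Etn/PEtn, HTau/Tau).
- **Chemometrics** (`fit_pca()`, `fit_plsda()`, `vip()`): PCA and
  two-class NIPALS PLS-DA with unit-variance or centred scaling, VIP
  scores (mean square 1 by construction) and back-transformed loading
  weights.
- **Monte Carlo cross-validation** (`run_mccv()`,
  `progressive_timepoint_models()`): 7-block stratified random splits,
  500 iterations, training-only scaling and latent-variable selection;
  reports Q2 = 1 - PRESS/TSS, sensitivity, specificity and
  classification rate, plus model series excluding progressively earlier
  timepoints.
- **Marker screening and selection** (`screen_markers()`,
  `select_donor_independent()`, `spearman_map()`): percent-variation
  trajectories with exact Wilcoxon rank-sum p-values (complete
  enumeration up to 12 samples), explicit donor-independence rules
  (common sign across donors, pooled significance, magnitude floor), and
  thresholded Spearman correlation maps.
- **Pipeline runner** (`run_pipeline()`): end-to-end orchestration with
  a JSON manifest; a fixed config and seed reproduce every table byte
  for byte.

## Worked example

Simulate the default cohort, process both compartments, and ask the
screen which endometabolites behave donor-independently:

```r
library(osteosig)

lib <- build_default_library()
cohort <- simulate_cohort(lib, cohort_config(seed = 1))
tabs <- cohort_tables(cohort, lib)   # full spectral pipeline

sel <- select_donor_independent(screen_markers(tabs$cells))
sel
#>   metabolite direction final_pct_var
#> 1        Cho        up     130.19840
#> 2       PCho      down     -46.73335
#> 3        Etn        up     105.75914
#> 4 UDP-GlcNAc        up     148.34967
#> 5 UDP-GalNAc        up     121.50719
#> 6      U3.48        up      86.38212
#> 7        ADP      down     -51.68423
#> 8        PCr      down     -55.88776
#> 9         MG      down     -61.18030
```

The screen recovers exactly the nine planted endometabolites, with the
direction and day-21 magnitude of each (e.g. choline up ~130%, ADP down
~52% relative to same-day controls). Validating that signature as a
classifier on the late-stage samples:

```r
endo <- lib$signatures$endo_osteo$metabolite
cells <- tabs$cells
res <- run_mccv(as.matrix(cells[cells$day >= 14, endo]),
                cells$arm[cells$day >= 14],
                mccv_config(n_blocks = 7, n_iterations = 500, seed = 7))
res
#> <mccv_result> 500 iterations x 7 blocks, n = 34
#> pooled: sens 1.000  spec 1.000  CR 1.000  Q2 0.908
```

Every held-out day-14/day-21 sample across all 500 random partitions is
classified correctly (100% sensitivity, specificity and accuracy), with
strong predictive power (Q2 0.91). The same analysis for the
17-exometabolite media signature is one `screen_markers(tabs$media,
denom = "abs")` away.

## Further reading

The methods vignette (`vignettes/marker-discovery.Rmd`) documents the
model assumptions, the simulator's noise structure and what it does and
does not emulate, the media-correction interpretation, the selection
rules and their rationale, numerical tie-breaks and known limitations.
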