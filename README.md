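# mitoifc

Imaging flow cytometry (IFC) phenotyping of mitochondrial disease
fibroblasts in R.

Mitochondrial diseases are notoriously hard to classify: patients with the
same deficient OXPHOS complex — even the same variant — can show opposite
cellular phenotypes. `mitoifc` implements a multifaceted alternative: from
multi-channel single-cell IFC images of patient fibroblasts it quantifies
five mitochondrial features, normalizes each patient to the healthy control
measured in the same run, flags values outside healthy-donor reference
ranges, and clusters patients by their functional response (hypometabolic:
low membrane potential; hypermetabolic: raised membrane potential, swelling
and mass).

The five features, per cell:

| Feature | Dye / channel | Definition |
|---|---|---|
| Membrane potential | TMRM ± FCCP | ΔMMP = TMRM intensity (untreated) − TMRM intensity (FCCP-uncoupled background) |
| Mitochondrial mass | NAO (read under FCCP) | integrated NAO intensity, decoupled from potential |
| Swelling | TMRM | total TMRM-mask area (µm²) |
| Fission/fusion | TMRM bright-spot mask | form factor = perimeter² / (4π·area), medians over spots |
| ROS | MitoSox, DRAQ5 | MitoSox intensity over the cytoplasm with the (dilated) nuclear mask excluded |

Sample-level values are medians over gated cells (nucleated, in-focus,
singlet), expressed as percent of the in-run healthy control. The reference
interval of each feature is the min–max of six healthy donors' percentages;
values strictly outside it are "abnormal". Cohort structure is assessed by
Ward clustering on Euclidean distances of the five percentages (UMAP with 8
neighbors, min_dist 0.01 for visualization), with Welch tests per feature,
Mann–Whitney subgroup tests, Spearman feature–phenotype correlations and
Fisher's exact cluster–phenotype tests.

Because instrument data are proprietary, the package ships a synthetic-data
module with known ground truth at two levels: a cell renderer (tubular
mitochondria as dilated random-walk skeletons, nucleus, artifact injection
for doublets/defocus) and a cohort generator (paired patient/in-run-control
runs with shared run-level intensity scaling that cancels under
normalization, plus planted cluster effects).

## Worked example

```r
library(mitoifc)

res <- run_pipeline(pipeline_config(seed = 1, cohort = list(umap = FALSE)))
res
#> <ifc_pipeline_result> 74 donor measurements, 31 patients
#> any-feature detection: 100.0% of patients
#> <ifc_cohort> 31 donors, 5 features, k = 2 clusters
#> <ward_clustering> k = 2 (cluster 1: n=16, cluster 2: n=15)
#> Welch tests between clusters:
#>                 feature      t   df        p        q
#>  membrane_potential_pct -11.98 27.4 2.05e-12 1.02e-11
#>           mito_mass_pct  -7.86 28.9 1.16e-08 1.93e-08
#>            swelling_pct -11.16 26.9 1.38e-11 3.45e-11
#>         form_factor_pct  -2.43 22.4 2.33e-02 2.33e-02
#>                 ros_pct   4.42 28.7 1.30e-04 1.63e-04
```

The synthetic cohort plants 31 patients in two response groups; the pipeline
normalizes every donor to its in-run control, builds reference ranges from
six healthy donors, and Ward clustering with automatic k recovers the two
planted groups exactly (cluster 1: membrane potential down; cluster 2:
membrane potential, swelling and mass up — hence the negative t statistics
for those features and the positive one for ROS).

Per-cell image analysis works the same way from rendered (or TIFF-loaded)
events:

```r
p <- cell_phenotype_params(noise_sd = 0, tmrm_level = 500, tmrm_fccp_floor = 0.2)
pair <- list(untreated = render_cell(p), fccp = render_cell(p, "fccp"))
feats <- extract_features(list(pair))
delta_mmp(feats$tmrm_pixel_mean, feats$tmrm_pixel_mean_fccp)
#> [1] 400        # = 500 * (1 - 0.2), the planted uncoupling response
```

See `vignette sources in vignettes/` for the model, parameter and design
discussion.

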