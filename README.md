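# tdpquant

Single-cell image quantification of TDP-43 assembly phenotypes and FRAP
mobility, for two-channel fluorescence microscopy of TDP-43 reporter
lines (endogenous TDP-43-mCherry × over-expressed TDP-43-GFP variants).

Nuclear clearance of TDP-43 and its aggregation are central to ALS/FTD
pathology. In reporter cells, over-expressed TDP-43 variants form three
kinds of assemblies — droplet-like **puncta** (0.5–2.5 µm), shell-like
**anisosomes** (~1–4 µm rings with a TDP-43-void core) and large
saturated **inclusions** (> 4 µm) — which can *sequester* the endogenous
nuclear pool: the diffuse nuclear signal drops while total cellular
TDP-43 is conserved. `tdpquant` measures this per cell:

* **Segmentation** — Otsu-based nucleus detection robust to
  phenotype-driven nuclear depletion, seeded Voronoi cell growing
  (EBImage), and assembly detection as hole-filled components above 25%
  of detector saturation.
* **Classification** — the published decision rules: inclusion if
  equivalent diameter ≥ 4 µm and max intensity ≥ 60% of saturation;
  otherwise anisosome vs punctum on 0.5–4 µm objects by core/rim
  intensity ratio (≤ 0.5 → anisosome).
* **Sequestration quantification** — per-cell partition of nuclear
  endogenous signal into diffuse and sequestered pools with the exact
  conservation identity `diffuse + nuclear sequestered = nuclear total`;
  assemblies are flagged as sequestering when their mean endogenous
  intensity exceeds the lower quartile of diffuse nuclear signal in
  GFP-only control cells; per-cell OLS regressions of depletion and
  sequestration against expression level.
* **FRAP** — EasyFRAP-style double normalization
  `I_dn(t) = [mean_pre(ref−bg)/(ref−bg)] · [(roi−bg)/mean_pre(roi−bg)]`,
  single-exponential recovery fit, and the four mobility metrics: mobile
  fraction `100·(I_max − I0)/(1 − I0)`, AUC over the 120-s window,
  maximal recovery, and t½ (interpolated, cross-checked against ln2/k).
* **Densitometry** — total-protein-normalized CRISPR editing ratios
  (tagged 72/74 kDa over all TDP-43 bands; 1.0 = all alleles tagged).
* **Synthetic data** — a ground-truthed scene and FRAP-trace generator
  (`render_scene()`, `render_frap_trace()`) emulating every phenotype the
  analysis must quantify, so the full pipeline is testable without
  microscope data.

## Worked example

Simulate a control well, a mock (untransfected) well and an
anisosome-forming 2KQ well, then run the whole pipeline:

```r
library(tdpquant)

conds <- list(
  control = list(scene_config(n_cells = 12, variant = "GFP_only")),
  mock    = list(scene_config(n_cells = 12, variant = "GFP_only",
                              transfection_fraction = 0)),
  KQ2     = list(scene_config(n_cells = 12, variant = "2KQ")))
res <- run_pipeline(conds, mock = "mock", seed = 1)

res$control_reference$control_diffuse_Q1
#> [1] 9448.879
subset(res$image_summaries, condition == "KQ2")[
  , c("puncta_per_cell", "mean_area_anisosome_um2", "pct_puncta_sequestering")]
#>       puncta_per_cell mean_area_anisosome_um2 pct_puncta_sequestering
#> KQ2_1        15.83333                 1.67903                98.94737
res$regressions$KQ2$diffuse
#> OLS: slope -0.0001836, intercept 1.326, r^2 0.710, n = 9
res$regressions$KQ2$sequestered
#> OLS: slope 8769, intercept -8.815e+06, r^2 0.958, n = 9
```

The control reference gives the sequestration cutoff (lower-quartile
diffuse nuclear intensity of control cells, here ~9449 on the 16-bit
scale). In the 2KQ condition nearly every shell sequesters endogenous
TDP-43 (98.9%), the diffuse nuclear fold-change falls with expression
(negative slope) and the sequestered signal rises with it (positive
slope, r² 0.96) — the concentration-dependent nuclear depletion the
assay is built to detect.

FRAP and densitometry run standalone:

```r
tr <- render_frap_trace(frap_sim_config(post_bleach_floor = 0.3,
        plateau = 0.8, half_time_s = 12, noise_sd = 0.02, seed = 7))
compute_metrics(normalize_trace(tr))
#> FRAP metrics: m.f. 72.6%, AUC 89.1 a.u., max recovery 0.815, t1/2 13.3 s

lane <- data.frame(band_label = c("tagged_72_74kDa", "untagged_43kDa"),
                   signal = c(9.1, 0))
editing_ratio(lane, total_protein_signal = 20)
#> [1] 1
```

A mobile fraction of ~73% with t½ ≈ 13 s describes a highly dynamic,
liquid-like pool; an editing ratio of 1.0 means every allele carries the
knock-in tag.

Batch processing of TIFFs from the shell:

```sh
Rscript inst/scripts/run-pipeline.R --config run.yaml --out results/
```

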