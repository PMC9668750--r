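# perturbmap

Cell-type and spatial prioritization of perturbation responses in
transcriptomics data.

## What it does, and for whom

Given single-cell/nucleus or spatial transcriptomics data from **two
experimental conditions** (e.g. treated vs untreated tissue), `perturbmap`
ranks *units* of the data by how strongly they responded — where a unit is
either an annotated **cell type** or a **spatial location**. The ranking
statistic is transcriptional separability: the cross-validated AUC of a
random-forest classifier predicting the condition from expression,

```
AUC = 0.5  → conditions locally indistinguishable (no response)
AUC → 1    → conditions fully separable (profound response)
```

* **Cell types**: per cell type, 50 balanced subsamples of 20 cells per
  condition; per subsample, variable-feature selection then a 3-fold
  cross-validated random-forest AUC; the mean ranks the cell types.
  Fixed-size subsampling makes scores comparable between rare and abundant
  populations. RNA-velocity matrices are accepted in place of counts.
* **Spatial locations**: per barcode, the k = 20 nearest neighbours *from
  each condition* in the common coordinate frame form a 40-barcode window;
  stratified 3-fold CV, repeated 50 times, yields the barcode's AUC. Sliding
  the window over all barcodes gives an AUC map of the tissue.

The package also ships the validation machinery: a gamma-Poisson spatial
simulator with ground-truth DE intensity fields (sharp border, linear
gradient, radial focus, graded foci, ring, null), two-dimensional locally
weighted (loess-style) smoothing of AUC maps, recovery scoring against
ground truth, readers/writers for Matrix Market triplets and positions
tables, QC filters, and a command-line interface.

It is aimed at analysts of perturbation studies — injury models,
stimulation, disease vs control — who need to know *which cells* and *which
regions* to look at before any gene-level analysis.

## Worked example

Simulate a sharp-border perturbation (10% of genes differentially expressed
on one half of the tissue), then map separability over space:

```r
library(perturbmap)

params <- splat_params(n_genes = 400, n_barcodes = 300, de_prob = 0.10,
                       de_fac_loc = 1.0, seed = 42)
ds <- simulate_spatial_pattern("half_border", params)

features <- normalize_log1p_cpm(ds$counts)
map <- prioritize_map(features, ds$coords, ds$conditions,
                      magellan_params(k = 10, n_repeats = 10, rng_seed = 1))
print(map)
#> Spatial prioritization: A vs B
#>  300 barcodes scored, 0 skipped; k = 10
#> mean AUC: 0.742  range: 0.24 - 1

perturbed <- ds$truth_barcodes$intensity > 0.5
mean(map$scores$mean_auc[!perturbed])   #> 0.526
mean(map$scores$mean_auc[perturbed])    #> 0.961

print(recovery_score(map, ds$truth_barcodes))
#> Recovery report
#>   spearman vs truth: 0.882
#>   detection AUROC: 0.995
#>   grand-mean AUC: 0.742
#>   recovered: TRUE
```

Reading: the unperturbed half sits at the null value (~0.5), the perturbed
half approaches 1, and thresholding recovers the true region almost
perfectly (detection AUROC 0.995). Individual null barcodes wobble (range
down to 0.24 — a 40-cell window has a wide null band; see the methods
vignette), which is why maps are read smoothed:

```r
sm <- loess_smooth_2d(map$scores[, c("x", "y")], map$scores$mean_auc)
```

Cell-type mode works the same way from a metadata table:

```r
res <- prioritize_cell_types(features, meta, comparison = c("A", "B"),
                             params = augur_params())
scale_scores(list(comparison1 = res))   # min-max scaled per comparison
```

## Command line

```sh
perturbmap simulate --pattern half_border --n-barcodes 5000 --n-genes 1000 \
    --de-prob 0.10 --de-fac-loc 1.0 --seed 1 --out sim/
perturbmap prioritize-spatial --counts-dir sim/ --positions sim/positions.tsv \
    --condition-a A --condition-b B -k 20 --repeats 50 --seed 7 \
    --mirror-x --out map.tsv
perturbmap smooth --scores map.tsv --out smoothed.tsv
perturbmap evaluate --scores map.tsv --truth sim/truth_barcodes.tsv \
    --out report.json
perturbmap validate-suite --scaled-down --seed 1 --out suite/
```

The launcher lives at `inst/cli/perturbmap` (on the library path after
install: `system.file("cli", "perturbmap", package = "perturbmap")`); every
run writes a provenance JSON with parameters, seed, and input hashes.

## Documentation

The methods vignette (`vignettes/perturbmap-methods.Rmd`) describes the
model, its parameters and defaults, the simulator's scope, numerical
choices, and known limitations.
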