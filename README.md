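# noriq

Quantitative histology with **normalized stimulated Raman imaging (NoRI)**
of kidney tissue, for microscopists and computational biologists who need
absolute protein/lipid/water concentrations from label-free imagery — and a
fully synthetic, ground-truthed way to validate every stage of that
analysis.

NoRI records stimulated Raman scattering at three bands — 2853 cm⁻¹ (CH₂,
lipid), 2935 cm⁻¹ (CH₃, protein) and 3420 cm⁻¹ (OH, water). Per pixel the
intensities follow

```
I(x) = A(x) · S · c(x) + ε
```

with `S` the 3×3 reference-spectra matrix, `c(x)` the component
concentrations and `A(x)` an unknown attenuation factor from light
scattering in thick tissue. Unmixing solves `S·c = I` (nonnegative least
squares under noise) and the NoRI normalization

```
ĉ_k = ρ_total · c_k / (c_protein + c_lipid + c_water),   ρ_total = 1000 mg/mL
```

cancels `A(x)` exactly, yielding absolute concentrations in mg/mL.

The package provides:

* **`phantom`** — a synthetic kidney-tissue generator: annular tubules
  (proximal / distal / collecting duct) with lumen, brush border, nuclei,
  nucleoli, lipid droplets and interstitial microvasculature, filled from
  published per-structure concentration priors (e.g. proximal cytoplasm
  194.3 ± 18.4 protein, 52.2 ± 9.5 lipid mg/mL), plus a forward imaging
  model with a smooth attenuation field and sensor noise.
* **`nori` core** — `unmix()`, `nori_normalize()`, the per-image
  "non-quantitative" comparator `denormalize_per_image()`.
* **segmentation & metrics** — a deterministic classical tubule segmenter,
  `dice()`, and `mean_average_precision()` (greedy IoU matching, 101-point
  AP).
* **quantification** — cytoplasm-by-subtraction, per-tubule feature tables,
  interstitial protein, cortex→medulla trends.
* **cluster detection** — single-linkage agglomeration of thresholded
  pixels (5-px Euclidean cutoff, 75-px minimum cluster) for lumens and
  lipid droplets, with droplet morphometry.
* **stats** — Kruskal–Wallis + Dunn, Mann–Whitney U, Kolmogorov–Smirnov,
  two-way ANOVA + Bonferroni, Cohen's d.
* **classify** — tile extraction, multinomial feature classifiers,
  macro-F1.
* **pipeline** — `run_all()` orchestrating everything from one seeded
  config, with TIFF/YAML artifacts and a run manifest.

## Worked example

```r
library(noriq)

gt    <- sample_tissue_layout(phantom_config(side = 256, n_tubules = 6), seed = 7)
gt    <- fill_concentrations(gt, default_priors(), seed = 8)
stack <- forward_srs(gt, nori_spectra(), noise_frac = 0.01, seed = 9)
conc  <- nori_concentrations(stack)
print(conc)
#> concentration_stack: 256x256 px (0.414 um/px), rho_total 1000 mg/mL
#>   protein mean    84.6  range [0.0, 257.0] mg/mL
#>   lipid   mean    27.5  range [0.0, 77.6] mg/mL
#>   water   mean   887.9  range [703.6, 1000.0] mg/mL

tab <- tubule_feature_table(conc, as_mask_set(gt), gt = gt)
round(tab[, c("tubule_id", "cytoplasm_protein", "cytoplasm_lipid",
              "nuclear_protein", "nuclei_area_fraction")], 2)
#>   tubule_id cytoplasm_protein cytoplasm_lipid nuclear_protein nuclei_area_fraction
#> 1         1            129.42           32.95          131.17                 0.14
#> 2         2            180.11           55.12          196.85                 0.14
#> 3         3            217.96           52.15          145.63                 0.13
#> 4         4            221.92           61.55          183.19                 0.13
#> 5         5            200.90           46.28          152.93                 0.10
#> 6         6            159.60           35.55          153.45                 0.20

microvasculature_protein(conc, as_mask_set(gt))
#> [1] 75.25939
```

The image holds four proximal tubules and two collecting ducts: even
through a 0.4–1.0 attenuation field and 1% sensor noise, each tubule's
measured cytoplasmic protein matches its generating draw to fractions of a
mg/mL (proximal draws scatter around 194.3, collecting ducts around 138.5),
the nuclear area fractions scatter around the 12.9% prior, and the
interstitial protein recovers the per-image draw (here 75.3 mg/mL against a
77.2 ± 22.3 prior). Detection works the same way:

```r
det <- detect_droplets(conc, gt$tubule_labels > 0 & !gt$masks$lumen &
                         !gt$masks$nuclei & !gt$masks$brush_border)
droplet_morphometry(det, conc)   # per-droplet size (px, um^3) and mean lipid
```

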