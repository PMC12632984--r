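---
title: "Quantitative NoRI histology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative NoRI histology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noriq)
```

## The measurement model

Normalized Raman imaging (NoRI) acquires stimulated Raman scattering images
at three vibrational bands — 2853 cm⁻¹ (CH₂, lipid-dominant), 2935 cm⁻¹
(CH₃, protein-dominant) and 3420 cm⁻¹ (OH, water). At every pixel the
recorded intensity vector is modelled as

$$ I(x) \;=\; A(x)\, S\, c(x) \;+\; \varepsilon, $$

where $S$ is the 3×3 reference-spectra matrix (band × component), $c(x) =
(c_\text{prot}, c_\text{lip}, c_\text{wat})$ the component concentrations,
$A(x) \in (0,1]$ a per-pixel attenuation factor produced by heterogeneous
light scattering in thick tissue, and $\varepsilon$ additive sensor noise.
Unmixing solves $S c = I$ per pixel (closed-form inverse; exact 3-variable
nonnegative least squares by support enumeration when noise pushes a
component negative). Normalization then maps components to absolute
concentrations:

$$ \hat c_k(x) \;=\; \rho_\text{total}\,
   \frac{c_k(x)}{c_\text{prot}(x)+c_\text{lip}(x)+c_\text{wat}(x)}. $$

Because $A(x)$ multiplies all three bands equally, it cancels exactly in the
ratio — this attenuation invariance is the core of the method and is tested
with random positive per-pixel fields. In the noiseless case the whole chain
is exact to numerical precision (< 0.1 mg/mL round-trip error is asserted;
the observed error is ~1e-13).

Key constants:

* `rho_total = 1000` mg/mL — the total mass density every tissue pixel is
  normalized to (water-dominated soft tissue); configurable, and recorded in
  all output metadata.
* The default reference matrix (rows 2853/2935/3420, columns
  protein/lipid/water) is `[0.30, 1.00, 0.05; 1.00, 0.45, 0.10;
  0.05, 0.02, 1.00]` — a diagonal-dominant stand-in with condition number
  ≈ 2.9 reflecting CH₃-dominant protein, CH₂-dominant lipid and OH-dominant
  water responses. Real instruments measure $S$ from calibration standards
  (BSA, DOPC, water); no published values were available, so this synthetic
  default is clearly labelled as such and fully configurable.
* Dark-offset subtraction and the nonnegativity constraint are both
  config-exposed (`nonneg` in `unmix()`), since acquisition pipelines differ
  on both.

## What the phantom generator emulates

Real NoRI kidney data are not redistributable at desk scale, so every stage
is validated against a synthetic tissue phantom with known ground truth:

* **Geometry.** Annular tubule cross-sections (outer radius 18–26 px at
  0.414 µm/px) with a central lumen (42% of the outer radius), a 2-px brush
  border lining proximal-tubule lumens, 1–3 elliptical nuclei per tubule
  each holding 0–2 nucleoli, Poisson-distributed circular lipid droplets in
  the cytoplasm, and inter-tubule space labelled interstitial
  microvasculature. Substructure masks are pairwise disjoint and contained
  in their tubule's footprint (the nuclear *envelope* is nuclei ∪ nucleoli).
* **Composition.** Each structure in each tubule draws one
  (protein, lipid) pair from Gaussian priors truncated at zero and constant
  across the structure; water fills the remainder to `rho_total`, so
  conservation holds exactly by construction. Lipid droplets draw one pair
  *per droplet*, because the droplet statistics of interest (e.g.
  76.8 ± 25.8 mg/mL after day-2 ischemia) are across-droplet distributions.
  The default priors encode measured healthy-kidney values: proximal
  cytoplasm 194.3 ± 18.4 protein / 52.2 ± 9.5 lipid, distal 170.8 ± 16.1 /
  62.4 ± 10.3, collecting duct 138.5 ± 19.7 / 40.2 ± 13.1 mg/mL; nuclear
  protein 166.8 / 130.7 / 134.7 mg/mL with negligible nuclear lipid;
  region-dependent interstitial protein (77.2–100.5 mg/mL) and droplet
  lipid (66.5–84.7 mg/mL); sex-specific proximal cytoplasm protein
  (female 256.9 ± 6.9, male 245.5 ± 3.2 mg/mL).
* **Nuclear area.** The per-tubule nuclear area fraction is drawn from
  12.9 ± 4.7% (clamped to [0.02, 0.35]) and realized *exactly*: the nuclei
  are rasterized as the `round(f × area)` smallest values of an elliptical
  quadratic form inside the epithelial ring, so the measured fraction equals
  the drawn fraction to rounding and its recovery is unbiased.
* **Priors the source did not print.** Healthy luminal protein defaults to
  15 ± 8 mg/mL — lumens carry dilute tubular fluid; the printed luminal
  values (30.8→39.9 mg/mL) describe pathological protein plugs after
  ischemia-reperfusion injury and are available through
  `set_prior(priors, "lumen", ...)` for injury phantoms. Brush border uses
  the closest printed values (protein ≈ 125, lipid 35.4 ± 11.2 mg/mL);
  droplet protein (30 ± 10) and nucleolus composition (210 ± 25 protein)
  are plausible defaults.
* **Imaging.** The attenuation field is Gaussian-smoothed uniform noise
  rescaled to [0.4, 1] with a 32-px smoothness length — super-cellular-scale
  heterogeneity typical of thick-tissue scattering. Sensor noise is additive
  Gaussian, specified either absolutely or as a fraction of the mean band
  intensity (recovery experiments use 1%).

What the phantom does **not** emulate: intra-structure concentration
texture (structures are piecewise constant, which keeps recovery targets
exact), out-of-focus light and 3-D sectioning, immunofluorescence channels,
irregular tubule shapes, and spatially correlated noise. Passing tests
therefore demonstrate correctness of the *computation* under the stated
generative model, not segmentation or classification performance on real
tissue.

## Segmentation and its evaluation

The learned segmentation models used on real data (SAM/YOLO/U-Net) require
trained weights and GPUs; the package ships a deterministic classical
stand-in so the *evaluation* layer (Dice, mAP, predicted-vs-truth
quantification) is fully exercised. The classical segmenter thresholds
total biomass (protein + lipid), fills enclosed holes, splits touching
instances by distance-transform watershed, and discards instances under an
area minimum. The foreground threshold is the background (interstitial)
median plus `max(4 × MAD, 20 mg/mL)`: a histogram-optimal two-class split
is biased here because the interstitium dominates the pixel count while
tubule biomass varies widely across types, which can push the optimum
inside the tubule mode and lose dim collecting ducts. The absolute 20
mg/mL floor is meaningful only because the data are absolutely calibrated.
This rule assumes the interstitium is the majority background, which holds
for the default layouts.

mAP uses greedy IoU matching with predictions ranked by instance area (the
classical segmenter yields no learned confidence), ties broken by lowest
label for determinism, and 101-point interpolated average precision — the
common modern convention; the matching is verified against an exhaustive
maximum-matching oracle on small cases.

## Lumen and lipid-droplet detection

Both detectors follow the stated clustering procedure: candidate pixels
pass an intensity threshold, are agglomerated by single-linkage hierarchical
clustering cut at a Euclidean distance of 5 px, and clusters under 75 px are
discarded. Single linkage is chosen because a distance cutoff then has exact
connected-components semantics, implemented by hashed integer-offset
neighbour lookup and verified against a brute-force all-pairs union-find.
The ≤-threshold convention is used (pixels exactly 5 px apart join).

* **Lumens** are low-intensity clusters on the max-projection of the
  protein and lipid planes (water is near-constant in tissue and would
  erase contrast; the instrument's extra fluorescence channels are not
  modelled). The default threshold is an absolute, predefined 40 mg/mL,
  sitting between luminal protein (15 ± 8) and droplet lipid (66.5 ± 15.6);
  absolute thresholds are transferable across images precisely because the
  data are quantitative. A fraction-of-median mode is available. Clusters
  with mean lipid above 20 mg/mL are discarded as droplets (luminal fluid
  is lipid-poor). A droplet abutting the lumen can still merge into the
  lumen cluster through single linkage, which bounds pixel precision
  slightly below 1 on dense phantoms.
* **Droplets** default to *low-protein* clustering (below half the region's
  median protein): droplets are protein-poor, and this low-intensity
  reading keeps detection independent of each droplet's lipid content, so
  recovered droplet-lipid statistics are unbiased. The alternative
  high-lipid direction (above the region mean + 2 SD on the lipid plane) is
  implemented as a mode, but it truncates the droplet lipid distribution at
  the threshold and upward-biases recovered means — the reason it is not
  the default.

## Statistics

`kruskal_dunn()` wraps the tie-corrected Kruskal–Wallis H and adds Dunn's
pairwise z tests (tie-corrected rank variance) with a Bonferroni-family
adjustment — chosen explicitly since only "Dunn's post-hoc" is specified.
`mann_whitney()` uses the exact enumeration null when both n ≤ 8 without
ties, otherwise the tie- and continuity-corrected normal approximation.
Cohen's d uses the df-weighted pooled SD. The two-way ANOVA is fixed
effects; balanced designs use the standard decomposition and unbalanced
ones type-II sums of squares, with Bonferroni-corrected pairwise cell
contrasts. A repeated-measures structure is mentioned in the source's
figure legends but never defined (what repeats within what), so the model
here is deliberately plain two-way fixed effects. All tests are calibrated
against 2000-replicate null simulations (type-I error at α = 0.05 within a
3σ binomial band; exact variants may be conservative but never
anti-conservative).

## Classification

The CNN stage of the original workflow (ResNet50, Grad-CAM, UMAP) is out of
scope; a multinomial logistic classifier on tubule-feature tables or
fixed tile summaries preserves the evaluation surface: macro-F1
(unweighted mean over classes of 2/(precision⁻¹ + recall⁻¹)), the tile-size
sweep (40–320 px ≈ 16.5–132.5 µm sides at 0.414 µm/px), and the
quantitative-versus-per-image-normalized ablation. Its absolute scores are
*not* comparable to the published CNN scores and are never asserted against
them. Splits are stratified 70/30 (fractions unstated in the source;
a standard choice) and fully seeded. When rows are tiles sampled from
shared images or tubules, the split must be grouped (`group_col`):
otherwise a per-image fingerprint leaks between train and validation and
inflates the non-quantitative comparator. The ablation fixture — images
differing only by a global +45 mg/mL protein shift — shows the designed
contrast: quantitative inputs retain the shift, per-image min/max
normalization destroys it by construction.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; one pipeline seed fans out to per-image, per-stage
  seeds as `(seed mod 20000) × 100000 + image × 10 + stage`, keeping all
  derived seeds below 2³¹ and collision-free.
* Unmixing refuses reference matrices above a condition-number bound
  (default 100) and inputs containing NaN bands; degenerate component sums
  (≤ 10⁻⁶ × `rho_total`) are flagged invalid, excluded, and counted, never
  silently zeroed. Structures with no pixels are reported as missing (`NA`),
  never as 0, so they cannot drag group statistics.
* Truncated draws re-sample; a truncation rate above 1% raises a warning
  (the day-2 droplet priors legitimately trigger it at ≈ 3%).
* Concentration TIFFs are stored as 32-bit floats scaled by `rho_total`
  with YAML sidecars carrying units and scale, since the TIFF writer clips
  outside [0, 1].

## Problem sizes

Recovery experiments use 500 tubules (250 per sex group, 300 droplets, 50
images for the interstitial summary) spread over 512-px images of 24
tubules each — the sample sizes at which the recovered means are compared
to the generating priors within 3·SEM. Unit tests run on 160–448 px
phantoms with 1–12 tubules. These sizes were chosen so the full suite and
the recovery runs each complete in a few minutes on a single CPU while
keeping 3·SEM tolerances tight enough to detect a ~1% bias in the
proximal-protein chain.

## Known limitations

* The reference spectra, attenuation statistics, and several minor priors
  are synthetic stand-ins; parameter recovery shows self-consistency of the
  computation, not instrument calibration.
* The classical segmenter is a stand-in for learned models and will not
  match their robustness on real, textured tissue.
* Detection thresholds are tuned to the phantom's contrast structure; real
  data would require re-examining them (they are all config-exposed).
* 2-D planes only; the source images optical sections of thick tissue, and
  glomeruli (hand-segmented in the original workflow) are out of scope.
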