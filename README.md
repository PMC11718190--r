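# mitocox

Quantification of mitochondrial oxidative-phosphorylation status and 3D
morphology from COX-reacted serial block-face SEM (SBF-SEM) stacks of
skeletal muscle.

## The problem

Cytochrome c oxidase (COX) histochemistry deposits an electron-dense
precipitate in proportion to enzyme activity, so in an 8-bit SBF-SEM stack a
mitochondrion's gray level is a functional readout: 0 = black = high COX
activity, 255 = white = none. Given a co-registered instance segmentation,
every mitochondrion in a muscle fibre yields both a COX measurement and a
full 3D morphology. `mitocox` implements the analysis layer for people
studying mitochondrial disease (e.g. mtDNA-deletion myopathies, where COX
deficiency is mosaic across and segmental within fibres):

- dataset-wide slice normalization of intensity stacks (multi-page TIFF in/out);
- per-mitochondrion mean COX intensity and precipitate fraction below the
  threshold τ = 50;
- 3D morphometrics per label: volume `V`, surface area `SA` (volume-matched
  marching-tetrahedra isosurface), mitochondrial complexity index
  `MCI = ((SA^1.5)/(4πV))^2` (sphere minimum `9/(4π) ≈ 0.716`), Wadell
  sphericity `Ψ = π^(1/3)(6V)^(2/3)/SA`, centroid;
- unsupervised COX classification: a 3-component Gaussian mixture on mean
  intensities (EM, 20 restarts) whose weighted-density intersections `t1 < t2`
  split mitochondria into COX-normal / -intermediate / -deficient; fibres
  classified by the > 50 % majority rule;
- fibre mitotypes (mean ± SEM intensity vs MCI), 3D class maps, and a
  k-nearest-neighbour class-concordance permutation test for spatial
  segregation within fibres;
- group statistics: Kruskal–Wallis / Mann–Whitney with the two-stage
  Benjamini–Krieger–Yekutieli FDR, PLS-DA with VIP scores, and
  Ward/Euclidean clustering of fibre morphology summaries.

Patient EM volumes of this kind are not redistributable, so the package
ships a phantom generator (`phantom_spec()` / `generate_phantom()`) that
synthesizes fibre ROIs with planted geometry, intensity mixture, class
composition and spatial pattern; all pipeline stages are scored against that
truth. See the vignette (`vignettes/cox-sbfsem-pipeline.Rmd`) for the model,
parameter defaults and their rationale.

## Worked example

```r
library(mitocox)

res <- run_pipeline(run_config(seed = 1))   # default 12-fibre phantom cohort
print(res$mixture)
#> 3-component Gaussian mixture on COX intensity (n = 1829 )
#>     component    weight      mean       sd
#>        normal 0.3342710  55.03869 12.30245
#>  intermediate 0.3346069 120.95117 18.06802
#>     deficient 0.3311222 198.40592 13.72994
#> thresholds: t1 = 83.021, t2 = 164.119; logLik = -9417.02
```

The three fitted components are the planted COX classes on the normalized
intensity scale (dark → light = active → inactive), and the two intersection
thresholds classify every mitochondrion. Scoring against the planted truth:
98.5 % of 1829 mitochondria and 12/12 fibres recover their planted class;
95.7 % of COX-deficient mitochondria are spherical (Ψ ≥ 0.75) versus 55.7 %
of COX-normal ones (the planted morphology coupling); the fibre mitotypes
show a Spearman correlation of −0.94 between mean intensity and mean MCI
(more COX activity ⇒ more complex mitochondria); and every fibre's spatial
class concordance is far above its permutation null (z ≈ 11–16 under the
segmental pattern).

The same analysis as a narrated, stage-by-stage workflow:

```sh
Rscript analysis/01_phantom.R           # synthesize cohort -> results/phantom/
Rscript analysis/02_measure.R           # normalize + measure -> results/tables/
Rscript analysis/03_classify.R          # mixture fit, classes, fibre summary
Rscript analysis/04_mitotypes_spatial.R # mitotypes, 3D maps, concordance
Rscript analysis/05_group_stats.R       # KW + FDR, PLS-DA + VIP, Ward heatmap
```

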