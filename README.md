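# scaffoldMRI

Quantitative tissue assessment in cell-seeded 3D porous scaffolds
from micro-MRI image stacks.

Tissue-engineered constructs are grown by culturing cells (for
example bone-marrow stromal cells) inside opaque porous polymer
scaffolds, and micro-MRI is one of the few ways to watch tissue form
inside them non-destructively: scaffold polymer images dark, the
buffer in the pores grey, and lipid-containing cell/ECM material
bright. At the low tissue densities that matter (a few percent of the
pore volume), smooth background-intensity inhomogeneity from the coil
and field dominates the tissue–buffer contrast, and plain global
thresholding fails. This package is for researchers who have such
stacks (or want to prototype the analysis before scanning): it
implements the complete post-imaging processing and quantification
sequence, and a synthetic phantom generator with exact ground truth
for validating every stage.

## Method

For slices $I_k$ of a stack with a scaffold-free reference slice
$I_r$ (top or bottom of the stack):

1. background estimate by grayscale morphological opening with a
   disk, $B = (I_r \ominus D_9) \oplus D_9$;
2. correction $I_k' = \max(I_k - B,\, 0)$, then a radius-2 disk
   median filter per slice;
3. segmentation inside a circular ROI (auto-fitted to the liquid
   region or user-supplied): tissue $= \{I' \ge t\}$ smoothed by a
   radius-2 binary opening; scaffold $= \{I \le s\}$ on the raw
   stack. The tissue threshold $t$ is calibrated as the smallest
   value at which a bare (cell-free) scaffold scan shows at most
   0.1 % false-positive pore pixels;
4. quantification per slice: $\text{pore} = \text{ROI} -
   \text{scaffold}$, $\ \text{tissue\%} = 100\,\text{tissue} /
   \text{pore}$; per-section (top/middle/bottom) mean ± SD, one-way
   ANOVA with Bonferroni post-tests, and 4-stage projection maps;
5. 3D surface models of tissue and scaffold (iso-level 0.5 surfacing
   with resampling factors 2 and 1), smoothed with a non-shrinking
   Taubin filter ($\lambda = 0.5$, $\mu = -0.53$, 10 iterations),
   exported as PLY/STL/OBJ.

## Worked example

Build a phantom with known tissue content spanning the 1–4 % pore
volume regime, plus a bare control for threshold calibration, and run
the full pipeline:

```r
library(scaffoldMRI)

ph   <- build_phantom(tissue = tissue_model(
          c(top = 0.01, middle = 0.025, bottom = 0.04)), seed = 42)
bare <- build_phantom(tissue = tissue_model(c(bottom = 0)), seed = 42)
print(ph)
#> mri_phantom: 128 x 128 x 45, seed 42, native contrast
#>   bias amplitude 0.20, noise sigma 5 (gaussian)
#>   ground truth occupancy (% of pore volume):
#>  section n_slices pore_px tissue_px occupancy_pct
#>      top       14  130100      1301      1.000000
#>   middle       15  138644      3466      2.499928
#>   bottom       14  129592      5184      4.000247

res <- run_pipeline(ph$stack, bare = bare$stack,
                    config = pipeline_config())
print(res)
#> mri_pipeline result
#> circular_roi: centre (64.50, 64.50) px, radius 58.96 px
#>   tissue threshold 18.1166 (calibrated), scaffold threshold 50
#>   tissue % of available pore volume per section:
#>  section first last n_slices mean_pct    sd_pct
#>      top     2   15       14 1.010907 0.4928538
#>   middle    16   30       15 2.569803 0.9411940
#>   bottom    31   44       14 4.152757 1.3804496
#> One-way ANOVA: F(2, 40) = 34.26, p = 2.14e-09 ***
#> Bonferroni-adjusted pairwise comparisons:
#>  group1 group2        p_adj stars
#>     top middle 2.231899e-05   ***
#>     top bottom 5.063259e-08   ***
#>  middle bottom 3.500534e-03    **
```

The recovered per-section percentages sit within ~0.15 percentage
points of the generator's ground truth; the ANOVA reports the
bottom-heavy distribution (bottom > middle > top) with the usual
star notation. `res$records` holds the per-slice table (slice id,
tissue/scaffold/pore/ROI pixel counts, tissue %), `res$projections`
the 4-stage maps, and `res$scene` the smoothed tissue + scaffold
surface models; `run_pipeline(..., output_dir = "out")` writes all of
it (TIFF masks, CSV tables, PNG projections, PLY/OBJ meshes, JSON run
log). A run log can be replayed with `replay_run()` and reproduces
the tables byte for byte.

A thin command-line front end with subcommands
`phantom | correct | segment | quantify | mesh | run-all` is
installed at `inst/scripts/scaffoldmri`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/scaffoldmri", package="scaffoldMRI"))')" \
  phantom --out phantom_out --seed 7 --occupancy top=0.01,middle=0.025,bottom=0.04
```

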