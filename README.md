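# hybridseg

Level-set segmentation of 2-D grayscale images with **intensity
inhomogeneity** — the smooth bias fields (nonuniform illumination, MR coil
shading, X-ray attenuation) that defeat global two-phase models. The
package implements a hybrid region-based active contour whose velocity
combines a global Chan–Vese fitting term, a ball-localized mean-separation
term, and an arc-length regularizer, alongside the two pure baselines it
interpolates between (global-only Chan–Vese, local-only), a seeded phantom
suite that reproduces the relevant failure modes with exact ground truth,
segmentation metrics (Dice, Jaccard, Hausdorff), and a small CLI.

It is aimed at people studying region-based active contours: the phantom
suite plus the paired baselines make the method's claimed advantages —
robustness to bias where the global model leaks, escape from the local
minima that trap purely local models — reproducible and measurable.

## The model

The contour is the zero level set of a field φ (positive inside). With the
smoothed Heaviside H<sub>ε</sub>(z) = ½[1 + (2/π) arctan(z/ε)] and
δ<sub>ε</sub> = H′<sub>ε</sub>, the energy is

E = α E<sub>global</sub> + β E<sub>local</sub> + ω L(φ)

- E<sub>global</sub> = ∫ H<sub>φ</sub>(I − m)² + (1 − H<sub>φ</sub>)(I − n)² — the
  piecewise-constant fitting residual with global interior/exterior means
  m, n;
- E<sub>local</sub> localizes a mean-separation energy with a binary ball
  B(x, ·) of radius r: at each pixel x it compares the mean intensities
  u<sub>x</sub>, v<sub>x</sub> (areas A<sub>u</sub>, A<sub>v</sub>) of the
  ball-restricted interior and exterior;
- L(φ) = ∫ δ<sub>ε</sub>(φ)|∇φ| penalizes contour length.

Gradient descent yields the evolution

∂φ/∂t = α δ<sub>ε</sub>(φ)[−(I − m)² + (I − n)²]
 + β δ<sub>ε</sub>(φ) Σ<sub>x</sub> B(x, y)(u<sub>x</sub> − v<sub>x</sub>)[(I − u<sub>x</sub>)/A<sub>u</sub> + (I − v<sub>x</sub>)/A<sub>v</sub>]
 + ω δ<sub>ε</sub>(φ) div(∇φ/|∇φ|),

discretized with explicit Euler (Δt = 0.45 by default) and central
differences. Defaults: α = β = 1, ω = 0.1, ε = 1, r = 9 px. See the
methods vignette (`vignettes/hybrid-active-contours.Rmd`) for the
derivation, the numerical conventions, and the design rationale.

## Worked example

Segment a biased, noisy three-objects phantom where the brightest
background exceeds the dimmest object:

```r
library(hybridseg)

ph   <- make_phantom(phantom_spec("three_objects", fg_level = 0.4, bg_level = 0.05,
                                  bias = bias_linear(0.5), noise_sigma = 0.03, seed = 3))
phi0 <- init_levelset(dim(ph$image), region_circle(39, 63, 12))
fit  <- evolve(ph$image, phi0, hybrid_params(max_iters = 4000))
fit
#> <levelset_evolution: hybrid model>
#>   79 x 75 field, 3440 iterations, converged: TRUE
#>   final energy: total=8.405e+04 global=163.5 residual=6591 length=41.18
#>   foreground pixels: 1746 / 5925

cv <- cv_evolve(ph$image, phi0, mu = 0.1, max_iters = 4000)
c(hybrid = dice(fit$mask, ph$mask), cv = dice(cv$mask, ph$mask))
#>   hybrid       cv
#>    0.999    0.848

seg_score(fit$mask, ph$mask)
#>    dice jaccard hausdorff changed_pixels
#> 1 0.999   0.998         3              3
```

The hybrid recovers all three objects (Dice 0.999) while the global model
leaks along the bias-brightened background (Dice 0.848). `tidy(fit)` gives
the energy trace, `glance(fit)` a one-row summary, `autoplot(fit)` the
trace plot, and `plot_segmentation(fit, ph$image, ph$mask)` the contour
overlay.

The same is available from a shell:

```sh
Rscript inst/scripts/hybridseg phantom --kind three_objects --fg 0.4 --bg 0.05 \
        --bias linear --bias-amplitude 0.5 --noise 0.03 --seed 3 --out work
Rscript inst/scripts/hybridseg segment --image work/image.tif --init circle:39,63,12 \
        --model hybrid --max-iters 4000 --truth work/mask.png --out work/run
Rscript inst/scripts/hybridseg bench --out bench.csv
```

`segment` writes the mask (PNG), the final level set (float TIFF), the
energy trace (CSV) and a JSON summary; `bench` runs all three models on
the six-phantom suite and tabulates iterations and Dice per run.

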