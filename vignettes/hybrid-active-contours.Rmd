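---
title: "Hybrid region-based active contours: model, numerics and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid region-based active contours: model, numerics and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(hybridseg)
```

## The segmentation problem

Medical and biological images routinely violate the assumption behind
global two-phase segmentation: that the object and the background each have
a roughly constant intensity. Illumination gradients, coil sensitivity in
MR, or beam attenuation in X-ray produce a smooth *bias field* on top of
the tissue contrast, so the brightest background pixels can exceed the
darkest object pixels and no global threshold — and no global region model
— can separate the phases. Purely local region models handle the bias but
see only a neighborhood of the current contour, so they stall in local
minima when the initialization is far from parts of the object.

`hybridseg` implements a level-set active contour whose velocity combines
both sources of information, together with the two pure baselines it
interpolates between, a seeded phantom suite reproducing the failure modes
above, and the metrics and command-line plumbing to compare them.

## The model

The contour is the zero level set of a field $\phi$, positive inside.
Region membership is written with a smoothed Heaviside
$H_\varepsilon(z)=\tfrac12\left[1+\tfrac2\pi\arctan(z/\varepsilon)\right]$
and its derivative $\delta_\varepsilon(z)=\tfrac1\pi
\tfrac{\varepsilon}{\varepsilon^2+z^2}$. The energy has three weighted
terms,

$$E \;=\; \alpha\, E_{\text{global}} \;+\; \beta\, E_{\text{local}}
\;+\; \omega\, L(\phi),$$

* $E_{\text{global}}$ is the piecewise-constant (Chan–Vese) fitting
  residual $\int H_\phi (I-m)^2 + (1-H_\phi)(I-n)^2$, with $m, n$ the mean
  intensities inside and outside the contour;
* $E_{\text{local}}$ measures, for every pixel $x$, how well the contour
  separates the intensities *inside the ball* $B(x,\cdot)$ of radius $r$:
  with local means $u_x, v_x$ and local areas $A_u, A_v$ of the
  ball-restricted interior/exterior, the localized mean-separation energy
  rewards $u_x \ne v_x$ along the contour;
* $L(\phi)=\int \delta_\varepsilon(\phi)\lvert\nabla\phi\rvert$ penalizes
  contour length, suppressing noise-induced fragments.

Gradient descent gives the evolution

$$\frac{\partial\phi}{\partial t} \;=\;
\alpha\,\delta_\varepsilon(\phi)\left[-(I-m)^2+(I-n)^2\right]
\;+\; \beta\,\delta_\varepsilon(\phi)\,F_{\text{local}}
\;+\; \omega\,\delta_\varepsilon(\phi)\,
\operatorname{div}\!\frac{\nabla\phi}{\lvert\nabla\phi\rvert},$$

where pixel $y$ accumulates, over every ball center $x$ whose ball covers
it,

$$F_{\text{local}}(y) \;=\; \sum_x B(x,y)\,(u_x-v_x)
\left[\frac{I(y)-u_x}{A_u(x)}+\frac{I(y)-v_x}{A_v(x)}\right].$$

### Why this local velocity

Two readings of the local term circulate in the literature on localized
region energies: the mean-separation descent direction above, and a raw
residual-contrast form $(I-u_x)^2/A_u-(I-v_x)^2/A_v$. The two differ by a
term proportional to $(I-u)(I-v)\,(1/A_u-1/A_v)$, which vanishes where the
ball is bisected by the contour — precisely the regime the model is
designed around — but not elsewhere. We tested both at phantom scale: the
mean-separation direction converges to the object boundary and stays there
(Dice 1.00 on the clean gourd phantom for both the local-only and hybrid
flows), while the raw form is not a descent direction — the local-only flow
drifts away from the boundary after approaching it. `local_force()`
therefore defaults to `form = "mean_separation"`; the raw integrand remains
available as `form = "as_printed"` for comparison, and both are validated
against brute-force double-loop oracles in the test suite.

A related ambiguity affects the *energy value*: the printed local energy
$\int\!\!\int B(x,y)(u_x-v_x)^2$ grows as the separation improves, whereas
the flow decreases the ball-restricted two-phase fitting residual. The
energy trace records both readings (`local_printed`, `local_residual`) so
the distinction stays observable; descent assertions in the tests use the
residual.

## Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `alpha` | 1 | dimensionless, 0–2 | weight of the global term; lower it for strongly inhomogeneous images |
| `beta` | 1 | dimensionless, 0–2 | weight of the local term; `alpha ~ beta` is the usual regime |
| `omega` | 0.1 | dimensionless | length penalty; controls smoothing of noisy contours |
| `dt` | 0.45 | time step | explicit Euler step; stable at the default on all shipped phantoms |
| `eps` | 1.0 | level-set units | Heaviside width. Not prescribed by the model; 1.0 is the conventional choice for the arctan regularization and gives $\delta_\varepsilon$ effectively global support, letting the flow act far from the contour (this is what lets the hybrid discover objects the initialization never touched) |
| `r` | 9 | pixels | ball radius; about 1/10 of the side of a ~100 px image, the usual localization scale. Must exceed the bias correlation length locally and stay below object spacing |
| `c0` | 2 | level-set units | magnitude of the binary initialization; conventional value |
| `max_iters`, `tol`, `check_every` | 2000, 1e-4, 20 | — | iteration cap, stopping tolerance, check cadence |

## Numerical choices

**Discretization.** Integrals are plain pixel sums (unit pixel area). All
spatial derivatives are central differences with replicate (Neumann)
boundary handling; the curvature denominator is regularized as
$\sqrt{\phi_x^2+\phi_y^2+\eta^2}$ with $\eta=10^{-8}$, far below any signal
scale. Updates are explicit forward Euler; statistics ($m$, $n$, $u$, $v$,
$A_u$, $A_v$) are recomputed from the current field every iteration
(`stats_every` exposes the cadence).

**Ball correlations.** The local statistics are exact in-domain gathers:
the ball around a center sums only pixels of the image domain, so the
effective ball area shrinks near borders rather than inventing values
beyond them. This makes $A_u + A_v$ equal the in-domain ball area exactly
and makes a ball larger than the image diagonal reproduce the global means
identically — the reduction the tests assert. Derivatives, by contrast,
use replicate padding; the two conventions serve different objects (region
integrals vs. differential operators).

**Initialization.** $\phi_0 = +c_0$ inside the seed region, $-c_0$ outside,
honoring the inside-positive convention used by every region integral
(an `invert` flag flips it). No signed-distance reinitialization is
performed — the model never requires $\phi$ to be a distance function, and
the length penalty keeps the field bounded in practice; the tests verify
boundedness over 5000 iterations on every shipped phantom.

**Ties and degeneracies.** Pixels with $\phi=0$ exactly are classified
outside, so labels are deterministic. Ball centers whose local interior or
exterior mass falls below $10^{-10}$ (possible only for very sharp
Heavisides) are flagged and contribute zero force — balls deep inside a
region carry no boundary information. An empty or full initial region is a
configuration error; a constant image is legal (all fitting forces vanish
and the length term shrinks the contour).

**Stopping.** The model itself prescribes no stopping rule. We declare
convergence when, at a check (every `check_every` iterations), fewer than
`tol` of all pixels changed label over the window *and* fewer than that are
on course to flip within the remaining iteration budget (labels
extrapolated linearly from the current velocity). The second clause is
needed because a binary initialization produces a warm-up phase in which
$\phi$ moves steadily but no pixel has crossed zero yet, which a pure
label-stability rule mistakes for convergence; a run started at the true
fixed point still converges at the first check. Iteration counts are
reported as PDE steps and are not comparable across implementations —
they depend on the intensity scale and the stopping rule.

## The phantom suite

Real test imagery for this model class is not redistributable, so the
suite regenerates its conditions synthetically, with seeded noise and
exact ground truth. `default_suite()` fixes six items:

* **gourd** (59×67) — two overlapping discs, clean: the baseline case every
  model should segment;
* **noisy_gourd** (59×67, $\sigma=0.05$) — tests that the length penalty
  keeps the contour in one smooth piece under noise;
* **three_objects** (79×75, linear bias 0.5, $\sigma=0.03$) — two dim discs
  at the low-bias side and a tall bar occupying the high-bias side, with
  base levels chosen so the brightest background *exceeds* the dimmest
  object. The global model leaks along the bright margin and drops the dim
  disc halves; the local model stays at the object the initialization
  touches; the hybrid recovers all three objects;
* **t_shape** (96×127, radial bias) — nonuniform illumination over a
  T-shaped object;
* **vessel1/vessel2** (110×111, 131×103) — curvilinear tubes of width 3–7 px
  with a sinusoidal centerline, crossing a strong bias oriented along the
  tube so that background at the bright end exceeds the vessel at the dim
  end.

Design notes, decided once and kept fixed:

* Geometry parameters are fractions of the image size; the exact shapes of
  the original figures are unrecoverable, so the suite is calibrated only
  to reproduce the *qualitative* failure modes (global leak, local trap),
  which it does.
* Bias is applied to object and background alike (a camera shades
  everything), then noise is added, then values are clipped to $[0,1]$;
  clipping truncates the noise distribution and is part of the contract.
* The three-objects geometry deliberately places the bias-brightened
  background adjacent to a true object edge. Where bright background lies
  far from any object, no weighting of the hybrid can expel it — the local
  term is neutral in a pure gradient (its force cancels at the mid-level
  of a linear ramp) and the global term holds the region. This mirrors the
  described imagery, where the background exceeds the object *near* it.
* Each recommended initialization overlaps part of one object. The global
  energy is invariant under swapping inside and outside together with the
  means, so an initialization wholly in the background converges with
  inverted labels; overlapping an object seeds the correct polarity for
  all three models. For the strongly inhomogeneous items (t_shape,
  vessels) the recommended weights shift toward the local term
  (`alpha` 0.2–0.3, `beta` 1.7–1.8), the adaptation to the degree of
  inhomogeneity that the model prescribes; three_objects runs at the
  defaults `alpha = beta = 1`.

What the phantoms do *not* emulate: textured tissue, partial-volume
boundaries, modality-specific noise (Rician, Poisson), and 3-D geometry.
Passing the suite shows the implementation realizes the model's intended
behavior under bias and Gaussian noise; it does not certify performance on
clinical data.

## Problem sizes in the tests

Oracle comparisons run on 12–32 px instances where double loops are exact
and fast; phantom runs use the native suite sizes (≤131×103). The descent
and boundedness checks iterate 5000 steps per phantom; everything else
converges by label stability, typically within a few hundred to a few
thousand iterations.

## Known limitations

The energy is nonconvex: results depend on the initialization, and the
recommended seeds are part of the suite for that reason. Iteration counts
are not comparable to other implementations (intensity normalization and
stopping rules differ). The local term costs a handful of ball
correlations per iteration — all of the model's extra cost over the global
baseline — and the implementation computes statistics at every pixel; a
narrow-band restriction would be the natural optimization and is out of
scope. Multi-region (more than two phases) segmentation is likewise out of
scope: the model is bimodal.
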