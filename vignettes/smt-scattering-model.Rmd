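---
title: "Modelling diffuse scattering from skin subvisible micro texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diffuse scattering from skin subvisible micro texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtoptics)
```

## The physical picture

Facial skin carries texture at two distinct scales. The visible macro
texture — ridges (crista cutis) separated by furrows (sulcus cutis) —
repeats with a period of a few hundred micrometres. On top of the ridges
sits a much finer ripple, the subvisible micro texture (SMT), with a
height of a few micrometres and a period of tens of micrometres:
invisible to the naked eye, but decisive for how the skin scatters light.
Two observable consequences matter for appearance. Light arriving from
outside is partly scattered back into air (*diffuse reflection*): the
angular broadening of that reflected lobe blurs the mirror image of the
light source and thereby softens the appearance of imperfections (the
"soft-focus" effect). Light travelling inside the skin that crosses the
surface into air (*diffuse transmission*) controls how much internally
scattered light escapes and hence the perceived translucency.

`smtoptics` implements a deliberately minimal forward model of both
processes: a single refractive interface with realistic topography,
geometric optics, and no volumetric transport. Everything the model says
about skin is therefore about the *surface*; the package quantifies how
far the five topography parameters alone take you.

## The equivalent 2D surface

One period of the surface is parameterized by `surface_params(W, H, W_V,
u_h, u_w, n)`. Along a period:

* the furrow occupies `[0, W_V]` as a half-ellipse groove of depth `H`
  (equivalently, two quarter-ellipse walls of horizontal semi-axis
  `W_V / 2` and vertical semi-axis `H` meeting at the flat-ish bottom);
  the walls are vertical at the rim,
* the ridge top occupies `[W_V, W]` at the reference height `h = 0` and
  carries a train of upper-half-ellipse ripple bumps of height `u_h`
  (peak-to-valley) and base `u_w`. The first bump starts at the furrow
  edge; a partial bump may be truncated at the far edge. The ripple sits
  on the ridge top only, not on the furrow walls, matching where the SMT
  is observed on real skin.

Degenerate limits behave as expected: `u_h = 0` gives a smooth macro-only
groove, `H = u_h = 0` a flat surface. The analytic height function is
periodic to machine precision and bounded by `[-H, u_h]`; scaling all
five lengths by a constant scales the profile pointwise, so the optics
depend only on shape ratios and the wavelength-free geometric-optics
assumption.

For ray tracing the profile is sampled to a polyline, by default with at
least 40 samples per ripple period and 200 across the furrow so that the
steep walls and the bump curvature are resolved; the sampling density is
a parameter (`samples_per_period`), and a minimum of 20 samples per
`u_w` is enforced.

## The Monte Carlo tracer

`simulate_scattering` launches `ray_count` parallel rays at incidence
angle `theta_i`, from air above (reflection mode) or from inside the
medium below (transmission mode). The only randomness is the seeded
uniform distribution of launch positions over one macro period — at every
surface hit the ray is split *deterministically* into a reflected and a
refracted child weighted by the unpolarized Fresnel power coefficients
(mean of s and p). This splitting scheme was chosen over stochastic path
sampling because it is reproducible, has much lower variance at a given
ray budget, and makes energy bookkeeping exact: each split conserves
power by construction, so `R + T + residual = 1` holds to 1e-9 on every
run. Under total internal reflection the refracted child is simply
omitted.

Children are traced until they escape the height-field slab upward or
downward, fall below `power_cutoff` (default 1e-4 of one launched ray's
power) or exceed `max_depth` (default 20 interactions); terminated power
is reported as `residual`, never silently dropped. In practice the
residual stays below 1e-3 across all bundled specimen presets and
incidence angles at the defaults. Intersections use a cell-marching scan
over the uniformly sampled polyline with periodic wrap in `x` and an
epsilon offset of 1e-6 um against self-re-hits; the tracer is compiled
code, so runs with 1e5 rays take fractions of a second. The model is a
2D profile extruded along the third axis, so scattering is strictly
in-plane; polarization, wavelength dependence, diffraction and
absorption are out of scope.

Exit angles are recorded signed, measured from the global surface
normal, with the forward (specular/Snell) side positive, so the
reflection lobe of a run at `theta_i = 45` degrees peaks near +45 and a
flat-surface transmission run peaks at the Snell angle. `R` always means
power returned to the illuminated side and `T` power delivered across
the surface, regardless of mode.

## Lobe fitting

`bin_exit_rays` bins escaped power conservatively (1-degree bins by
default; total power is preserved exactly) and `fit_gaussian` fits
`A * exp(-(theta - mu)^2 / (2 sigma^2))` by Levenberg–Marquardt least
squares. Initialisation uses the maximum bin for `A` and `mu` and the
power-weighted angular standard deviation for `sigma`; tolerances are
set tight (1e-15) so that fits of exact model histograms recover the
generating parameters to better than 1e-6 and the fit is
shift-equivariant to 1e-9. Zero-power bins participate in the loss — they
are real observations of zero radiance and constrain the width. The
centre `mu` is a free parameter by default (it can be fixed via
`fix_center`); the loss is unweighted because the binned powers are
deterministic fractions, not counts. Distributions with fewer than five
nonzero bins, or with essentially all power in a single bin (a bare
specular spike), raise a degenerate-fit error rather than returning a
meaningless width; an optional flag can drop an isolated spike more than
100 times its neighbours before fitting, off by default. A fit whose
coefficient of determination falls below 0.2 is flagged `poor` (a
uniform distribution is the canonical example).

## Empirical closed forms and refits

The package ships the published closed-form models linking the texture
ratios to the lobe parameters and to total reflectance/transmittance:
linear models in `u_w/u_h` (with a weaker `W_V/W` modulation) for the
lobe amplitude `A` and reciprocal width `1/sigma`, sigmoid models in
`theta_i` for `R` (air to medium) and `T` (medium to air), and
`angle_average` for uniform-illumination averages computed by composite
trapezoid quadrature at a 0.01-degree step (the averages quoted below
change by under 1e-5 when the step is refined tenfold). All constants
live in one table (`smt_constants()`) and every model function accepts a
replacement coefficient vector, so alternative calibrations — including
refits of the same functional families against this package's own tracer
via `run_sweep` + `fit_linear_form` / `fit_sigmoid_form` — can be swapped
in without code changes. Refitted coefficients are reported alongside the
published ones but are not expected to match them numerically: the
published values come from a different tracer on specimen geometries that
are not fully tabulated. What does transfer, and what the test suite
asserts, is structure: `1/sigma` affine in `u_w/u_h` with positive slope
(goodness above 0.9 on the standard sweep), amplitude increasing and
width decreasing in `u_w/u_h`, rank correlation of width with the SMT
ratio at or below -0.9, and a weaker `W_V/W` effect.

One published inconsistency deserves note. Direct evaluation of the
reflectance sigmoid as printed yields uniform-illumination angle averages
near 0.92–0.96, far from the two averages quoted alongside it (0.081 and
0.094), and no reading of the formula reproduces both quoted values and
their increasing trend simultaneously. The package keeps the formula
exactly as printed, asserts only the increasing trend of its angle
average, and excludes those two numbers from quantitative checks. The
transmittance sigmoid *is* self-consistent: its averages evaluate to
0.496 and 0.479 at `u_w/u_h` = 11.8 and 25, matching the quoted 0.495
and 0.479 within 0.005, and these are the quantities
`scripts/acceptance.R` recomputes.

## Translucency index

`translucency_index(eta, u_ratio)` combines the two sigmoids into
`tau = eta * tau_diffuse + (1 - eta) * tau_direct`, where the direct
component averages `(1 - R(theta)) * T(theta')` with `theta'` the Snell
refraction angle inside the medium (relative index fixed at 1.4 for
skin, configurable), and the diffuse component factorises into
`<1 - R> <T>` under the isotropic-scattering assumption. The mixing
ratio `eta` — the diffusely scattered fraction of the internal light — is
an input, not an estimate: the single-interface model has no mechanism
to predict it, and the intervening "complete reflection by the deeper
layer" is idealised as lossless. The algebra is exact (endpoints,
affinity in `eta`) and the headline ordering is robust: for any `eta`,
the finer ripple (`u_w/u_h` = 11.8) yields a higher index than the
coarser one (`u_w/u_h` = 25). With the printed sigmoids the direct
component evaluates *above* the diffuse one over the tabulated ratio
range — the package computes and reports both without asserting either
ordering, since it is sensitive to the reflectance-sigmoid inconsistency
described above.

## Parameterizing measured profiles

`parameterize_profile` inverts the builder on a sampled cross-section.
Furrow cores are detected as contiguous runs deeper than a configurable
fraction (default 50%) of the robust 1st–99th percentile height range. A
detected set of grooves is accepted as macro texture only if its mean
depth exceeds three times the ridge's own height spread — otherwise the
"grooves" are just ripple valleys and the profile is treated as
ripple-only (shallow-groove surfaces below that contrast are deliberately
classified as ripple). Because the elliptical walls are steep only near
the rim, a run measured at the 50% threshold underestimates the true
groove width by about 13%, so each accepted run's edges are refined
outward to a shallow crossing (default 2% of the run depth); `W` is the
mean spacing of run centres, `W_V` the mean refined width, `H` the mean
depth below the ridge reference plane.

On the ridge runs, ripple peaks are local maxima passing a topographic
prominence filter (default 10% of the local ridge amplitude) after a
light 5-sample running-mean smooth; an optional moving-median detrend
(window of roughly three expected ripple periods) is available for
curved ridge tops. `u_w` is the mean peak spacing. For `u_h` the naive
peak-to-valley estimate is biased: where two convex bumps meet, the
profile has a sqrt-shaped cusp, and the deepest *sample* overshoots the
true floor by O(sqrt(dx)) — about 6% at the default sampling. Each
valley floor is therefore refined by fitting a two-branch sqrt cusp
model `c + a_L sqrt(x0 - x) + a_R sqrt(x - x0)` around the sampled
minimum, which recovers the floor to well under 1% on noise-free
profiles and falls back to the sampled minimum when the model does not
fit. The refined valley heights also relocate the ridge reference plane,
sharpening `H`. Noise-free round trips through `build_profile` recover
all five parameters within 5% (typically within 0.5%) for all bundled
specimen presets; with 5%-of-`u_h` Gaussian noise the ripple period is
still recovered within 10%.

## Synthetic height maps

`synth_height_map` extrudes the analytic profile along `y` and adds
independent Gaussian pixel noise, emulating a laser-microscope scan of
the idealised surface (the default extent mirrors a 708 um by 531 um
scan field). It reproduces exactly what the model assumes — perfect
periodicity, straight extrusion, white noise — and none of what real
scans add: curved ridge tops, anisotropy, waviness, outliers, missing
pixels. Passing round-trip tests on these maps therefore validates the
estimator implementations, not their robustness on clinical data.

## Numerical and design choices

* Sampling: profiles default to at least 40 samples per `u_w`,
  200 across `W_V`, 512 per period; intersection epsilon 1e-6 um;
  traversal capped at 2e6 cells per ray (capped power joins the
  residual).
* Tracer defaults: `max_depth` 20, `power_cutoff` 1e-4, 1-degree bins,
  launch over one macro period; unpolarized light throughout.
* Problem sizes: the test suite runs 1e5 rays for the quantitative
  acceptance checks and 2e4–5e4 rays for structural checks, where the
  launch-position sampling error in `R` is well below the asserted
  tolerances; simulations at normal incidence on a symmetric period are
  mirror-symmetric to within a few percent L1 at 1e5 rays.
* The ambiguous molded-plate specimen row is exposed as two presets
  (`hd6_a`, `hd6_b`) rather than one hard-coded reading, and the
  separately quoted ratio list (11.8, 15.2, 21.9, 25) is exposed via
  `printed_u_ratios()` without reconciling it against the tabulated
  length quotients.
* Rank correlations use mid-ranks with the t approximation for p-values;
  an exact permutation null (enumerating distinct tied-rank
  arrangements) is available for n of 10 or fewer.

## Limitations

Single interface, single wavelength, geometric optics, in-plane
scattering only: the model cannot represent volumetric subsurface
scattering, chromophore absorption, interference colours, out-of-plane
anisotropy, or multilayer effects, and its empirical closed forms are
calibrated only within the tabulated specimen parameter range
(`u_w/u_h` roughly 9–39). Within that envelope it reproduces the
qualitative benchmark orderings — the sandblasted plate scatters more
diffusely than the molded one, the finer-rippled skin sample scatters
more diffusely than the coarser one at every incidence angle — and the
quantitative transmittance averages quoted above.
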