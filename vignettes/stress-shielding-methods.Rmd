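---
title: "Methods: stress shielding, bone resorption and implant safety on a synthetic femur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress shielding, bone resorption and implant safety on a synthetic femur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femshield)
```

## The problem

After a total hip arthroplasty the femoral stem carries part of the load the
proximal femur used to carry. Because load in a composite structure follows
stiffness, a metal stem (Ti6Al4V, E = 110 GPa) bypasses the surrounding
cortical bone (E ≈ 16.7 GPa); the unloaded bone remodels away (Wolff's law),
the fixation loosens, and revision surgery follows. A polymer stem (PEEK,
E = 1.69 GPa) is closer to — in fact below — cortical stiffness, so the
post-operative stress field stays nearer to the intact one. `femshield`
quantifies that contrast: per-Gruen-zone stress shielding, predicted bone
resorption, stem safety factors, and the strain-gauge / agreement machinery
used to validate stress models against bench measurements.

All quantities are computed from *paired element fields*: tables of element
volume, density, von Mises stress and principal compressive strain for an
intact and an implanted femur with element-by-element correspondence.

## Stress Shielding Increase

For a region (Gruen zone) the volume-weighted mean von Mises stress of
cortical bone is
$$\langle\sigma\rangle = \frac{\sum_e \sigma_e V_e}{\sum_e V_e},$$
with the element-centroid stress standing in for the element integral (no
higher-order quadrature: the inputs are already element summaries). The
Stress Shielding Increase is
$$\mathrm{SSI} = \frac{\langle\sigma^{\mathrm{intact}}\rangle -
\langle\sigma^{\mathrm{implanted}}\rangle}{\langle\sigma^{\mathrm{intact}}\rangle},$$
positive where the implant shields the bone, negative where local stress
rises. The total SSI weights the per-zone values by their cortical volume
fractions (zones 1–7 only; a flagged alternative over the whole femur would
differ only through the denominator). Zone labels follow the clinical
convention: lateral 1–2–3 proximal to distal, medial 7–6–5, zone 4 distal to
the stem tip. Only elements flagged `medial`/`lateral` (cortical fibers)
enter the averages; interior stem/resin/cancellous elements are excluded by
their `side` flag.

## Strain-adaptive bone resorption

Remodeling is driven by the strain energy per unit bone mass $S$. Changes
within a *dead zone* of width $s$ around the intact level are tolerated;
resorption occurs only when $S < (1-s)\,S_{\mathrm{intact}}$. With the
principal compressive strains before and after implantation,
$$\frac{S_{\mathrm{implanted}}}{S_{\mathrm{intact}}} =
\left(\frac{\varepsilon_{\mathrm{implanted}}}{\varepsilon_{\mathrm{intact}}}\right)^2,$$
and the resorbed mass fraction of a zone is the mass-weighted mean of the
indicator
$$m_r = \frac{\sum_e f_e\,\rho_e V_e}{\sum_e \rho_e V_e},\qquad
f_e = \mathbf{1}\!\left[\frac{(\varepsilon_{\mathrm{imp}}/\varepsilon_{\mathrm{int}})^2}{1-s} < 1\right].$$

Two deliberate readings are worth stating explicitly:

* **Indicator algebra.** We evaluate the resorptive function at
  $x = (\varepsilon_{\mathrm{imp}}/\varepsilon_{\mathrm{int}})^2/(1-s)$.
  Written with a squared $(s-1)$ factor inside the function argument, the
  dead-zone condition could never fire; the form used here is the one that
  exactly reproduces the resorption branch $S < (1-s)S_{\mathrm{intact}}$ of
  the remodeling law, and is the only internally consistent reading.
* **Only the resorption branch** is implemented. The densification branch
  and the time integration of $d\rho/dt$ are out of scope: the quantity of
  interest is the equilibrium resorbed fraction.

Defaults: $s = 0.6$ (the typical clinical densitometry value; with it,
resorption requires an energy ratio below 0.4, i.e. a strain ratio below
$\sqrt{0.4}\approx0.63$). Elements whose intact strain magnitude is below
`strain_floor` ($10^{-9}$ absolute strain) are excluded from both sums and
counted, never divided by. The total across zones is mass-weighted by
default; volume weighting is available (`resorption_report(weighting=)`).
Because squaring removes sign, tensile fibers — whose principal compressive
strain is the Poisson transverse strain — contribute the same strain ratio
as their axial ratio, so no special casing is needed.

## Stem safety

At peak load the static factor of safety is
$\mathrm{FoS}_{\mathrm{yield}} = \sigma_y/\sigma_{\max}$. For cyclic loading
with stress ratio $R = \sigma_{\min}/\sigma_{\max}$ (0.1 here: 230 N trough
against a 2300 N peak), linearity of the model makes the cycle proportional,
so $\sigma_{\min} = R\,\sigma_{\max}$ rather than re-solving at the trough
load; then $\sigma_m = (\sigma_{\max}+\sigma_{\min})/2$,
$\sigma_a = (\sigma_{\max}-\sigma_{\min})/2$, and the Soderberg criterion
$$\mathrm{FoS}_{\mathrm{Soderberg}} =
\left(\frac{\sigma_a}{\sigma_N} + \frac{\sigma_m}{\sigma_y}\right)^{-1}$$
with PEEK constants $\sigma_y = 85.5$ MPa, $\sigma_N = 70$ MPa (endurance at
the 5×10⁶-cycle qualification). A point is unsafe iff it lies above the
Soderberg line; at $R = 1$ the cycle degenerates and the fatigue FoS equals
the yield FoS exactly. Minimum-FoS reporting ignores unstressed elements
(infinite FoS) and breaks ties by element id; `unsafe_fraction()` counts
elements by default ("fraction of elements below 1"), with volume weighting
available.

## Rosette reduction

A 45° rectangular rosette (gauge A at 0° along the shaft axis, B at +45°,
C at +90°, counterclockwise positive — the instrument convention adopted
here, with channel A taken as the axial gauge) determines the surface state:
$$\varepsilon_{1,2} = \frac{\varepsilon_A+\varepsilon_C}{2} \pm
\frac{1}{\sqrt2}\sqrt{(\varepsilon_A-\varepsilon_B)^2 +
(\varepsilon_B-\varepsilon_C)^2},\qquad
\tan 2\theta = \frac{2\varepsilon_B-\varepsilon_A-\varepsilon_C}
{\varepsilon_A-\varepsilon_C},$$
followed by plane-stress recovery of the surface von Mises stress. Raw
bridge counts convert to microstrain at the acquisition sensitivity
(545.4 counts/µε); microstrain is the canonical internal unit, counts exist
only at the I/O boundary. Repeat averaging uses the arithmetic mean (five
repeats per configuration in the emulated protocol), with a median option
and no default outlier rejection.

## The synthetic femur generator

The generator's role is to produce paired fields with the *structure* of a
post-THA stress analysis — proximally concentrated shielding that grows with
stem stiffness, a neutral zone 4, plausible magnitudes — at desk scale. It
is a modulus-weighted composite beam, not a solid-mechanics surrogate:

* The femur is a stack of 20 annular stations over a 328 mm working length
  (cortical annulus around a cancellous core; outer radius tapering
  15.5→13.5 mm, canal 10.5→8 mm). Implanted configurations replace the core
  proximal to the stem tip (150 mm) with a tapering stem plus canal-filling
  resin; distal stations are untouched, which is exactly why zone 4 is
  implant-insensitive in the generator.
* The load (2300 N default, 10° adduction applied before 9° flexion; axes
  z distal, x lateral→medial, y posterior→anterior; head offset
  (40, 0, −60) mm) resolves into an axial force and bending moments. Station
  strain is `N/ΣEA + (M_y/ΣEI_y)x − (M_x/ΣEI_x)y`; stress is `E_i ε`
  (uniaxial, so von Mises = |σ|). The head offset magnitude is a
  configuration choice — anatomy varies and no single value is canonical —
  set to a typical adult femoral-head offset.
* Materials: cortical 16.7 GPa/ν 0.3/1.64 g/mL, cancellous 0.155 GPa/0.27
  g/mL, resin 2.5 GPa, Ti6Al4V 110 GPa, PEEK 1.69 GPa/ν 0.35.
* Noise is multiplicative Gaussian, sd 2% (strain-gauge repeatability
  scale), one factor per element, seeded; intact and implanted fields draw
  independent factors, as two independent analyses would. Multiplicative
  noise keeps SSI exactly invariant under load scaling at a fixed seed.
* Cortical fibers are meshed first so their element ids are identical across
  configurations, giving the element-by-element pairing the SSI and
  remodeling formulas need.

What the generator does **not** emulate: the femoral neck and head resection
(so stem stress concentrations at the neck/taper are absent and the
synthetic stem field stays far below yield), anatomic asymmetry
(anterior/posterior bow), contact and micromotion at the interface, and any
3D stress triaxiality. Consequently, passing tests demonstrate the
*metrics'* correctness and the expected qualitative orderings (total SSI and
resorption increase with stem modulus; zone 4 neutral), not the magnitudes a
CT-derived solid model would give; headline magnitudes from such models are
not reproduction targets here. Likewise the measured stem stiffnesses
(2.758 and 0.276 kN/mm) are bench reference constants: the
load–displacement module *recovers* them from synthesized records, it cannot
derive them.

## Validation machinery

`fit_stiffness()` is an ordinary least-squares slope of load on
displacement. Without an explicit window it scans all contiguous windows
holding at least half the samples and keeps the highest R² (longer window on
ties), which discards toe-in segments; the R² is computed directly from the
residuals. `bland_altman()` uses measured − predicted differences, the
sample (n−1) standard deviation, and 95% limits of agreement
bias ± 1.96 sd; "agreement" is declared when no point falls outside the
limits, the reading used for model validation throughout.

## Numerical choices and degenerate inputs

* SSI with zero intact mean stress, stress ratios with non-positive intact
  stress, and resorption with every element excluded raise errors rather
  than returning silently dropped values.
* The dead-zone boundary is closed on the no-remodeling side: an energy
  ratio exactly at $(1-s)$ does not resorb ($x < 1$ is strict).
* Worked factor-of-safety values are compared at the printed precision with
  half-away-from-zero rounding (85.5/76 = 1.125 prints as 1.13).
* Element noise factors are clamped below at 0.01 to keep stresses positive
  (a >4.9σ event at the default sd; it never fires in practice).
* Problem sizes: 20 stations × 16 circumferential points give 320 cortical
  and 144 stem elements per configuration — small enough that the whole
  pipeline, including both stems, runs in about a second, while leaving
  ~25 elements per proximal zone so zone means are stable.

## Limitations

Beyond the generator's scope above: the remodeling estimate is an
equilibrium bound, not a time course, and is not directly comparable to
early post-operative densitometry; isotropic linear elasticity throughout;
the Soderberg treatment uses a single endurance limit, not an S–N curve; and
the synthetic gauge channels carry no bridge nonlinearity or temperature
drift (deliberately out of scope).
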