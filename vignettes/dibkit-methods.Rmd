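---
title: "Models and methods behind dibkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dibkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dibkit)
```

`dibkit` analyses three measurements that together characterise how an
amphipathic drug such as aspirin (ASA) perturbs a lipid bilayer: osmotic
water transport through droplet interface bilayers (DIBs), interfacial
energetics of droplet adhesion, and thermotropic/structural changes seen
by DSC and Raman microspectroscopy.  This vignette documents the models,
the tunable parameters and their defaults, the synthetic-data generators,
and the numerical choices — including what passing the closed-loop tests
does and does not demonstrate about real data.

## Osmotic transport in a droplet pair

Two monolayer-coated droplets adhered across a bilayer of area $A$
exchange water when their osmotic concentrations differ.  We adopt the
standard osmotic volume-flow law

$$\frac{dV_1}{dt} = P_f\, V_w\, A\, (c_1 - c_2), \qquad
  \frac{dV_2}{dt} = -\frac{dV_1}{dt},$$

with $P_f$ the osmotic water permeability (µm/s), $V_w = 18.05$ cm³/mol
the molar volume of water near 25–30 °C (`WATER_MOLAR_VOLUME`), and
$c_i = n_i / V_i$ the instantaneous concentration of osmotically active
solute.  Assumptions: water is the only permeant (solute amounts $n_i$
are constants of motion); the two-droplet system is closed, so
$V_1 + V_2$ is conserved — the implementation integrates only $V_1$ and
sets $V_2 = V_\mathrm{tot} - V_1$, making conservation exact rather than
a solver tolerance; osmolality (mOsm/kg) maps to concentration (mol/m³)
one-to-one under the dilute-solution convention (water density 1 kg/L).
The ODE is integrated with `deSolve::ode()` (lsoda, `rtol = 1e-10`); the
sampling interval `dt` is an output grid, not the solver step, and a
positivity guard aborts with an informative error if a droplet would be
driven empty.

Two geometric conventions relate volumes and observed radii.  The
default `"sphere"` mode treats each droplet as a full sphere — at the
contact angles of interest (≈ 25–37°) the spherical-cap correction is
second order.  The `"truncated"` mode subtracts the cap cut off by the
contact plane, $V_\mathrm{cap} = \pi h^2 (R - h/3)$ with
$h = R - \sqrt{R^2 - r^2}$, and is used consistently on the forward
(radii from volumes, by root-finding) and inverse (volumes from radii)
paths.  The bilayer area is held at its initial value by default —
shrinkage is small over a measurement window — with an optional mode that
recomputes it from a fixed contact angle each sample.

### Estimators

* `pf_initial_slope()` fits a straight line to the first `window` volume
  samples and divides the slope by $V_w A_0 \Delta c_0$.  It is exact in
  the noiseless small-time limit; because the driving force decays along
  the window, its downward bias grows monotonically with window length
  (asserted in the tests).
* `pf_fit_trajectory()` minimises the sum of squared radius residuals of
  both droplets against the forward model, over $P_f$ alone, with
  `stats::optimize()` on $[0, P_f^{\max}]$ (`tol = 1e-5` µm/s).  The
  standard error comes from the local curvature of the objective,
  $\mathrm{se} = \sqrt{2\hat\sigma^2 / (d^2 SS/dP_f^2)}$ with the
  curvature estimated by central differences.  A fit that terminates at
  the search boundary raises a non-convergence error carrying the best
  iterate.

A series with equal osmolalities has no identifiable $P_f$; both
estimators raise a cannot-estimate error rather than returning a number.

Drug effects are summarised by `relative_change()`,
$100\,(P_f - P_f^\circ)/P_f^\circ$ rounded to whole percents, the
precision at which such changes are conventionally reported.  Note that
rounding is applied to the quotient of the *given* inputs; pairs of
already-rounded permeabilities can differ by a point from percentages
computed upstream of rounding, and the package makes no attempt to force
agreement in such cases.

## Interfacial energetics

From monolayer tension $\gamma_m$ (mN/m) and contact angle $\theta$
(degrees, converted internally for trigonometry):

$$\gamma_B = 2\gamma_m\cos\theta, \qquad
  \Delta F = 2\gamma_m(\cos\theta - 1) \le 0, \qquad
  \pi = \gamma_m(1-\cos\theta).$$

$\gamma_B + |\Delta F| = 2\gamma_m$ and $|\Delta F| = 2\pi$ are algebraic
identities, tested to machine precision.  The contact angle from droplet
geometry uses the mean half-angle of two contacting spherical caps,
$\theta = \tfrac12[\arcsin(r/R_1) + \arcsin(r/R_2)]$ — symmetric in the
droplets and reducing to $\arcsin(r/R)$ for equal spheres.  This is the
package's chosen geometric convention; it is validated indirectly by the
consistency of the derived $\gamma_B$ and $|\Delta F|$ columns with
published per-condition values across the whole measurement table.
Monolayer tension is always an *input* (pendant-drop tensiometry is out
of scope).  Report rounding follows the conventional precision: tension
to 2 decimals, energy densities to 3.  Both the signed $\Delta F$ and its
absolute value are exposed, since reports conventionally quote
$|\Delta F|$.

## DSC analysis

Heat flow (mW, endothermic-up; a flag flips endothermic-down inputs) is
normalised to molar excess heat capacity
$C_p = \dot q / (\beta\, n_\mathrm{lipid})$ in kcal mol⁻¹ °C⁻¹, with the
scan rate $\beta$ in °C/min.  The baseline is a straight line through the
mean $C_p$ of two flanking windows (default −40…−32 °C and −8…0 °C for
scans of the DOPC transition region); windows must hold ≥ 3 samples and
must not overlap a detected peak.  A linear baseline suffices because the
transition region is narrow; sigmoidal baselines are out of scope.

`transition_params()` reports:

* **Tm** — the apex, refined beyond the grid by a parabolic
  least-squares fit over the upper quartile of the peak (samples ≥ 75 %
  of the maximum).  A symmetric window around a symmetric peak makes the
  vertex estimate unbiased, and fitting many samples rather than the
  3-point apex stencil keeps the estimate stable against noise, whose
  effect on a 3-point parabola grows as the grid refines.  For symmetric
  peaks the recovery error is far below grid spacing (tested at
  spacing/10).
* **ΔH** — trapezoidal integral over the peak support: the contiguous
  region where the corrected curve exceeds
  $\max(3\sigma_\mathrm{noise},\ 1\%\ \mathrm{of\ apex})$, extended
  outward to the baseline crossings.  The noise floor is estimated by the
  MAD of the flanking 10 % of samples.
* **FWHM** — linear interpolation of the half-maximum crossings.

If no sample rises above the noise floor, a no-transition result
(`deltaH = 0`, `Tm = NA`) is returned — the expected outcome for
cholesterol-saturated (1:1) membranes.  More than one sustained run above
half maximum triggers a multi-peak warning; deconvolution of overlapping
transitions is out of scope.  `transition_shift()` reports
$\Delta T_m$ to one decimal and the enthalpy change in whole percents,
matching reporting conventions.

## Raman analysis

Spectra are normalised to the most intense phospholipid band at
2849 cm⁻¹ (windowed maximum; idempotent and scale-invariant).  For
drug-containing mixtures, aspirin bands are removed by scaled reference
subtraction: the pure-ASA reference is resampled to the mixture grid
(linear interpolation), scaled by
$k = I_\mathrm{mix}(1606)/I_\mathrm{ref}(1606)$ — the aromatic C=C
stretch of ASA, a band where the lipid does not scatter — and
subtracted.  A single-anchor scale was chosen over full-spectrum least
squares deliberately: lipid bands would bias a global scale.  Negative
residual intensities are clipped at zero; a clipped fraction above 5 %
warns of over-subtraction.

Order ratios are windowed maxima (± 10 cm⁻¹, clamped to midpoints when
bands crowd) at 2848 (methylene symmetric C–H stretch), 2890 (methylene
asymmetric) and 2930 cm⁻¹ (terminal methyl): increases in
I(2848)/I(2890) and I(2930)/I(2890) indicate chain decoupling and
disordering.  Windowed maxima are robust and parameter-free; a
fitted-band mode could be added without changing the output contract.
No smoothing is applied by default.  Cholesterol-rich C–H regions
(overlapping sterol bands) are not deconvolved — ratio analysis is
restricted to compositions where the three bands are attributable.

## Synthetic data

The generators exist because studies of this kind publish summary values,
not raw traces.  Their defaults *are* the study conditions:

* `default_pf_table()` — true permeabilities (71, 88, 77, 85, 68, 77, 73,
  75, 65, 70, 62, 63 µm/s) for POPC and POPC:cholesterol membranes with
  and without ASA at pH 3 and 7.
* `default_dsc_table()` — (Tm, ΔH) pairs (−17.58 °C/9.59, −18.09/7.67,
  −23.23/1.33, −18.05/6.14, −19.36/3.18 kcal/mol, and a no-transition
  1:1 cholesterol row) with Gaussian peak widths 0.8–1.8 °C growing with
  perturbation, emulating the observed broadening.
* Raman band tables for the lipid (1300, 1440, 1650, 2848, 2890,
  2930 cm⁻¹) and ASA (1240, 1606, 2940, 3080 cm⁻¹) plus a
  disorder parameter that rises linearly with $\chi_\mathrm{ASA}$ —
  steeper at pH 3 (slope 1.0) than pH 7 (0.45), since the uncharged drug
  partitions into the acyl-chain region — shifting the 2848 band up by up
  to 4 cm⁻¹, attenuating 2890 by up to 32 % and strengthening 2930 by up
  to 25 %.  All response shapes (Gaussian peaks, linear dose response)
  are modelling conveniences of the generator, not measured lineshapes.

Noise defaults: multiplicative Gaussian radius noise of 0.2 % (sub-pixel
edge tracking of ~150 µm droplets), additive heat-capacity noise of
0.01 kcal mol⁻¹ °C⁻¹, additive spectral noise of 0.002 of the normalised
peak, plus a 1 % residual fluorescence background on lipid spectra so
intensities stay positive.  Droplet-pair geometry: equal 150 µm droplets,
60 µm contact radius, 300 vs 100 mOsm/kg, sampled every 30 s for 60
samples (~30 min) — a window over which the radius change (~6 %) is well
resolved against the noise.  `gen_study()` writes 8 replicate droplet
pairs per permeability condition and `study_report()` averages their
fits, mirroring bench practice of averaging many independent pairs; this
brings the standard error of each reported permeability to ~0.4 µm/s, the
precision needed to resolve the smallest (1 µm/s) configured effects.

Every generator is a pure function of `(config, seed)`; per-modality
streams are derived from the master seed by fixed offsets so modalities
regenerate independently, and every fixture is written alongside its
ground truth in the manifest.

What the closed-loop tests show — and what they do not: recovery of
generator truths demonstrates that the estimators correctly invert the
package's own forward models at realistic noise, and that the pipeline's
plumbing (units, baselines, subtraction, rounding) is sound.  Real
measurements add physics the generators deliberately omit: droplet
drift and segmentation artifacts, DSC thermal lag and scan-rate
hysteresis, cosmic-ray spikes and wavelength-dependent fluorescence,
solute leakage across imperfect bilayers.  Passing the synthetic suite
does not certify accuracy under those effects.

## Numerical and design notes

* Angles are stored in degrees (reporting units) and converted at the
  trigonometric boundary; tensions in mN/m, energies in mJ/m²,
  permeabilities in µm/s, enthalpies in kcal/mol.
* Truncated-sphere radius inversion uses `uniroot` bracketed above the
  sphere-equivalent radius (`tol = 1e-10`).
* Percent changes round with `round()` (half-to-even); temperatures
  report to two decimals, $\Delta T_m$ to one.
* Degenerate inputs fail loudly with classed conditions
  (`dibkit_invalid_geometry`, `dibkit_domain_error`,
  `dibkit_cannot_estimate`) rather than returning NA.
* File formats are plain text with `# key: value` metadata comments;
  parse errors name the offending line.  The run configuration is YAML
  with unknown keys rejected.
* The package's interface is R functions returning tibbles (with
  `tidy()`/`glance()`/`autoplot()` methods); batch work goes through
  `gen_study()`/`study_report()` rather than a shell entry point.

## Known limitations

* The osmotic model ignores solute permeation, monolayer transport and
  activity corrections; it is a dilute, water-only model.
* The half-angle contact formula assumes spherical caps meeting at a
  thin bilayer rim; strongly asymmetric or gravity-flattened droplets
  violate it.
* The DSC baseline is linear and single-peak extraction only; the Raman
  subtraction assumes the drug reference spectrum is unchanged by the
  membrane environment, which is only approximately true.
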