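---
title: "Methods: a lumped-parameter twin of bioprosthetic valve testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lumped-parameter twin of bioprosthetic valve testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and intent

`valvetwin` is a desk-scale reduced-order model of bioprosthetic aortic
heart valve (BHV) testing in a ViVitro-class pulse duplicator. It couples
four components: (i) anisotropic hyperelastic constitutive models of the
valve leaflets with collagen fiber dispersion, (ii) reduced-order
(Windkessel-type) driving and loading circuits, (iii) a zero-dimensional
valve surrogate, and (iv) a seeded generator of synthetic "experimental"
datasets with the statistical structure of multi-cycle pulse-duplicator
recordings. It deliberately does **not** contain a three-dimensional
fluid--structure-interaction (FSI) solver: the 0D valve surrogate stands in
for the 3D valve, and every place where that substitution matters is called
out below.

# Leaflet mechanics

Leaflets are treated as anisotropic, incompressible, hyperelastic
membranes. The strain energy splits into isochoric and volumetric parts,
$\Psi(\mathbb{F}) = W(\bar{\mathbb{F}}) + U(J)$ with
$\bar{\mathbb{F}} = J^{-1/3}\mathbb{F}$, and the isochoric part combines an
exponential neo-Hookean matrix with a dispersed fiber family:

$$W_{\mathrm{iso}} = C_{10}\{\exp[C_{01}(\bar I_1 - 3)] - 1\}, \qquad
W_{\mathrm{aniso}} = \frac{k_1}{2k_2}\{\exp[k_2 E^2] - 1\},$$

where $E = \kappa \bar I_1 + (1-3\kappa)\bar I_4^\star - 1$ and
$\bar I_4^\star = \max(\bar I_4, 1)$ clamps the fiber contribution to
extension. The dispersion $\kappa \in [0, 1/3]$ interpolates between
perfectly aligned fibers ($\kappa = 0$) and an isotropic fiber distribution
($\kappa = 1/3$); the isotropy limit is verified to machine precision in the
tests. $U(J) = \beta(J\ln J - J + 1)$ is a volumetric stabilization term.

Two fitted parameter sets ship as presets: a glutaraldehyde-fixed porcine
aortic valve ($C_{10} = 0.302$ kPa, $C_{01} = 3.25$, $k_1 = 0.197$ MPa,
$k_2 = 0.001$, $\kappa = 0$) and a bovine pericardial valve
($C_{10} = 0.119$ kPa, $C_{01} = 22.59$, $k_1 = 2.38$ MPa, $k_2 = 149.8$,
$\kappa = 0.292$, mean fiber angle 45° in-plane), with
$\beta = 14.1$ MPa.

Numerical choices:

* The fiber term uses the `expm1` primitive, so the porcine $k_2 = 0.001$
  does not suffer catastrophic cancellation in the
  $\tfrac{k_1}{2k_2}(\exp(k_2E^2)-1)$ prefactor; at $k_2 = 0$ exactly, the
  analytic limit $\tfrac{k_1}{2}E^2$ is used.
* Stresses are kPa internally; $k_1$ and $\beta$ are converted from MPa on
  construction. Circuit pressures are mmHg; the Bernoulli law converts via
  1 mmHg = 1333.22 dyn/cm².
* The first Piola--Kirchhoff stress is analytic
  ($\mathbb{P} = \partial\Psi/\partial\mathbb{F}$) and verified against
  central finite differences of the energy to better than $10^{-6}$
  relative error on random volume-preserving deformations.
* $k_2 E^2 > 700$ would overflow `exp`; this raises an explicit error
  naming the offending fourth invariant rather than returning `Inf`.
* Membrane (plane-stress) computations treat the tissue as exactly
  incompressible, $F = \mathrm{diag}(\lambda_1, \lambda_2,
  (\lambda_1\lambda_2)^{-1})$, with the out-of-plane normal stress
  eliminated by the incompressibility pressure. $\beta$ is inactive there
  (it acts only at $J \ne 1$) and is retained for full 3D states.

## Biaxial fitting

`fit_material_params()` minimizes unweighted squared stress residuals
(σ₁₁ and σ₂₂ stacked across protocols, kPa) with Levenberg--Marquardt,
restarted from bounds-scaled random initial points. Unweighted stress least
squares is a deliberate choice: the original fitting objective for these
presets (stress vs. tension residuals, per-protocol weighting) is not
published, so the simplest defensible objective is used and stated.
Because the historical biaxial tables are not deposited, fitting is
exercised against synthetic data from `gen_biaxial_dataset()`: an
equibiaxial path $\lambda \in [1, 1.15]$ plus two constrained strip-biaxial
paths ($\lambda_2 = 1$, then $\lambda_1 = 1$), 30 points each — a protocol
set chosen to make $\kappa$ and $k_2$ identifiable. With a single protocol
and free $\kappa$ the fitter warns about non-identifiability. Noise-free
recovery is exact to well under 1%; under 2% multiplicative noise the
median $k_1$ error stays below 15% across replicates.

# Reduced-order circuits

Both platforms load the aortic side with a three-element Windkessel
(R--C--R): characteristic resistance $R_c$, compliance $C$, peripheral
resistance $R_p$, ground at 0 mmHg. Printed compliance magnitudes are
interpreted as mL/mmHg (the physiological convention; the values 0.915 and
1.27 only make sense on that scale). Downstream values: porcine
$R_c = 0.0218$, $R_p = 1.31$, $C = 0.915$; pericardial $R_c = 0.0282$,
$R_p = 1.22$, $C = 1.27$ (resistances mmHg·s/mL).

Upstream, the porcine platform is driven by a pressure source through
$R_1 = 0.15$, a VIA (viscoelastic impedance adapter) compliance
$C_{VIA} = 0.1$ to ground, and $R_2 = 0.15$ into the ventricular node. The
published schematic does not fix a unique netlist, so the topology is
declared in the configuration and alternatives are testable. The
ventricular node needs a state to be well posed; a small regularizing
compliance $C_{LV} = 0.02$ mL/mmHg is introduced (a modeling device, not a
printed value) and its influence on stroke volume is at the 0.1% level.

The pericardial platform has a richer upstream description: a flow-source
piston into node V1 ($C_{VIA_1} = 0.0275$), $R_{VIA} = 0.15$ into node V2
($C_{VIA_2} = 0.0347$) which is the ventricular node, an atrial pressure
source through a mitral diode ($R_{MV} = 0.0280$, softplus-smoothed with
width 0.01 mmHg), and a return resistance $R_{out} = 0.0898$. The placement
of $R_{out}$ is not stated in the source text; the default connects V1 to
ground and the alternative (V2 to ground) is selectable in the
configuration.

## Integration

The coupled system is integrated with `deSolve`'s lsoda at 70 beats per
minute, cycle by cycle, until the relative L2 distance between consecutive
cycles falls below $10^{-4}$; the converged cycle is returned on a uniform
1 kHz grid covering one period (half-open, $T = 60/70$ s). lsoda is used
rather than a plain explicit Runge--Kutta scheme because the nearly-closed
valve (leak area 0.1% of the orifice) makes the valve-flow equation stiff,
with local time constants near $10^{-5}$ s; a stiff/non-stiff switching
integrator handles this at ordinary cost, and halving the maximum step
changes the converged cycle by less than 0.1%. Initial pressures (aortic
store 80 mmHg, others 10 mmHg) only speed convergence; the periodic
solution is independent of them. With the valve replaced by a linear
resistance the simulated periodic state matches an independent
frequency-domain (complex nodal analysis) solution to better than 0.5%,
and volume balance at every compliance node closes to within 0.1% of the
stroke volume per converged cycle.

# The 0D valve surrogate

The source experiments resolve the valve in 3D; a 0D twin needs an
explicit valve law, so the surrogate is an honest modeling substitution,
not a reproduction. It has three ingredients:

* **Opening dynamics** (Mynard-type): $\dot\theta = k_{open}(1-\theta)\,
  \Delta p$ for $\Delta p \ge 0$, $\dot\theta = k_{close}\theta\,\Delta p$
  otherwise, with $\theta \in [0,1]$. Defaults $k_{open} = k_{close} =
  5\,/(\mathrm{mmHg\,s})$ give opening/closing time constants of
  10--20 ms at typical transvalvular pressures, consistent with valves
  that open and close within a few tens of milliseconds. (A rate of
  0.3 /(mmHg·s) would give ~170 ms transients, which would let the opening
  transient dominate the forward pressure difference; both rates are
  exposed in the configuration.)
* **Orifice law**: $\Delta p = \frac{\rho}{2} \frac{q|q|}{A_{eff}^2} +
  L\dot q$, with $A_{eff} = A_{leak} + (A_{max}-A_{leak})\theta$,
  inertance $L = 5\times10^{-4}$ mmHg·s²/mL, and $A_{leak} =
  0.001\,A_{max}$ (the valve is modeled as nearly competent).
  $A_{max}$ is set by the Gorlin/Bernoulli inversion
  `calibrate_eoa()`: $EOA = q_{peak}\sqrt{\rho/(2\Delta p_{peak})}$,
  evaluated at the printed peak operating points (porcine: 452.5 mL/s at
  22.4 mmHg → 1.85 cm²; pericardial: 425.1 mL/s at 16.4 mmHg → 2.03 cm²).
  The preset peak flows are the values implied by the printed peak
  Reynolds numbers with the 28 mm test section and saline.
* **Diastolic membrane state**: a quasi-static spherical-cap Laplace
  balance $T(\lambda) = \Delta p\,R_{cap}/2$ with
  $T(\lambda) = t\,\sigma_{biax}(\lambda)$ from the constitutive law,
  solved by bracketing bisection. This exercises the leaflet model under
  diastolic load (cap radius 1.25 cm and thickness 0.04 cm are surrogate
  geometry for a 25 mm BHV).

The PDVA (projected dynamic valve area) proxy is proportional scaling,
$PDVA = (EOA/0.7)\,\theta(t)$, using a conventional discharge coefficient
of 0.7 — a surrogate convention, not a measured relation. Leaflet flutter
is *not* produced by the surrogate; it appears only in the synthetic
experiment generator, mirroring the fact that flutter lives in the
measured data, not in this class of reduced model.

# Synthetic experiments

`gen_experiment()` emulates a multi-cycle recording at the preset operating
conditions: 70 bpm; porcine targets 69.4 ± 0.4 mL forward stroke volume
and 22.8 ± 0.2 mmHg peak forward pressure difference; pericardial targets
71.6 ± 0.7 mL and 19.7 ± 0.5 mmHg; peak flows 452.5 and 425.1 mL/s. The
± values are treated as cycle-to-cycle standard deviations over the
10-cycle recordings (they could alternatively be read as 95% half-widths;
the SD reading is the generator's stated convention).

The generator first calibrates the twin to the preset operating point by a
fixed-point loop over three driver/valve knobs — pulse amplitude, systolic
width, and pulse flatness (a shape exponent on the sin² pulse), plus a
Bernoulli rescaling of the orifice area against the pressure-difference
target — converging each iteration from a warm-started periodic run. It
then emulates measurement: one multiplicative amplitude factor per cycle
(independently for flow and pressures, CV = SD/mean from the preset — the
simplest noise model reproducing the printed ± values), additive white
sensor noise, zero-phase 4th-order Butterworth filtering at 100 Hz applied
per platform convention (porcine: pressures and flow; pericardial: flow
only; PDVA never filtered), and a damped 40 Hz flutter oscillation with
random phase added to the systolic PDVA plateau (flutter frequency and
amplitude are free parameters; no printed values exist for them). All
randomness flows through one seed recorded in the dataset metadata, and a
fixed seed reproduces files byte-for-byte.

What the generator does *not* emulate: baseline drift, beat-to-beat shape
(as opposed to amplitude) variation, correlated sensor noise, and the
within-beat waveform fine structure of a real pulse duplicator. Passing
tests therefore demonstrate internal consistency of the pipeline at the
printed operating points, not agreement with any new experimental data.

# Validation metrics

`discrepancy()` implements the normalized discrepancy
$\Delta M_q = \|M^{sim} - M^{exp}\|_{L^q(0,T)} / \|M^{exp}\|_{L^q(0,T)}$
for $q = 2, \infty$, with trapezoidal quadrature on the reference 1 kHz
grid and linear resampling of the simulation; norms are computed over one
converged cycle. Stroke volume is the forward (positive-part) flow
integral per cycle — the hydrodynamic-assessment convention — with the net
volume also available since the printed definition is not explicit.
`max_forward_dp()` masks to samples with positive aortic flow.
`re_peak()` computes $Re_{peak} = \rho Q_{peak} D / (\mu A)$ with
$A = \pi D^2/4$, D = 2.8 cm, and cP→poise conversion. Ensemble statistics
are the pointwise mean and central 95% band across phase-aligned cycles.
Before comparison, simulated cycles are circularly shifted to align
valve-opening onset (first upcrossing of 5% of peak flow) with the
experimental mean, mirroring the alignment convention of pulse-duplicator
comparisons.

# Problem sizes and reproduction

The shipped analysis sizes are: 50-cycle synthetic datasets for the
scalar-summary reproduction (standard errors of the preset SDs over 50
cycles are well below the comparison tolerances), 200 cycles for the
law-of-large-numbers checks, 20 replicates for the noisy fitting study,
and 1 kHz output sampling of a 0.857 s cycle. `scripts/acceptance.R`
re-runs the whole chain — generator calibration, synthetic datasets for
both platforms, the calibrated porcine twin, and the Reynolds-number
arithmetic — from a single seed and writes the resulting scalars as JSON.

# Known limitations

* The valve surrogate has no 3D kinematics: no per-leaflet closure order,
  no commissural stress concentrations, no flutter mechanics.
* Viscoelasticity of the fixed tissue is not modeled (the constitutive
  law is hyperelastic).
* The fitted-parameter recovery study uses synthetic biaxial protocols in
  place of the original (undeposited) tensile-test tables.
* The upstream netlists are schematic reconstructions with two documented
  free choices ($C_{LV}$, $R_{out}$ placement), both exposed in the
  configuration.
* Effective orifice area and regurgitant fraction per ISO 5840 are not
  implemented.
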