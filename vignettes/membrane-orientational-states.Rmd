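---
title: "Orientational states of a membrane-anchored GTPase domain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientational states of a membrane-anchored GTPase domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memstates)
```

## The problem

A myristoylated small GTPase anchors to a bilayer through its N-terminal
amphipathic helix while its folded G domain remains tethered above the
membrane surface, mobile enough to exchange between several preferred
orientations. Three linked NMR observables report on this arrangement:

* **Methyl PRE profiles.** Nitroxide-labelled lipids (e.g. 5-doxyl PC) form a
  planar layer of unpaired electrons below the headgroups. Each methyl
  reporter's intensity ratio I/I0 between paramagnetic and diamagnetic
  samples encodes its time-averaged proximity to that layer, so the pattern
  of ratios across the G domain encodes height *and* orientation.
* **Solid-state ²H spectra** of the acyl chains give segmental order
  parameters and, through a mean-torque model, chain extension profiles that
  report how deeply the myristoyl anchor embeds.
* **TRACT relaxation** gives the G domain's rotational correlation time,
  distinguishing a domain tumbling semi-independently from one rigidly
  attached to the (much larger) nanodisc.

`memstates` implements the quantitative core of this analysis: PRE
back-calculation for conformers in a fixed membrane frame, fixed-size
ensemble selection against measured PRE profiles with noise-perturbed
repeats, orientational-state statistics and potentials of mean force, the
²H order/extension analytics, and correlation-time utilities. A synthetic
data module generates every input with known ground truth, which is how the
package validates itself.

## Membrane frame and orientation convention

All geometry lives in a fixed frame: the membrane normal is +z and z = 0 is
the phosphate plane of the protein-side leaflet. Heights may be negative
(inserted below the plane).

A conformer's orientation is extracted by least-squares (Kabsch)
superposition of its G-domain reporters onto a reference conformer. The
reference's **principal-axes body frame** (largest-variance axis = body z,
tie-broken toward the membrane normal; second axis = body x, toward membrane
x) is rotated by the extracted rotation, and we report

* **β** — the polar angle of the rotated body z axis against the membrane
  normal (0–180°), and
* **γ** — the azimuth of the rotated body x axis about the normal, measured
  from the membrane x axis, in [0, 360).

This convention is a package choice: collective-variable definitions differ
between analyses, so `compute_orientation()` exposes `beta_offset` /
`gamma_offset` calibration parameters rather than guessing any particular
external convention. Note one property of the convention itself: when the
body z axis points below the membrane plane (β > 90°) the reported azimuth
is rotated by 180° relative to the naive spin angle; the synthetic
generator and the state definitions both live at β < 90° where the mapping
is direct.

The default orientational states are rectangular (β, γ) bins:
S1 (β 57–73°, γ 115–187°, the "occluded" pose with the switch-I face toward
the bilayer), S2 (β 8–20°, γ 64–118°) and S3 (β 20–30°, γ 0–50°, switches
exposed). γ intervals live on the circle, so ranges past 360° wrap and the
printed 115–187° range is honoured without clipping at 180°. Overlapping
state definitions are rejected at load time; a shared single β edge with
disjoint γ (as with S2/S3 at β = 20°) is allowed.

PMF surfaces are histogram-based: F(bin) = −k~B~T ln(count/count~max~), so
the most populated bin is exactly 0 and occupied bins are non-negative.
Empty bins are *unvisited*, serialized as NA — never 0 and never an infinite
stand-in value.

## PRE model

The labels diffuse laterally much faster than the PRE builds up, so the
relaxing field is modelled as a uniform plane of electron density rather
than discrete label positions. Integrating the Solomon–Bloembergen r⁻⁶
interaction over a plane at perpendicular distance Δ gives

Γ₂(Δ) = K σ π / (2 Δ⁴),  K = (1/15)(μ₀/4π)² γ~H~² g~e~² μ~B~² S(S+1) [4J(0) + 3J(ω~H~)],

with J(ω) = τ/(1+ω²τ²) and S = 1/2. K is always recomputed from physical
constants. A second term with Δ′ = z + d~PP~ − d adds the trans leaflet.
`gamma2_discrete()` is the brute-force oracle: the same kernel summed over
an explicit square lattice of point labels; at 0.5 Å spacing and a cutoff of
100 Δ it agrees with the closed form to ~10⁻⁶ relative (the residual is the
truncated tail, (Δ/cutoff)⁴).

Intensities attenuate as I/I0 = R₂,dia e^(−Γ₂ t) / (R₂,dia + Γ₂): line
broadening plus loss during the transfer periods. Defaults (τ~PRE~ = 5 ns,
850 MHz, R₂,dia = 20 s⁻¹, t = 8 ms, σ = 0.05/65 Å⁻², label depth 8 Å,
phosphate separation 38 Å) are conventional methyl-TROSY-era values and
bilayer geometry; every one is configuration, not physics baked into the
code. Reporters at or below the label plane are *bleached* (ratio 0, with a
warning) rather than an error, so deeply inserted helix methyls remain
representable.

Ensemble profiles average under **fast exchange**: Γ₂ is weight-averaged per
reporter before a single intensity conversion. Direct intensity averaging is
kept as an option; by Jensen's inequality it always gives the larger ratio,
which the tests verify numerically.

## Ensemble selection

The fit selects a multiset of N = 16 conformers (repetition allowed,
uniform weights 1/N) minimising

χ² = Σ~j~ ((I/I0)~calc,j~ − (I/I0)~meas,j~)² / σ~j~²,

over the reporters present in the measurement table, with σ~j~ the
propagated intensity error floored at 0.01 to avoid division blow-ups.

The default search is **exhaustive best-single-swap coordinate descent**:
from a random start (the first restart uses a greedy forward construction),
every position is repeatedly offered its best replacement over the whole
library until no swap improves, over 20 restarts. A random-proposal hill
climb (`search_method = "proposals"`) is retained for comparison; the sweep
variant was adopted as default because it reaches substantially lower χ² for
the same budget and is deterministic given the seed.

When the best fit lands in the near-exact regime (χ² per reporter below
`polish_threshold`) an additional polish phase runs: solutions supported on
one, two or three distinct conformers are enumerated exactly (the third
member located by a two-pointer match on a fixed scalar projection of the
summed rates), followed by joint two-member repairs alternated with sweeps.
This phase exists because noise-free profiles generated by ensembles that
concentrate on a few recurring conformations — the situation the best-fit
ensembles themselves produce — can then be refit to χ² = 0 exactly. For
*diffuse* generating multisets (16 distinct members) the noise-free optimum
is massively degenerate: alternative multisets sharing no members with the
generator fit to χ² ~ 10⁻⁵, and no local search can be expected to find the
exact needle. The package's planted-solution tests therefore certify
concentrated ensembles; with noisy data the polish phase is skipped
automatically because the optimum sits orders of magnitude above the
threshold.

### Repeats and populations

`repeat_selection()` refits the ensemble 100 times (default), each time
perturbing every measured ratio with independent Gaussian noise of SD =
15% × ratio, and reports per-state population means ± SD, the per-repeat
fractions (multiples of 1/16), and the ensemble COM height. Each repeat's
randomness derives from (seed, repeat index), so results are bit-identical
across runs and safely parallelisable.

Two protocol details were deliberate design choices:

* **Perturbed ratios are clipped at 0 only.** Intensity ratios above 1 occur
  in real spectra through noise. Truncating the perturbation at 1 silently
  shifts every high reporter down by up to several percent per repeat, which
  drags the refit ensembles toward the membrane and, in our benchmarks,
  collapsed the population of the highest state almost to zero.
* **Refit weights include the injected noise**, σ~eff~² = σ~meas~² +
  (0.15 × ratio)². The perturbed data carry that error by construction;
  weighting them by the much smaller spectral error alone makes every refit
  chase individual noise excursions and destabilises the populations.

Population differences between two conditions are tested with a two-sided
Welch t-test on the per-repeat fractions (`compare_populations()`).

### What recovery does and does not show

The three-state benchmark (library of 2000 conformers, truth fractions
20/30/50%, state height means 18/22/26 Å, 15% noise, N = 16, 100 repeats)
recovers each population within ±2 reported SD, with no unassigned members
and the mean ensemble COM within 2 Å of truth. The reported SDs are large
(~30 percentage points): under 15% noise the fit is genuinely degenerate
between neighbouring states — a low S1 member can supply the same mean
relaxation as several mid-height members — and individual repeats swing
between S2-heavy and S3-heavy compositions while the mean stays near truth.
This is a property of the observable, not of the optimizer: PRE constrains
the *ensemble-averaged* rate profile, and composition beyond that is only
weakly identified. Real data, with reporter-specific side-chain geometry
and more graded height contrast, may be more or less informative than the
synthetic stand-in; passing the benchmark shows the machinery is unbiased
and calibrated, not that any particular experimental dataset pins its
populations tightly.

## Deuterium order analytics

Pake-doublet splittings convert to segmental order parameters as
|S~CD~| = Δν / (0.75 χ~Q~), with χ~Q~ = 167 kHz by default and the 3/4
factor for the 90° powder edges; methyl groups gain an additional factor
1/3 from fast C₃ rotation. These constants are configuration
(`quadrupole_params()`), since conventions differ between laboratories.

Smoothed profiles use plateau assignment: resolved |S| values are sorted
descending and assigned from the upper chain toward the terminal methyl,
with unresolved positions filled by shape-preserving monotone (Hyman)
interpolation — the result is always non-increasing toward the chain end.

Chain extension uses the first-order mean-torque closed form,
⟨cos β~i~⟩ = (1 + √((8|S~i~| − 1)/3))/2, valid for |S| ≥ 1/8; below that
the model leaves its domain and the package applies the flagged fallback
⟨cos β⟩ = 1/2 rather than extrapolating. Per-segment travel is 1.27 Å ×
⟨cos β⟩ and cumulative extension is measured from the terminal CH₃, placed
at 0 by convention (so only slopes, not offsets, compare between chains).
Limits worth remembering: |S| = 0.5 → 1.27 Å (all-trans), |S| = 0.25 →
1.00162 Å, |S| = 1/8 → 0.635 Å.

Zeeman-order inversion-recovery series fit I(t) = I∞(1 − 2f e^(−R₁Z t)) by
Levenberg–Marquardt with a 95% t-based confidence interval on R₁Z; the
default delay schedule is the conventional 11-point series from 1 ms to
1.8 s. Square-law tables pair R₁Z with S² and are deliberately left unfitted
— the curvature of R₁Z vs S² is itself the diagnostic of membrane
elasticity. Order parameters can also be computed directly from trajectory
C–H unit vectors as ⟨(3cos²θ − 1)/2⟩.

## Rotational correlation times

TRACT decays are fitted as independent mono-exponentials for the TROSY (α)
and anti-TROSY (β) components; the rate difference ΔR = 2η~xy~ is inverted
for τ~c~ by monotone root-finding, with the ¹⁵N CSA/dipole cross-correlated
rate built from conventional constants (r~NH~ = 1.02 Å, Δσ = 160 ppm,
θ = 17°, rigid isotropic rotor with J(ω) = (2/5)τ/(1+ω²τ²)). The inversion
round-trips to 0.1% over 5–100 ns.

The hydrodynamic estimate is Stokes–Einstein–Debye with a hydration shell:
r = (3Mv̄/4πN~A~)^{1/3} + 3.2 Å, τ~c~ = 4πηr³/3k~B~T. For a 21 kDa domain
at 25 °C in H₂O this gives ≈ 8.9 ns; empirical correlations quoted for
proteins of this size run somewhat higher (~13 ns), and the package reports
the closed-form value without forcing agreement — the hydration shell and
v̄ are parameters for exactly this reason.

Temperature rescaling uses τ~c~(T₂) = τ~c~(T₁)·(η(T₂)/η(T₁))·(T₁/T₂) with
embedded viscosity tables for light water (standard reference values,
linearly interpolated) and heavy water (the H₂O table times an interpolated
heavy/light viscosity ratio — an approximation adequate for rescaling
ratios, flagged here rather than hidden). A 34 ns correlation time measured
at 45 °C corresponds to ≈ 54–56 ns at 25 °C depending on the solvent table;
samples in D₂O buffer motivate providing both.

## The synthetic-data module

`make_toy_domain()` builds a rigid stand-in for the G domain: 41 methyl
reporters on an anisotropic shell (per-axis spreads 0.55/0.45/0.72 × radius,
sign-symmetrised so the principal axes coincide *exactly* with the membrane
axes in the reference pose) plus 3 helix reporters on a line 6.5 Å below the
phosphate plane — 44 reporters in all, matching the scale of a real
methyl-labelled construct. `sample_library()` draws conformers from a
three-state truth mixture: a state per the truth fractions, an orientation
uniform within the state's (β, γ) bins (the rotation is built in the
reference body frame, so orientation extraction recovers the sampled angles
exactly and state labels close the loop with probability 1), and a G-domain
height from the state's Gaussian (means 18/22/26 Å, SD 1.5 Å by default —
separable but overlapping PRE signatures; heights that would push a
reporter below the label plane are resampled). The helix stays put: it is
the anchor.

What the generator does *not* emulate: side-chain rotamer averaging,
per-reporter mobility (order-parameter scaling of the PRE), correlated
noise between reporters, and conformer geometries beyond a rigid body.
Conclusions from passing tests are therefore about the correctness and
calibration of the machinery, not about the information content of any real
dataset.

Every generator is a pure function of (spec, seed); problem sizes in the
package's own validation (library 2000, truth sample 400, 100 repeats,
20 certificate seeds, 100-seed fitter-bias checks) were chosen to make
sampling error comfortably smaller than the tolerances being checked.

## Numerical choices and degenerate inputs

* Kabsch superposition uses SVD with a determinant correction, so proper
  rotations are returned even for reflective optima; fewer than 3 shared
  reporters or collinear geometry is an error naming the conformer.
* Principal-axis ties break by descending eigenvalue, then the sign fixes
  (body z toward membrane +z, body x toward membrane +x).
* β is clamped to [0, 180] after `acos` rounding; γ arithmetic is modulo
  360 throughout.
* χ² comparisons in the search use a 10⁻¹⁵ strict-improvement margin; the
  polish phase's projection shortlist uses a tolerance at the floating-point
  cancellation scale of the summed rates, and every shortlisted candidate is
  accepted or rejected on the true objective only.
* Mono-exponential fits initialise from a log-linear regression where
  intensities allow, and inversion-recovery fits from the terminal
  intensity; non-convergence is an error, not a silent NA.
* Viscosity lookups refuse temperatures outside the tabulated 0(5)–100 °C
  range rather than extrapolating.

## Known limitations

* PRE back-calculation is distance-to-plane only: no order-parameter
  scaling, no discrete label rotamers, no curvature (nanodisc edge) effects.
* Ensemble weights are uniform 1/N multisets; continuous reweighting
  (maximum-entropy or Bayesian) is out of scope.
* Population identifiability under 15% noise is intrinsically weak (large
  per-repeat SDs); the repeats quantify that honestly rather than hiding it.
* The ²H module starts from picked splittings; no de-Pake-ing or spectral
  processing.
* Isotropic rotational diffusion only; no anisotropic tensors or
  model-free analysis.
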