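# memstates

Orientational-state analysis for lipid-anchored GTPase domains hovering over
a membrane, from NMR observables.

A myristoylated small GTPase binds a bilayer through its N-terminal
amphipathic helix while the folded G domain stays tethered above the
surface, exchanging between a few preferred orientations. `memstates`
implements the quantitative pipeline that turns three kinds of NMR data into
a picture of that ensemble:

* **PRE back-calculation** — for a conformer held above a planar layer of
  nitroxide-labelled lipids, the Solomon–Bloembergen interaction integrated
  over the label plane gives each methyl reporter's extra relaxation,
  Γ₂(Δ) = K σ π / (2Δ⁴), and intensity ratio
  I/I₀ = R₂ e^(−Γ₂t)/(R₂+Γ₂). A brute-force lattice-sum oracle validates
  the closed form.
* **Ensemble selection** — a fixed-size multiset of N = 16 conformers
  (uniform weights, fast-exchange averaging of Γ₂) is selected from a
  library to minimise χ² = Σⱼ((I/I₀)ᶜᵃˡᶜⱼ − (I/I₀)ᵐᵉᵃˢⱼ)²/σⱼ² against a
  measured profile; 100 noise-perturbed refits (15% multiplicative error)
  give per-state populations ± SD, compared between conditions with a
  Welch t-test.
* **Orientation statistics** — tilt/spin angles (β, γ) extracted by Kabsch
  superposition in a fixed membrane frame, assignment to the S1/S2/S3
  orientational states, and potentials of mean force
  F = −k_BT ln(n/n_max) over angle space.
* **²H chain order** — Pake splittings to |S_CD| = Δν/(0.75 χ_Q), smoothed
  monotone profiles, mean-torque chain extension
  ⟨cos β⟩ = (1 + √((8|S|−1)/3))/2 with 1.27 Å per segment, inversion-recovery
  R₁Z fits, and square-law (R₁Z vs S²) tables.
* **Rotational correlation times** — TRACT rate differences inverted through
  the ¹⁵N CSA/dipole cross-correlated rate, Stokes–Einstein–Debye estimates,
  and temperature/viscosity rescaling τ(T₂) = τ(T₁)·(η₂/η₁)·(T₁/T₂).

Everything the pipeline consumes can be generated with known ground truth by
the built-in synthetic-data module, which is how the package validates
itself end to end.

## Worked example

Simulate a three-state library, generate a measurement from a known truth
ensemble, and recover its populations:

```r
library(memstates)

ref   <- make_toy_domain()                      # 44-reporter rigid stand-in
truth <- truth_ensemble(fractions = c(S1 = 0.2, S2 = 0.3, S3 = 0.5), seed = 101)
lib   <- sample_library(ref, truth, 2000)       # conformer library + labels
clib  <- conformer_library(lib$conformers, ref) # precomputed PRE responses

truth_samp <- sample_library(ref, truth_ensemble(
  fractions = c(S1 = 0.2, S2 = 0.3, S3 = 0.5), seed = 202), 400)
meas <- simulate_pre_measurement(truth_samp$conformers, noise_fraction = 0, seed = 7)

summ <- repeat_selection(clib, meas, fit_config(seed = 5))
summ
#> <population_summary> 100 repeats
#>   S1          29.8% +/- 31.8
#>   S2          34.9% +/- 35.6
#>   S3          35.2% +/- 35.7
#>   unassigned   0.0% +/- 0.0
#>   ensemble COM 24.1 +/- 3.0 A; median chi2 37.02
```

The truth sample's label fractions were 23.5/27.2/49.2% with a G-domain
centre-of-mass height of 23.1 Å: each recovered population lands within its
reported spread, no members fall outside the state bins, and the mean
ensemble height tracks the truth within ~1 Å. The large per-repeat SDs are
real: under 15% noise, PRE constrains the ensemble-averaged relaxation
profile tightly but the state composition behind it only loosely, and the
repeat protocol quantifies exactly that.

Single quantities follow the same grammar:

```r
rescale_tauc(34, 318.15, 298.15, "heavy_water")$tau_c_ns  # 55.6 ns
chain_extension(order_profile(2:4, c(0.5, 0.25, 0.125)))$travel_A
# 1.270000 1.001617 0.635000
```

A thin command-line wrapper (`inst/cli/memstates.R`) exposes the stages as
subcommands (`simulate`, `fit-ensemble`, `pmf`, `order`, `tauc`, ...); see
`?cli_main`.

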