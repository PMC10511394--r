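---
title: "Constituent-based quasi-linear viscoelasticity for arterial walls: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constituent-based quasi-linear viscoelasticity for arterial walls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbqlv)
```

## The problem

Arteries stiffen under dynamic (pulsatile) loading compared with slow
quasi-static loading, and the amount of stiffening and of energy
dissipation depends strongly on the operating pressure. Classical
quasi-linear viscoelasticity (QLV) cannot reproduce this pressure
dependence: a single reduced relaxation function applied to the whole
tissue makes the dynamic-to-static stiffness ratio a function of loading
frequency alone. This package implements a constituent-based variant
(cbQLV) in which QLV is applied separately to the two main load-bearing
constituents of the wall — the elastin-dominated isotropic matrix and four
collagen fibre families. Each constituent keeps a deformation-independent
relaxation spectrum, but because the constituents' shares of the total
stress shift with deformation (elastin dominates at low pressure, collagen
is recruited at high pressure), the tissue-level viscoelasticity becomes
fully nonlinear with a single, deformation-independent parameter set.

## Kinematics

The vessel is a thin incompressible cylindrical membrane. All stretches
refer to the in-vivo reference configuration `κ_r` — the vessel at
100 mmHg and the in-vivo axial length `l_iv` — rather than the unloaded
state `κ_u`; `vessel_geometry()` derives the unloaded prestretches
(`Λ_Z = L_0/l_iv`, `Λ_Θ` from wall-volume conservation) and
`current_deformation()` maps a measured outer radius and length to the
mid-wall principal stretches `(λ_r, λ_θ, λ_z)` with
`λ_r λ_θ λ_z = 1`. Deformations are orthotropic (no twist). A utility,
`stretch_rel_unloaded()`, converts to unloaded-referred stretches for
reporting; internally everything stays referred to `κ_r`.

## Elastic law

The strain energy is a four-fibre-family function:
`Ψ_e = (μ/2)(I_{1,e} − 3)^{1+β}` for the matrix, with elastin deposition
stretches `λ_{θ,e}`, `λ_{z,e}` entering through a unit-determinant
deposition tensor, and
`Ψ_c = Σ_i k_1/(4 k_2^i) [exp(k_2^i (I_4^i − 1)^2) − 1]` over axial,
circumferential and two symmetric diagonal families, with a common
deposition stretch `λ_c` along each fibre. A compressed family
(`I_4 < 1`) swaps its `k_2` for the tiny `k2_comp`, which keeps the
stress slope continuous at the switch and makes the compressive response
nearly quadratic. `β = 0.15` (nearly neo-Hookean matrix) and
`k2_comp = 1e-6` are fixed defaults.

Two details are worth making explicit:

* **Diagonal-family invariant.** Applying the deposition-stretch tensor
  built from `λ_c sin α` and `λ_c cos α` entries literally gives
  `I_4 = λ_c^2(λ_θ^2 sin^4 α + λ_z^2 cos^4 α)` for the diagonal families,
  which is inconsistent with `λ_c` being the deposition stretch *along
  the fibre* (it would give `I_4 ≠ λ_c^2` in the reference state). The
  package uses the standard form
  `I_4 = λ_c^2(λ_θ^2 sin^2 α + λ_z^2 cos^2 α)`, which agrees with the
  literal form at 0° and 90°; the literal form remains available behind
  the `literal_diag_invariant` flag for sensitivity checks.

* **Incompressibility multipliers.** The Cauchy stress carries one
  Lagrange multiplier per constituent. These are not fixed by the theory,
  so the package closes them with the membrane convention applied *per
  constituent*: each `p_j` is chosen so that the constituent's radial
  Cauchy stress vanishes, making `σ_rr ≡ 0` identically. Luminal pressure
  and axial force depend only on stress differences
  (`(σ_θθ − σ_rr) h/r_m` and `π(2σ_zz − σ_θθ − σ_rr) r_m h`), so all
  observables are invariant to this choice; the closure simply makes the
  per-constituent stresses well-defined for reporting.

## Relaxation kernel and hereditary integral

Each constituent has a continuous-spectrum (structural-damping) reduced
relaxation function

`Q(t) = [1 + ν (E_1(t/τ_2) − E_1(t/τ_1))] / [1 + ν ln(τ_2/τ_1)]`,

with `Q(0) = 1` handled analytically, plateau
`Q(∞) = [1 + ν ln(τ_2/τ_1)]^{-1}`, and a nearly frequency-flat loss
between `1/τ_2` and `1/τ_1`. `τ_1` is fixed at `1e-3` s for both
constituents (just above the inverse of the highest loading frequency of
interest); `ν` and `τ_2` are constituent-specific. The exponential
integral `E_1` is evaluated in-package by a power series for `x ≤ 1` and
a modified-Lentz continued fraction for `x > 1`, accurate to better than
`1e-12` (verified against adaptive quadrature in the tests).

The stress is the hereditary integral of the elastic stress rate, per
constituent:

`σ_ii(t) = {S_ii(0) + Σ_j ∫_0^t Q_j(t − s) d/ds[Ŝ_ii,j(s)] ds} λ_i^2(t)`,

where `Ŝ_ii,j` is constituent `j`'s elastic hat stress (extra stress plus
its membrane-closure Lagrange term, evaluated instantaneously — which
keeps `σ_rr(t) ≡ 0` exactly at all times) and `S(0)` assumes complete
relaxation of the prior history: each constituent's hat stress scaled by
its `Q_j(∞)`. In sQLV mode both constituents share one kernel, which is
the classical whole-tissue QLV.

**Discretisation.** Histories are uniform in time. Hat stresses are
evaluated at the sample points, increments between consecutive samples
are convolved with the kernel evaluated at interval midpoints
(`Q((m − 1/2)Δt)`), a midpoint rule that is second-order accurate; the
tests verify the `O(Δt^2)` rate against adaptive quadrature. The direct
`O(N^2)` summation is implemented in compiled code; histories at the
problem sizes used here (hundreds to a few thousand samples per protocol
step) evaluate in milliseconds. Pressure-driven simulation
(`solve_pressure_driven()`) advances one sample at a time, freezing the
history and solving the scalar thin-wall balance for `λ_θ` by a
safeguarded bracketed root solve (hard bracket `[0.3, 3]`, with a scan
fallback when the local bracket fails, e.g. near a limit point of a
fibre-free wall).

## Synthetic protocol

`generate_dataset()` emulates a 20-step biaxial characterisation of a
mouse common carotid artery: three quasi-static inflation/deflation
sweeps, 10–180 mmHg at 3 mmHg/s, at 105 %, 95 % and 100 % of `l_iv`;
twelve sinusoidal pressure-loop trains (2.5, 5, 10, 20 Hz crossed with
40–80, 80–120 and 120–160 mmHg) at `l_iv`; and five axial force sweeps at
0.11 1/s between the zero-force length and the length reaching the
maximum force of the 105 % sweep, at 10–180 mmHg. Every step starts from
the fully relaxed state, mirroring the long rest periods between
experiments, and loop trains are recorded in full from that state (four
cycles by default). Sampling intervals are 0.25 s for pressure sweeps,
0.02 s for axial sweeps and 200 samples per loop cycle — sizes chosen so
a full dataset generates in seconds at desk scale while keeping the
discretisation error of the hereditary integral far below the signal
amplitudes.

Default geometry: unloaded outer diameter 470 µm and wall thickness
75 µm (measured values for this vessel class); the axial lengths
(`l_iv = 6` mm, `L_0 = l_iv / λ_{z,e}`) are synthetic modelling choices,
not measurements. The reference outer diameter is solved by
`consistent_reference_diameter()` so that the fully relaxed model
pressure at the identity deformation is exactly 100 mmHg — the defining
property of `κ_r`.

The noise model adds independent Gaussian noise to pressure (0.5 mmHg),
diameter (1 µm) and force (0.05 mN) and can misalign the diameter channel
of each loop by up to 2 ms, emulating camera/DAQ synchronisation and
pressure-wave travel delays. `estimate_alignment_shift()` inverts such
delays using the near rate-independence of the soft-tissue loss factor,
with the 2.5 Hz loops as delay-free reference. What the generator does
*not* emulate: instrumentation transfer functions, preconditioning,
smooth-muscle tone, wall heterogeneity and drift — so passing tests show
self-consistency of the method under the model class, not robustness to
every feature of real recordings.

## Metrics

* `stiffness_ratio()`: `K_D` is the OLS slope of Cauchy stress versus
  circumferential stretch over a dynamic loop; `K_QS` is the mean of the
  loading- and unloading-branch slopes of the quasi-static curve
  restricted to the loop's pressure range. Regressing on stretch rather
  than a strain measure is immaterial — the ratio is invariant to affine
  rescaling of the strain axis.
* `loss_factor()`: hysteresis-loop area divided by `2π` times the stored
  elastic energy. The stored energy is the average quarter-cycle area of
  the branch-averaged backbone curve about its mid-strain point. An
  alternative normalisation (branch areas above the loop's minimum
  stress, divided by four) was considered and rejected: it yields
  `tan δ / 2` instead of `tan δ` for a linear viscoelastic sinusoid. The
  implemented normalisation recovers `tan δ` exactly in that limit, which
  the tests enforce within 5 %.
* `modulus_ratio_grid()`: simulates small (0.5 mmHg half-amplitude)
  pressure sinusoids over a pressure × frequency grid at `l_iv` and
  reports `E_D/E_S` in the 2nd Piola–Kirchhoff / Green–Lagrange plane,
  with the 1e-5 Hz response as the fully static reference. Each final
  cycle is fitted with a quadratic in strain plus a linear time term (the
  time term absorbs residual creep from the relaxed start), and the
  dynamic slope is evaluated at the mean strain of the static cycle. This
  common-operating-strain evaluation matters: the static cycle sits at a
  slightly larger mean strain than the dynamic one (the relaxed wall is
  more compliant), and with exponential stiffening a naive whole-cycle
  OLS slope picks up a first-order finite-amplitude bias of order 1 %
  that masks the structural pressure-independence of the sQLV ratio. With
  the common-strain estimator the sQLV ratio is pressure-independent to
  about `2e-4` at the default amplitude.

## Parameter estimation

The pipeline estimates 12 free parameters in three steps
(`fit_cbqlv()`), with `β`, `k2_comp`, `τ_1` fixed and
`λ_{z,e} = l_iv/L_0` (elastin assumed axially unstretched in `κ_u`):

1. A purely elastic model (8 parameters) is fitted to branch-averaged
   quasi-static curves (35 nodes per branch, uniform in the controlled
   variable), minimising the normalised pressure/force cost with weight 1
   per pressure sweep and a cumulative weight 1 shared by the axial
   sweeps in proportion to their arc length in the
   `(λ_θ, λ_z)` plane. The deposition stretches `λ_c`, `λ_{θ,e}` are then
   frozen.
2. The full viscoelastic model is fitted to the in-vivo-length steps:
   the quasi-static sweep with loading and unloading kept separate, plus
   the squared mismatch of modelled versus experimental `K_D/K_QS` over
   the twelve loops. Free: six elastic parameters plus `(ν_e, τ_{2,e},
   ν_c, τ_{2,c})` (cbQLV) or a shared `(ν, τ_2)` (sQLV). Experimental
   ratios and the pressure-window sample sets are computed once from the
   data; the modelled `K_QS` uses the same fixed windows, which keeps the
   cost smooth across optimiser iterations.
3. The six elastic parameters are refined on all quasi-static data,
   branches separate, viscous parameters frozen.

Each step is a bounded Levenberg–Marquardt least-squares solve repeated
from seeded Latin-hypercube initial guesses (50 by default); the best
final cost wins. Scale-like parameters (`μ`, `k_1`, the `k_2`s, `τ_2`)
are sampled and optimised on a log10 scale — with linear-scale sampling
the fibre exponentials make most starts land in degenerate basins and the
multistart needs far more draws. The first start of steps 2 and 3 warm
starts from the preceding step's estimate. Residuals that fail to
evaluate return a large constant penalty so the optimiser survives
excursions into overflow territory. Bounds bracket the reference
parameter tables with wide margin; the `k_1` lower bound is `1e-3` kPa,
numerically zero relative to wall stresses.

The reported fit errors follow the convention of the reference tables:
`RMSE = Π/(N·M)` without a square root, with `N` the datapoints per step
(70 for branch-separate fits), `M` the number of steps, and the dynamic
denominator additionally counting the 12 ratio terms.

On a noise-free synthetic 20-step protocol generated from the sample II
reference parameters, the pipeline with 10 multistarts recovers all
elastic parameters within 1 % and all viscous parameters within about
4 % (the acceptance tests assert 5 %/10 %); the weakest-identified
parameter is `τ_{2,e}`, whose influence enters mainly through the product
`ν_e ln τ_{2,e}`.

## Degenerate inputs, tie-breaks, tolerances

* Histories must be strictly increasing and uniform in time; non-uniform
  histories are either rejected or linearly resampled on request.
* `I_{1,e} − 3` is clamped at zero against round-off (it is non-negative
  in tension), avoiding complex powers under `β = 0.15`.
* The pressure root solve targets machine-level residuals (`λ_θ`
  tolerance `1e-10`, pressure residuals below `1e-6` mmHg).
* Quasi-static branches are split at the extremum of the controlled
  variable; branch resampling requires at least 4 samples per branch and
  interpolates with mean-collapsed ties, so mildly noisy controlled
  signals are tolerated.
* An elastin-only wall (`k1 = 0`) has a pressure limit point; the inverse
  solver reports a clear bracketing error above it rather than returning
  a spurious root.

## Known limitations

Single-layer membrane: no transmural stress distribution, no
layer-specific parameters, no opening-angle residual-stress kinematics.
No smooth-muscle constituent — its passive viscoelastic contribution is
absorbed into the collagen families. Axial harmonic loading is not part
of the protocol, so the axial viscous response is only constrained
quasi-statically. The synthetic-data generator shares its constitutive
model with the fitting pipeline, so parameter-recovery results validate
the estimation machinery, not the physiological truth of the model.
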