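# cbqlv

Constituent-based quasi-linear viscoelastic (cbQLV) modelling of arterial
walls in R.

## The problem

Arteries are viscoelastic: under pulsatile (dynamic) loading the wall is
stiffer than under slow quasi-static loading, and both the dynamic
stiffening and the energy dissipated per cycle depend strongly on the
operating pressure. Classical quasi-linear viscoelasticity (QLV) — one
reduced relaxation function for the whole tissue — cannot reproduce this
pressure dependence. This package implements a constituent-based variant
in which Fung's QLV is applied separately to the elastin-dominated
isotropic matrix and to four collagen fibre families of a thin-walled
vessel. Each constituent keeps a deformation-independent continuous
relaxation spectrum

&nbsp;&nbsp;`Q_j(t) = [1 + ν_j (E₁(t/τ₂ⱼ) − E₁(t/τ₁))] / [1 + ν_j ln(τ₂ⱼ/τ₁)]`,  `j ∈ {e, c}`,

but because the constituents' shares of the load shift with deformation
(elastin dominates at low pressure, collagen is recruited at high
pressure), the tissue-level response is fully nonlinear viscoelastic with
a single parameter set. The Cauchy stress is the hereditary integral

&nbsp;&nbsp;`σᵢᵢ(t) = {S(0) + ∫₀ᵗ [Q_e(t−s) dŜᵢᵢ,ₑ/ds + Q_c(t−s) dŜᵢᵢ,𝒸/ds] ds} λᵢ²(t)`

of the elastic stress rate of a four-fibre-family strain energy function
with constituent deposition stretches, and luminal pressure / axial force
follow from thin-wall equilibrium, `P = (σ_θθ − σ_rr) h/r_m`,
`F = π(2σ_zz − σ_θθ − σ_rr) r_m h`.

The package is aimed at vascular-biomechanics researchers who fit
constitutive models to biaxial (pressure–diameter–axial force) test data:
it provides the forward simulator (deformation-driven and
pressure-driven), the viscoelastic summary metrics (dynamic-to-quasi-static
stiffness ratio K_D/K_QS, loss factor, dynamic-to-static modulus grids
E_D/E_S), the three-step multistart estimation pipeline, and a synthetic
20-step protocol generator that emulates a full mouse carotid
characterisation so the entire pipeline is testable without any
experimental download.

## Worked example

```r
library(cbqlv)

# ground truth: reference artery II; synthetic but self-consistent geometry
p    <- carotid_params("II")
geom <- synthetic_carotid_geometry(p)

# simulate the full 20-step biaxial protocol (noise-free)
ds <- generate_dataset(geom, p, protocol_spec())

# viscoelastic metrics of the 10 Hz loops against the quasi-static sweep
qs <- qs_branches(ds$steps$qs_sweep_100, geom)
for (rng in c("low", "medium", "high")) {
  lp <- loop_from_step(ds$steps[[paste0("loop_", rng, "_10Hz")]], geom, cycles = "last")
  cat(sprintf("%-6s  K_D/K_QS = %.3f   loss factor = %.4f\n",
              rng, stiffness_ratio(lp, qs)$ratio, loss_factor(lp)))
}
#> low     K_D/K_QS = 1.010   loss factor = 0.0380
#> medium  K_D/K_QS = 1.296   loss factor = 0.0582
#> high    K_D/K_QS = 1.350   loss factor = 0.0605

# recover the parameters with the three-step pipeline (10 multistarts)
fit <- fit_cbqlv(ds, fit_config(n_starts = 10, seed = 42))
dplyr::filter(tidy(fit), term %in% c("mu", "lam_c", "nu_c", "tau2_c"))
#> # A tibble: 4 x 3
#>   term    value fixed
#>   <chr>   <dbl> <lgl>
#> 1 mu     46.7   FALSE
#> 2 lam_c   1.17  FALSE
#> 3 nu_c    0.0612 FALSE
#> 4 tau2_c 46.5   FALSE
```

The loops stiffen and dissipate more at higher pressure — the collagen
recruitment signature that a single-kernel (sQLV) model cannot produce —
and the fit recovers the generating parameters (true µ = 46.8 kPa,
λ_c = 1.17, ν_c = 0.061, τ₂,c = 46.2 s) to within a few percent from
noise-free data.

`autoplot()` methods are provided for datasets, modulus grids and fits;
`inst/cli/cbqlv.R` is a thin command-line wrapper
(`synth | simulate | fit | metrics | grid`) over the same functions.

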