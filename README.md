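# tendonscale

Multiscale analysis of tendon mechanics, organization, and ECM stress
transmission.

Tendon transmits muscle force across a structural hierarchy — tissue,
fiber, cell, nucleus — and both fatigue loading and injury healing degrade
that transfer. `tendonscale` is for biomechanics researchers who want the
full quantitative chain in one tested package:

* **Cyclic mechanics** from force–displacement records: per-cycle tangent
  stiffness, dynamic modulus, hysteresis (stress–strain loop area) and
  laxity; equilibrium stress after relaxation holds and its change between
  1 % and 10 % strain (strain stiffening); |E\*| and tan δ from frequency
  sweeps.
* **Fiber recruitment model** of the nonlinear toe region: slack lengths
  Gaussian (μ, σ), recruited fraction Φ((L₀ − μ)/σ), population force
  F(x) = K_tot[(x − μ)Φ(z) + σφ(z)], fit by nonlinear least squares.
* **Fibrous-matrix constitutive law**: Cauchy stress
  σ = κ(J − 1)I + G dev(B̄)/J + (1/J) Σₐ f′(λₐ) λₐ nₐ⊗nₐ, with a piecewise
  C¹ fiber response between critical stretches λ₁ < λ₂ and stiffening
  exponents n, m; uniaxial response, parameter fitting, numerical tangent.
* **Cell contraction simulation**: axisymmetric nonlinear finite elements
  around a contracting spheroidal cell (5 % volume loss), displacement
  decay profiles u(r) ∝ r^(−η), the decay exponent η and its
  cellularity-scaled effective value; a 1-D spherically symmetric solver
  ships as an independent oracle.
* **Organization imaging**: polarized-light sin²(2θ) region fits, circular
  standard deviation (CSD) for axial angle data, the bilinear realignment
  transition strain, Fourier (spectral second-moment) SHG fiber
  orientation, nucleus segmentation with aspect ratio (nAR) and angular
  disorganization (nCSD), and percent F-actin.
* **Regression workflow**: 2.2 × IQR outlier rule, Pearson screen,
  backward stepwise regression with partial-F thresholds (enter 0.05,
  remove 0.10), a collinearity tolerance gate (1 − R²ₖ ≥ 0.01), and the
  Durbin–Watson statistic.
* **Synthetic data generators** for every input — loading protocols,
  polarizer stacks, SHG textures, nuclei fields, regression tables — with
  exact ground truth, plus `run_study()` which chains everything into a
  loading × healing study.

## Worked example

Fit the recruitment model to a noisy synthetic tensile test (gauge length
5 mm, true μ = 5.05 mm, σ = 0.03 mm, K_tot = 30 N/mm, 2 % force noise):

```r
library(tendonscale)
p <- recruitment_params(mu = 5.05, sigma = 0.03, K_tot = 30)
x <- seq(4.9, 5.5, length.out = 300)
set.seed(1)
f <- recruitment_force(x, p) * (1 + 0.02 * rnorm(300))
fit_recruitment(x, f, gauge_length = 5)
#> Fiber recruitment model fit (expectation mode)
#>       estimate      se    lower    upper
#> mu     5.05045 0.00074  5.04899  5.05192
#> sigma  0.03079 0.00247  0.02593  0.03565
#> K_tot 30.06348 0.08173 29.90263 30.22432
#> mean slack strain: 1.009 %
```

All three parameters are recovered within their confidence intervals; the
mean slack strain (~1 %) is the strain at which the average fiber
uncrimps — the toe-to-linear transition.

Simulate a cell contracting 5 % of its volume in a stiff, sharply
recruiting fibrous matrix and measure how far the displacement travels:

```r
pm <- fibrous_params(E_b = 0.1, E_f = 100, lambda1 = 1.0, lambda2 = 1.01,
                     n = 2, m = 2)
mesh <- build_mesh(cell_geometry(a = 5), mesh_spec(1, 6, 100))
fld <- solve_contraction(mesh, pm, increments = 4)
fit_power_law(radial_profile(fld))
#> Power-law decay fit: eta = 0.6710 (R^2 = 0.9516, 46 points, r in [6, 50] um)
effective_decay(0.671, cellularity = 2400, reference_cellularity = 800)
#> [1] 0.3874  (eta_eff; attribute records the areal spacing rule)
```

η ≈ 0.67 means displacement decays far slower than the r⁻² of a plain
elastic medium — fiber stiffening transmits the contraction roughly ten
cell radii. Long-toe, low fiber/matrix-ratio parameter sets (emulating
healing or fatigue-damaged matrix) give η ≈ 2 instead.

Run the stepwise stage on a synthetic specimen table whose outcome is
generated from cellularity, nuclear disorganization, and healing state:

```r
tab <- gen_regression_table(120, seed = 42)
backward_stepwise(tab, "nAR")
#> Backward stepwise regression for nAR
#> retained: cellularity, nCSD, healing
#> R^2 = 0.915 (adj 0.912), overall p = 1.22e-60, DW = 2.316
```

The procedure recovers exactly the generating predictors, and the
Durbin–Watson value near 2 shows uncorrelated residuals.

The whole multiscale study — mechanics, imaging, contraction, regression
for a loading × healing design — is one call:

```r
res <- run_study(study_config(seed = 1))
print(res)   # per-group d_seq, tan_delta, CSD, dnAR, nCSD, eta, eta_eff
```

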