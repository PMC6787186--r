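# nanostripe

Coarse-grained simulation and analysis of charged polymer chains — short
single-stranded DNA in particular — adsorbed on patterned two-dimensional
surfaces such as a graphene / h-BN in-plane heterostructure.

## The problem

A narrow stripe of strongly binding material embedded in a weakly binding
plane acts as a *planar nanochannel*: a surface-adsorbed chain diffuses to
the stripe, is trapped by the extra binding energy (about 6.1 kcal/mol per
monomer for ssDNA on h-BN versus graphene), and is stretched by the lateral
confinement.  An in-plane electric field then transports the stretched chain
along the stripe.  `nanostripe` provides, for anyone studying this kind of
system (polymer physics on 2D materials, surface nanofluidics, planar DNA
sequencing platforms):

* a discrete worm-like-chain (WLC) energy model on a smooth two-material
  landscape with analytic forces,
* an overdamped Langevin (Brownian-dynamics) trajectory generator with
  scenario presets (free diffusion, boundary crossing, stripe confinement,
  driven transport),
* the estimator pipeline: tangent-correlation persistence length
  (cos θ = e^(−Na/lp)), windowed MSD → diffusion constant
  (D = ⟨ΔX²⟩/2Δt), drift velocity → electrophoretic mobility (through-origin
  v–E slope), Einstein-relation effective charge (q_eff = kBT·μ/D),
  screening vs the Manning condensation benchmark (1 − b/lB),
* closed-form channel-confinement theory: Gauss–de Gennes extension
  lc·lp/w, Odijk extension lc·[1 − A·(lp/w)^(−2/3)] with A = 0.17, and
  regime classification (Odijk / transition / de Gennes),
* XYZ trajectory I/O with JSON provenance sidecars, YAML run configs, a
  thin CLI (`inst/scripts/nanostripe-cli.R`), ggplot2 `autoplot()` methods
  and broom-style `tidy()`/`glance()` for every fit object.

Everything is tibble-in / tibble-out and pipe-friendly.

## Worked example

```r
library(nanostripe)

# closed-form confinement predictions for a 20-mer (a = 0.625 nm,
# lp = 1.39 nm) on a 1.8-nm stripe
confinement_theory()
#> # A tibble: 1 x 7
#>      lc    lp     w prefactor_A degennes_extension odijk_extension regime
#>   <dbl> <dbl> <dbl>       <dbl>              <dbl>           <dbl> <chr>
#> 1  12.5  1.39   1.8        0.17               9.65            9.98 transition

# simulate confinement-driven stretching and compare (values in A)
tr <- run_scenario(scenario("stripe_confinement", seed = 1, discard_frac = 1/3))
mean(end_to_end(tr)$r_ee) * 10
#> [1] 93.82694

# transport: diffusion from zero-field replicates, mobility from three fields
D <- mean(sapply(1:4, function(r) {
  com_diffusion(run_scenario(scenario("driven_transport", field_E = 0,
                                      discard_frac = 0, seed = r)))$D
}))
vels <- data.frame(E = c(0.002, 0.005, 0.01))
vels$v <- sapply(1:3, function(i) {
  tr <- run_scenario(scenario("driven_transport", field_E = vels$E[i],
                              discard_frac = 0, seed = 10 + i))
  drift_velocity(com_series(tr, "x"))$v
})
tf <- transport_fit(fit_mobility(vels), D)
tf
#> <transport_fit> mu = 50.22 nm^2/(ns V); D = 0.1255 nm^2/ns
#>   q_eff = 10.34 e;  screened: 45.6% (Manning: 12.0%)
```

(Each of these eight runs is a production-length simulation; the block
takes a few minutes.)  The simulated stripe extension (~89 Å when averaged
over replicate runs; individual seeds scatter by ±4 Å) sits just below the
de Gennes (96.5 Å) and Odijk (99.8 Å) hard-wall predictions — the tanh
boundary confines a little more softly than a hard channel.  The
Einstein-relation effective charge recovers the chain's total charge
(10.2 e): about 46% of the 19 bare backbone charges appear screened,
against 12% from Manning condensation theory alone.

## Documentation

The methods vignette (`vignettes/nanostripe-methods.Rmd`) describes the
energy model and its unit system, the stiffness-to-persistence-length
mapping and its excluded-volume calibration, the integrator and its
stability criterion, each estimator with its sampling-error behaviour, the
confinement theory, and the package's numerical choices and limitations.
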