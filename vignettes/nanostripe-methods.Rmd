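---
title: "Coarse-grained chains on patterned 2D surfaces: model and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained chains on patterned 2D surfaces: model and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nanostripe)
```

## The physical problem

Short single-stranded DNA adsorbs strongly on 2D materials such as
graphene and hexagonal boron nitride, yet stays laterally mobile.  When
the surface is an in-plane heterostructure — a narrow h-BN stripe
seamlessly joined to graphene on either side — the extra binding energy
of ssDNA on h-BN (about 6.1 kcal/mol per nucleotide) turns the stripe
into a planar "nanochannel": the molecule diffuses to the stripe, stays
there, and is stretched by the lateral confinement.  An in-plane
electric field then transports the stretched molecule along the stripe.

`nanostripe` implements the quantitative pipeline for this system at the
coarse-grained level: a discrete worm-like chain (WLC) on a patterned
adhesive plane, an overdamped Brownian-dynamics (BD) generator of
trajectories, and the estimators that turn trajectories into persistence
lengths, extensions, diffusion constants, mobilities and effective
charges, together with the closed-form confinement theory
(Gauss–de Gennes and Odijk) the measurements are compared against.

## The model

Units are nm, ns, kBT (300 K) and elementary charges throughout;
`units_convention()` records the conversions (1 kcal/mol = 1.6774 kBT,
kBT = 0.025852 eV).

A chain of $n$ beads (default $n = 20$, one bead per nucleotide) carries
the energy

$$U = \sum_i \tfrac12 k_b\,(|\mathbf r_{i+1}-\mathbf r_i| - a)^2
    + \sum_i \kappa\,(1-\cos\theta_i)
    + U_{\mathrm{ev}} + \Delta\varepsilon \sum_i s(\mathbf r_i)
    - \sum_i q_i E\, x_i ,$$

with $a = 0.625$ nm the monomer spacing (contour length
$l_c = n a = 12.5$ nm), $k_b = 100\,k_BT/a^2$ a stiff bond spring,
$\kappa$ the bending stiffness, and an optional soft excluded-volume
repulsion $\varepsilon_{\mathrm{ev}}(1 - r/d)^2$ ($d = a$,
$\varepsilon_{\mathrm{ev}} = 1\,k_BT$) between non-bonded beads that
suppresses self-crossing of initially circular or self-overlapping
conformations (off by default; see below).

The two-material surface enters through a smooth indicator
$s \in [0,1]$ (0 on the weak material, 1 on the strong one) built from
tanh profiles with smoothing length $\delta = 0.3$ nm — the scale of a
van-der-Waals contact, chosen so forces are analytic.  Only the binding
*contrast* $\Delta\varepsilon = -6.1$ kcal/mol per bead exerts lateral
force; the common base depth (about $-23.2$ kcal/mol per bead on the
weak material) is uniform, force-free, and kept as metadata.  Desorption
off the surface is excluded by construction: the model is strictly 2D,
consistent with the sub-ångström height changes of an adsorbed molecule.
The stripe geometry has width $w = 1.8$ nm along $x$, centred on
$y = 0$.

The driving field acts along $x$; a bead of charge $q$ (default total
10.2 e spread uniformly) feels $qE/(k_BT/e)$ in internal force units.
Charge and friction are *effective* parameters: solvent, counterions and
electrostatic plus hydrodynamic screening are not modelled explicitly,
they are absorbed into the effective charge (the Einstein-relation value
measured for the stretched molecule) and the per-bead friction
$\gamma = k_BT/(n \cdot 0.13\ \mathrm{nm^2/ns})$, calibrated so the
chain's centre-of-mass diffusion constant $k_BT/(n\gamma)$ equals the
measured 0.13 nm²/ns.

## Bending stiffness from the target persistence length

For the ideal discrete chain in 2D the per-joint tangent correlation is
the Bessel ratio
$\langle\cos\theta\rangle = I_1(\beta\kappa)/I_0(\beta\kappa)$, and the
WLC decay $e^{-a/l_p}$ then fixes $\kappa$.  We invert this relation
numerically (`bend_stiffness_from_lp()`); the familiar large-stiffness
asymptote $\kappa \approx l_p k_BT/(2a)$ is off by ~35% at the working
stiffness ($a/l_p = 0.45$) and is not used.  For $l_p = 1.39$ nm,
$a = 0.625$ nm this gives $\kappa = 1.68\,k_BT$, and simulations with
the excluded volume *disabled* recover $l_p$ within ~1%, confirming the
mapping.

Whether the chain should also be self-avoiding depends on what is being
measured, and the package treats this as a per-scenario choice — a
genuine modelling finding worth spelling out.  In two dimensions
self-avoidance is strong.  With the soft repulsion enabled,
production-length free-chain simulations give tangent correlations
whose $N = 1..6$ log-slope reads $l_p \approx 1.9$ nm at the
Bessel-mapped $\kappa$, still $\approx 1.55$ nm at $\kappa = 1\,k_BT$
(where the ideal chain reads 0.78 nm), and $\approx 1.7$ nm again at
$\kappa = 0.6\,k_BT$: the apparent persistence length has a *floor*
near 1.55 nm, because swelling correlations replace bending
correlations as stiffness is removed.  The decay is simply not
exponential, and no bending stiffness makes a self-avoiding 20-mer
reproduce a WLC tangent fit of 1.39 nm.  The ideal discrete chain, by
contrast, has independent joint angles, matches the exponential form
exactly, and recovers the target within sampling error.  The
free-surface scenarios therefore use the ideal chain: they exist
precisely to realise the WLC statistics the persistence-length
estimator assumes.

Confinement is the opposite case.  An ideal chain pressed into the
stripe lowers its extension by folding *through* itself — backfolded
hairpins with coinciding strands — which no real molecule can do, and
the measured stripe extension collapses by a third.  The confinement
and transport presets therefore enable the repulsion; on the stripe the
chain is extended, excluded-volume contacts are rare, and the term acts
almost solely to veto the unphysical self-crossings.  Transport
observables are indifferent to the choice: pair forces are internal and
cancel exactly in the centre-of-mass motion.  Both settings are
defaults of the *presets*, not hidden switches — `chain_params()` and
`scenario()` expose the flag, and the provenance of every trajectory
records it.

## Brownian dynamics

The integrator is Euler–Maruyama for the overdamped Langevin equation,
$\Delta\mathbf r_i = \mathbf F_i\,dt/\gamma + \sqrt{2 k_BT\,dt/\gamma}\,
\boldsymbol\xi_i$, with no hydrodynamic interactions (strongly screened
for a surface-adsorbed chain).  The time step obeys the bond-relaxation
stability criterion $dt \le 0.1\,\gamma/k_b$; the default
$dt = 1.5\times10^{-4}$ ns sits at that limit, and `bd_simulate()`
refuses larger steps.  A production run is $10^7$ steps (1.5 μs of model
time), sampled every $10^3$ steps, with the first 10% discarded as
equilibration (scenario presets override this where the analysis
demands, e.g. one third for the confinement average).  Forces are
analytic — the suite verifies them against a central finite difference
of the energy on random configurations to $10^{-5}$ relative — and a
bond stretched beyond $3a$ aborts the run with the offending step, which
converts an unstable parameter choice into a loud failure instead of
quiet nonsense.

All randomness flows through R's RNG: seeding the scenario makes
trajectories bit-reproducible, and every trajectory carries its full
provenance (parameters, pattern, field, dt, seed) through analyses and
into the XYZ + JSON sidecar written by `write_xyz()`.

Four scenario presets generate the study conditions: `free_uniform`
(persistence-length statistics), `boundary_crossing` (a chain released
2 nm into the weak material crosses the boundary and, with a ~10 kBT
per-bead contrast, essentially never returns), `stripe_confinement`
(stretching on the stripe) and `driven_transport` (stripe plus field;
zero field gives the 1D diffusion measurement).  Coordinates are
evolved unwrapped — the stripe landscape is invariant along $x$, so a
periodic wrap would be purely cosmetic; a wrapped column is added only
when a box length is supplied.

## Estimators

**Persistence length.**  Unit tangents along bonds give
$C(N) = \langle \mathbf t_i\!\cdot\!\mathbf t_{i+N}\rangle$, averaged
over bead index and frames; a least-squares fit of $\ln C(N)$ against
$Na$ over $N = 1..6$ yields $l_p = -1/\mathrm{slope}$.  The short-range
window is deliberate: for a 20-mer, $C(N)$ beyond $N \approx 6$ is both
noise-dominated and contaminated by excluded-volume correlations.
Non-positive correlations are dropped with a warning; fewer than two
usable points is an error.  Against samples drawn independently from
the exact single-joint density $\propto e^{\beta\kappa\cos\theta}$ the
estimator reproduces the Bessel-ratio quadrature, and on exact
exponential inputs the fit is the identity for any $(l_p, a)$.

Persistence-length estimates from single runs deserve a warning: the
end-to-end relaxation time of the free 20-mer is of order
$R^2/D_{\mathrm{com}} \sim 300$ ns, a fifth of a production run, so
per-run $l_p$ estimates scatter by several percent and short runs are
essentially uninformative.  Quantitative statements in this package
average a few independently seeded production runs.

**Diffusion.**  `msd()` computes the windowed (all-pairs) mean-squared
displacement; `fit_diffusion()` fits a free-intercept line over a lag
window and halves the slope (1D convention).  For generic series the
default window is the upper part of a quarter-duration lag range — a
bias/variance compromise when the short-lag behaviour may be
non-diffusive.  For the chain *centre of mass* the model is special:
internal forces cancel exactly and the stripe force is transverse, so
COM $x$ is ideal Brownian motion at every lag and short-lag fitting is
unbiased.  `com_diffusion()` therefore fits lags up to 1% of the run,
where the time-averaged MSD concentrates (relative spread
$\approx\sqrt{4\tau_{\max}/3T}$, i.e. ~15–20% per production run,
versus ~80% at quarter-duration lags), and quantitative use averages
over replicate runs.  The acceptance pipeline uses 12 replicates, giving
a ~5% standard error on $D$.

**Drift, mobility, effective charge.**  `drift_velocity()` is the OLS
slope of the COM displacement; `fit_mobility()` the through-origin
slope of $v$ against $E$ (zero field gives zero drift by symmetry);
`effective_charge()` applies the Einstein relation
$q_{\mathrm{eff}} = k_BT\,\mu/D$.  In the coarse-grained model the
expected mobility is $q_{\mathrm{tot}}E/(n\gamma E) = 51.3$
nm²/(ns·V) — the free-draining value, since screening is already folded
into the effective charge — and the pipeline recovers the generator's
total charge to within its stochastic error, which is the end-to-end
consistency check of the transport stack.  `screening_fraction()`
compares $q_{\mathrm{eff}}$ with the 19 bare phosphate charges of a
20-mer backbone, and `manning_condensed_fraction()` gives the
counterion-condensation benchmark $1 - b/l_B$ with the Bjerrum length
0.71 nm of water at 300 K; both the charge count and $l_B$ are exposed
as parameters.

**Occupancy and proximity.**  `domain_occupancy()` classifies beads by
indicator threshold 0.5 — the coarse-grained analogue of per-material
atomic contact counts — and `proximity_count()` counts points of one
set within a cutoff (default 0.35 nm) of another.

## Confinement theory

For a WLC of contour length $l_c$ and persistence length $l_p$ in a
channel of width $w$, `confinement_theory()` evaluates the
Gauss–de Gennes (blob) extension $l_c\,l_p/w$ and the Odijk
(deflection-segment) extension $l_c[1 - A\,(l_p/w)^{-2/3}]$ with the
universal prefactor $A = 0.17$, and classifies the regime: Odijk for
$w \le l_p$, Gauss–de Gennes for $w \ge 2l_p$, transition between
(ties assigned to the adjacent named regime, since only the open
interval is defined).  With the default parameters both predictions
bracket a narrow range (96.5 and 99.8 Å) although $w = 1.8$ nm lies in
the transition regime where both are approximations; the simulated
stripe extension tracks each within ~10–15% rather than falling
strictly between them, sitting somewhat below both because the soft
tanh walls admit transverse excursions a hard channel would forbid.
The contour-length convention is
$l_c = n a$ (not $(n-1)a$): it is the convention under which the blob
prediction reproduces the 96.5 Å reference.  Note the same prefactor is
carried over from channel confinement to the surface stripe — a
one-dimensional lateral confinement — which the underlying study
assumes rather than derives.

```{r theory}
confinement_theory()
```

## What the generator does and does not emulate

The BD generator reproduces the *statistical structure* the estimators
assume: WLC tangent decay at the target $l_p$, confinement-driven
stretching controlled by $l_p/w$, free-draining diffusion at the
calibrated friction, and linear field response at the stated effective
charge.  It does not attempt atomistic realism: no explicit water or
ions (screening enters only through the effective parameters), a single
friction on both materials (measured separately they differ, but no
separate values are available), no sequence effects, no base pairing or
hairpins, no desorption, and no attempt to match atomistic timescales
such as boundary-crossing times.  Passing tests therefore demonstrate
the internal consistency of model + estimators and agreement with the
closed-form physics — not that the coarse-grained dynamics reproduces
every feature of an atomistic trajectory.

A further caveat: the tanh-smoothed stripe confines softly.  Beads pay
$|\Delta\varepsilon|(1 - s(y))$ to approach the edge, so the effective
channel width differs slightly from the nominal $w$; the agreement of
the simulated extension with the closed forms at the nominal $w$ is
physics, not construction.

## Numerical choices

* $dt = 1.5\times10^{-4}$ ns — the stability bound for the default
  stiffness/friction; `bd_max_dt()` recomputes it for other parameters.
* Equilibration: 10% of a run by default; 1/3 for the confinement
  average, 0 for transport runs started from the stretched state.
* $l_p$ fit range $N = 1..6$; MSD default window the upper 20–100% of
  computed lags; `com_diffusion()` small-lag window as motivated above.
* Mobility forced through the origin; drift and MSD fits are plain OLS.
* Degenerate inputs fail loudly: zero-length bonds, non-finite forces,
  bead-count mismatches, non-uniform sampling, negative MSD slopes and
  non-decaying correlations all raise errors rather than propagate.
* Problem sizes: production runs of $10^7$ steps; the test-suite
  versions use $10^5$–$10^7$ steps per check and a handful of seeds,
  sized so each estimator's sampling error is several times tighter
  than the tolerance it is tested at.

## A worked example

```{r example, eval = FALSE}
# stretch a 20-mer on the stripe and compare with theory
tr <- run_scenario(scenario("stripe_confinement", seed = 1,
                            discard_frac = 1/3))
mean(end_to_end(tr)$r_ee) * 10          # ~85-95 A per run
confinement_theory()[, c("degennes_extension", "odijk_extension")] * 10

# transport: D from zero-field replicates, mu from three fields
D <- mean(sapply(1:4, function(r) {
  com_diffusion(run_scenario(scenario("driven_transport", field_E = 0,
                                      discard_frac = 0, seed = r)))$D
}))
vels <- data.frame(E = c(0.002, 0.005, 0.01))
vels$v <- sapply(seq_len(3), function(i) {
  tr <- run_scenario(scenario("driven_transport", field_E = vels$E[i],
                              discard_frac = 0, seed = 10 + i))
  drift_velocity(com_series(tr, "x"))$v
})
tf <- transport_fit(fit_mobility(vels), D)
tidy(tf)
```

## Known limitations

* The default chain is ideal (no self-avoidance).  Real ssDNA is
  self-avoiding, and its measured "persistence length" on a surface
  partly reflects swelling; the package treats the 1.39-nm target as an
  effective WLC parameter.  Enabling the soft repulsion changes the
  free-chain tangent statistics qualitatively (see above) and is
  recommended only where self-crossing must be prevented.
* Transition-regime confinement has no exact closed form; both
  implemented predictions are asymptotic results used as brackets.
* The Euler–Maruyama scheme is first-order; at the stability-bounded
  default step the discretisation error is negligible against sampling
  noise, but users pushing `dt` toward `bd_max_dt()` with stiffer
  bonds should halve it and check convergence.
* Estimates from single trajectories (especially $l_p$ and $D$) carry
  the sampling spreads quantified above; replicate averaging is part of
  the method, not an optional refinement.
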