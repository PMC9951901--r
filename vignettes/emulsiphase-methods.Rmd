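---
title: "Models and methods behind emulsiphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emulsiphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emulsiphase)
```

This vignette is the package's own account of its science: the models, the
assumptions behind them, the tunable parameters, and the numerical and
design choices that were genuinely open.  Everything quantitative shown
here is computed by the code as it runs.

## 1. The pseudophase kinetic model

An oil-in-water emulsion is treated as three notional phases in dynamic
equilibrium — oil (volume fraction $\Phi_O$), interfacial ($\Phi_I$,
the surfactant volume over the emulsion volume) and aqueous ($\Phi_W$) —
with $\Phi_O + \Phi_I + \Phi_W = 1$.  `emulsion_composition()` defaults to
$\Phi_W = 1 - \Phi_O - \Phi_I$, i.e. the surfactant volume counts against
the water.  For a 1:9 (v:v) oil-in-water formulation $\Phi_O = 0.10$, so
$\Phi_I = 0.04$ gives $\Phi_W = 0.86$.  This complement convention matters:
the interfacial percentages reported downstream depend on it, and it is the
one under which the package's distribution numbers are internally
consistent with its partition identity.

An **oil-insoluble** antioxidant distributes between water and interface
only, described by a single dimensionless partition constant

$$P_W^I = \frac{(AO_I)}{(AO_W)},$$

the ratio of *effective* concentrations — moles of antioxidant per liter
of that region's own volume.  Chemical trapping with a probe whose reaction
is confined to the interface gives an observed rate constant that decreases
as surfactant dilutes the interfacial reactant pool:

$$k_{obs} = \frac{[AO_T]\,k_I\,P_W^I}{\Phi_I P_W^I + \Phi_W}.$$

Only the composite $[AO_T]\,k_I$ is identifiable from a $k_{obs}$ series;
the package therefore reports $k_I$ relative to the supplied $[AO_T]$ and
makes no claim about its absolute units.  From $P_W^I$ follow the
interfacial percentage and the effective concentrations:

$$\%AO_I = \frac{100\,\Phi_I P_W^I}{\Phi_W + \Phi_I P_W^I},
\qquad (AO_I) = \frac{[AO_T]\,(\%AO_I/100)}{\Phi_I}.$$

Note the $/100$: the percentage enters as a fraction.  Under this reading
the model reproduces its own mass balance
$\Phi_I (AO_I) + \Phi_W (AO_W) = [AO_T]$ to machine precision, and at
$\Phi_I = 0.005$, $[AO_T] = 10^{-4}$ M, $P_W^I = 93$ it yields a ~70-fold
interfacial enhancement:

```{r enhancement}
d <- distribution(93, 1e-4, emulsion_composition(0.10, 0.005))
d$effective_conc_interfacial / 1e-4
```

### Fitting

`fit_partition()` offers two routes, both reported because experimental
practice plots both $k_{obs}$ and $1/k_{obs}$ against $\Phi_I$:

* **nonlinear** (default): unweighted Levenberg–Marquardt least squares of
  the forward model on the $k_{obs}$ scale.  Initialization comes from the
  reciprocal-linear estimates; on failure the start point is perturbed
  multiplicatively five times with an internal fixed-seed generator (the
  user's RNG state is saved and restored, so fitting never disturbs
  reproducibility of surrounding code).
* **reciprocal-linear**: with $\Phi_W = 1-\Phi_O-\Phi_I$, the reciprocal
  curve is exactly linear in $\Phi_I$,
  $1/k_{obs} = \frac{1-\Phi_O}{[AO_T] k_I P} + \Phi_I\frac{P-1}{[AO_T] k_I P}$,
  so ordinary least squares on $(\Phi_I, 1/k_{obs})$ back-transforms to
  $(P, k_I)$.  The reciprocal transform reweights the noise — small
  $k_{obs}$ values dominate — which is why it is not the default.

Uncertainties are asymptotic standard errors (from the fit Jacobian, or by
the delta method from the regression covariance).  No bootstrap is run by
default; nothing in the reporting should be read as a confidence interval
of stated coverage.

## 2. The synthetic droplet generator

The generator replaces two expensive upstream sources — wet-lab kinetics
and a long molecular-dynamics production run — with draws from explicit
laws, so that every analysis in the package can be validated by a
round trip against known truth.

A `species_spec()` describes one droplet.  The defaults are the package's
reference conditions: 200 oleic-acid molecules in a 20 Å core, 20
surfactant molecules spanning a 17 Å interfacial shell, 8 gallic-acid
molecules whose center-of-mass radius follows a gaussian with mean 31 Å
and sd 3 Å, 33,804 water points filling the shell from the water onset to
the box bound (23 Å beyond the interface), and a two-component (α, β)
orientation mixture centered at (55.5°, 64.5°) and (82.5°, 154.5°) with
6° spread — the two preferred interfacial tilts of the solute.  The sd
values are the generator's own choice where only modes and ranges are
reported for the emulated system; they are stated here once and not tuned.

Deliberate simplifications, and what they imply for interpreting passing
tests:

* Oleic acid and water are **point particles**; the surfactant is three
  reference sites (ring, hydroxyl termini, oleate tail) on one outward
  ray.  Only those reference points are ever analyzed, but any conclusion
  about full atomistic structure is outside what the round trips show.
* Frames are **independent draws**, not a dynamical trajectory: there is
  no force field, no thermostat, no time correlation.  Convergence
  behavior with frame count is binomial/CLT, not governed by
  autocorrelation times as in real MD.
* The gallic-acid template (`gallic_acid_template()`) is an **idealized
  heavy-atom geometry** — planar aromatic ring, standard bond lengths, no
  hydrogens, stored as a plain-text fixture.  All downstream observables
  depend only on relative geometry (center of mass, para axis, ring
  plane), so template idealization does not bias the angle definitions.
* The oleic core is recentered after sampling so its center of mass is
  exactly the origin.  Radial placements are therefore exact by
  construction, which is what makes delta-law round-trip tests meaningful
  at $10^{-9}$ Å tolerance.
* A real solvated droplet sits in a truncated-octahedron box; the
  synthetic water shell is spherical.  Equivalence of the two solvation
  geometries is not claimed.

### Orientation sampling

The solute's tilt is described by three angles against the radial vector
$\vec R$ (molecule center of mass → droplet center): α to the para axis
(oriented O4 → C7), β to the center-of-mass→C6 vector, γ to the aromatic
plane (folded to [0°, 90°]; γ = 90° means ring parallel to the droplet
surface).  A rigid placement has three rotational degrees of freedom, and
the spin about $\vec R$ changes none of the three angles — so at most two
of them can be prescribed independently, and the third follows from the
fixed body angle δ ≈ 74.2° between the para axis and the COM→C6 vector.
The generator therefore offers explicit modes rather than pretending all
three laws can hold at once: `orient_joint()`/`orient_alpha_beta()` realize
a target (α, β) constructively (place the para axis on its cone about
$\vec R$, solve the spherical-triangle azimuth for C6, pick the mirror
branch at random, then spin uniformly about $\vec R$), while
`orient_gamma()` aligns the ring normal and lets α and β fall out.  Pairs
violating the spherical-triangle inequality
$|\alpha - \delta| \le \beta \le \alpha + \delta$ (up to folding) are
rejected and redrawn; a law with no feasible mass errors out rather than
silently clipping.

### Oxidation curves

`simulate_oxidation()` integrates a minimal mass-action radical chain
(deSolve, `lsoda`, rtol $10^{-10}$): initiation at constant rate
$r_{init}$, propagation $k_{prop}[RH][ROO^\bullet]$, termination
$2k_{term}[ROO^\bullet]^2$, inhibition $k_{inh}[AOH][ROO^\bullet]$ with
$n$ radicals trapped per antioxidant (default 2).  Two modelling choices:
alkyl radicals are not tracked (the R• + O₂ step is taken as instantaneous
in excess oxygen, the standard steady-state view), and the conjugated-diene
signal is taken proportional to the hydroperoxide pool, since primary
oxidation products are what the 233 nm absorbance tracks and no calibration
is modelled.  With antioxidant present the peroxyl pool is clamped low
until the antioxidant depletes near $t \approx n\,aoh_0/r_{init}$, which is
what produces the lag; the simulator records that depletion time as
generator ground truth.  The default rate constants are chosen to give a
clearly two-phase curve with a lag of tens of hours at an
accelerated-assay timescale, with inhibition much faster than propagation.

## 3. Trajectory analysis: numerical choices

**Radial profiles** are histograms of reference-point distances from the
oil-core center, normalized to unit integral (probability per Å, default
bin 1 Å — fine enough to resolve a 16–18 Å interface without starving
$10^3$–$10^4$ samples per species).  Two normalizations are provided.  The
raw per-distance probability is the default and matches how such profiles
are usually plotted.  `volume_corrected = TRUE` divides by the shell
volume $\tfrac{4}{3}\pi\,\Delta(r^3)$ first, giving a relative number
density.  **Boundary estimation should use the corrected variant**: in a
spherical shell the raw water density grows as $r^2$ all the way to the
box bound and has no plateau (in a box-truncated MD system the geometry
itself produces the plateau), whereas the corrected profile is flat over
uniformly filled regions.  `estimate_regions()` rejects a water profile
that is still rising across its outer 20% of bins instead of guessing.

Boundary conventions: the core radius is the right edge of the first bin
whose oleic cumulative mass *strictly exceeds* `core_cut` (default 0.95) —
the strict inequality makes an exact step profile uniform on [0, 20] read
as 20, not 19; the water onset is the left edge of the first bin reaching
`bulk_cut` (default 0.90) of the plateau, the plateau being the mean
density over the outer 20% of bins.  Both cuts are configurable because
the underlying physical boundaries are gradual, not sharp.

**Angles** use total-least-squares constructions robust to small template
distortions: the para axis is the first principal direction of
{O4, C4, C1, C7} oriented O4 → C7 (fixing the α ↔ 180° − α ambiguity),
and the ring plane is the least-squares plane of the six ring carbons.
γ is folded to [0°, 90°] because an unsigned plane cannot distinguish its
two normals.  Angle histograms default to 3° bins, whose centers (1.5°,
4.5°, ...) tile both the [0°, 180°] and [0°, 90°] ranges exactly; joint
(α, β) maxima are bins strictly dominating their 8-neighborhood, ranked by
density.  Degenerate inputs — a molecule at the droplet center, a
collinear ring — raise errors rather than returning angles of undefined
meaning.

Coordinates are assumed pre-imaged (the droplet whole, no periodic
wrapping); frames are an unordered ensemble, so nothing dynamical
(diffusion, autocorrelation) is computed.

## 4. Induction time

The two-phase conjugated-diene curve is modelled as exactly two straight
lines.  For every admissible breakpoint (at least 3 points per side — two
to define a slope, one for residuals) both segments are fit by least
squares; the breakpoint minimizing the total SSE wins, and τ_IND is the
abscissa of the two lines' intersection.  The search is exhaustive, so it
is the global two-segment optimum by construction.  Parallel lines (no
kink) and intersections outside the observed time range are errors, not
numbers.  τ_IND is invariant under affine maps of the signal axis — which
is why the choice between raw absorbance and the percent-increase
transform `percent_delta_cd()` (defined operationally as
$100(A_t - A_0)/A_0$, without an instrument-specific calibration) cannot
change the extracted induction time, and is checked not to.

## 5. Problem sizes and limitations

The validation suite runs at deliberately modest sizes chosen as adequate
for the statistical checks they support: droplet round trips use hundreds
of oleic points and a few thousand water points over a handful of frames
(binomial standard errors of a few percent on region occupancies),
replicated fit recovery uses 200 seeded series of 8 points, and
orientation checks use up to a few thousand molecule-frames.  All
generators are deterministic given their seed, and internal randomness
(fit restarts) never touches the caller's RNG stream.

Known limitations: the partition model covers oil-insoluble antioxidants
only (one partition constant; amphiphilic solutes would need a second);
the generator validates the *analysis* code, not molecular reality — a
passing round trip says nothing about force-field accuracy; the oxidation
scheme is a minimal caricature adequate for lag/propagation shape studies,
not for quantitative chemistry of a real lipid matrix; and binary MD
trajectory formats are not read — convert to multi-MODEL PDB or XYZ first,
optionally remapping residue names via the `mapping` argument of
`read_frames()`.
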