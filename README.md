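# emulsiphase

Where does a water-soluble antioxidant sit in an oil-in-water nanoemulsion,
and how does that placement control lipid oxidation?  `emulsiphase` is an R
package for scientists who study antioxidant efficiency in emulsified
systems (food chemistry, colloid science, molecular modelling).  It bundles
three analyses that are usually scattered across lab notebooks and ad hoc
scripts, together with a synthetic-data generator that produces every input
with known ground truth:

1. **Pseudophase partitioning.**  The emulsion is treated as oil,
   interfacial and aqueous pseudophases with volume fractions
   Φ_O + Φ_I + Φ_W = 1.  For an oil-insoluble antioxidant, the distribution
   is set by one partition constant P = (AO_I)/(AO_W), and the observed
   rate constant of a probe reaction varies with the surfactant volume
   fraction as

       k_obs = [AO_T] · k_I · P / (Φ_I · P + Φ_W)

   Fitting (Φ_I, k_obs) pairs to this curve yields P and k_I; from P follow
   the interfacial percentage %AO_I = 100·Φ_I·P/(Φ_W + Φ_I·P) and the
   effective interfacial concentration (AO_I) = [AO_T]·(%AO_I/100)/Φ_I.

2. **Droplet geometry.**  Given stored configurations of a spherical
   droplet (synthetic, or converted MD output as multi-MODEL PDB /
   multi-frame XYZ), the package computes radial probability profiles per
   species, estimates the oil-core radius and interfacial thickness,
   classifies molecules into the three regions, measures per-oxygen
   insertion depths of gallic acid, and characterizes its tilt by three
   angles against the radial vector: α (para axis O4–C4–C1–C7), β (center
   of mass → C6) and γ (aromatic plane; 90° = ring parallel to the droplet
   surface), including 2-D (α, β) densities with ranked maxima.

3. **Oxidative stability.**  Conjugated-diene kinetic curves are reduced to
   an induction time τ_IND by the classical two-straight-line construction
   (exhaustive breakpoint search, least squares per segment, intersection
   abscissa), and antioxidant effectiveness is reported as the ratio of
   induction times with/without antioxidant.

## Worked example

```r
library(emulsiphase)

# --- partitioning: fit a noisy synthetic rate series ---------------------
series <- generate_kobs_series(p_wi = 93, k_i = 1e4, ao_total = 1e-4,
                               phi_oil = 0.10,
                               phi_list = seq(0.005, 0.04, length.out = 8),
                               noise_cv = 0.05, seed = 42)
fit <- fit_partition(series)
fit
#> <partition_fit> method: nonlinear (n = 8)
#>   P_w^i = 104.05 +/- 8.59
#>   k_i   = 9768.66 +/- 390
#>   RSS   = 14.19
```

The fitted partition constant (here 104 ± 9 from one noisy draw of a
series generated with P = 93) says the antioxidant favors the interface
about a hundred-fold over water.  Turning it into a distribution:

```r
distribution_table(fit$p_wi, ao_total = 1e-4, phi_oil = 0.10,
                   phi_list = c(0.005, 0.01, 0.02, 0.04))
#>   phi_interfacial phi_water pct_interfacial pct_aqueous conc_interfacial_M
#> 1           0.005     0.895           36.76       63.24           0.007352
#> 2           0.010     0.890           53.90       46.10           0.005390
#> 3           0.020     0.880           70.28       29.72           0.003514
#> 4           0.040     0.860           82.88       17.12           0.002072
```

More surfactant pulls a larger share of the antioxidant into the interface
(37% → 83%) yet *dilutes* its effective interfacial concentration
(7.4 mM → 2.1 mM), because the interfacial volume grows faster — the
central trade-off in formulating with surfactant.

```r
# --- geometry: build a droplet, recover its structure --------------------
spec <- species_spec(n_oleic = 400, n_water = 6000, seed = 1)
traj <- sample_trajectory(spec, 5)
bounds <- estimate_regions(
  radial_profile(traj, "oleic", 1, volume_corrected = TRUE),
  radial_profile(traj, "water", 1, volume_corrected = TRUE))
bounds
#> <region_boundaries> core 20 A | interface 17 A | water onset 37 A
round(region_fractions(traj, bounds, "antioxidant"), 2)
#>  pct_oil pct_interfacial  pct_aqueous
#>        0              95            5

# --- stability: induction times from simulated oxidation curves ----------
tg <- seq(0, 150, by = 0.25)
ctrl <- simulate_oxidation(kinetic_scheme_params(aoh0 = 0), tg, "control")
ao   <- simulate_oxidation(kinetic_scheme_params(aoh0 = 1e-7), tg, "antioxidant")
round(effectiveness_ratio(ao, ctrl), 2)
#> [1] 2.68
```

A configuration-driven run of all stages, with a JSON manifest and MD5
checksums for reproducibility, is available via
`run_pipeline(system.file("extdata", "pipeline_demo.yaml",
package = "emulsiphase"), out_dir)`.

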