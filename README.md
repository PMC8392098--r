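# glycodpd

Mesoscale simulation and analysis of the endothelial glycocalyx (EG) — the
bushy, sugar-rich layer on the blood-facing surface of vascular endothelium —
interacting with the glycocalyx of a passing red blood cell (RBC) through the
*near-field flow* of an explicit solvent. The two brushes never touch; the
question the package is built to answer is how much momentum each transmits
to the other through the fluid: how strongly a moving upper brush deforms the
tethered lower one, and whether the lower brush can, in turn, measurably
propel the upper surface.

The engine is a dissipative particle dynamics (DPD) simulator in reduced
units. Pairs of beads within the cutoff $r_c$ interact via

$$
\mathbf F_{ij} =
a_{ij} w(r)\,\mathbf e_{ij}
\;-\; \beta w^2(r)\,(\mathbf e_{ij}\!\cdot\!\mathbf v_{ij})\,\mathbf e_{ij}
\;+\; \sqrt{2\beta k_BT/\Delta t}\, w(r)\,\alpha_{ij}\,\mathbf e_{ij},
\qquad w(r) = 1 - r/r_c ,
$$

a soft conservative repulsion ($a_{ww}=25$, $a_{gw}=26.3$, $a_{gg}=30$), a
pair drag ($\beta = 4.5$) and a fluctuation–dissipation-matched random force
— together an exact momentum-conserving thermostat at $k_BT = 1$. Glycocalyx
chains are bead-spring filaments with harmonic bonds $E = k_s(r-b_0)^2$
($k_s = 100$, $b_0 = 0.5$) and harmonic bending
$E = \tfrac12 k_E(\varphi-\pi)^2$; the bending constant maps to an
Euler–Bernoulli rigidity $EI = k_E b_0 \approx 490$ pN nm at the baseline
$k_E/2 = 231$. Lower chains are wall-tethered; upper anchors ride a plane
driven at a constant streamwise speed. Integration is Groot–Warren modified
velocity-Verlet ($\Delta t = 10^{-3}\tau$, $\lambda = 0.65$) with
counter-based pair noise, so runs are bit-reproducible and restartable.

On top of the engine sit the study's full case matrix (`glyco_cases()`:
baseline, drive-speed, density, chain-length, stiffness, separation,
chain-release and activation-pulse variants, at full scale and two
desk-scale reductions) and tidy analysis tools: tip deflection and windowed
chain RMSD, B-spline brush interfaces, binned flow fields with circular
orientation statistics and Kolmogorov–Smirnov comparisons, shear profiles,
in-engine solvent viscosity calibration, per-bead lifting forces, and
rigid-cylinder RBC propulsion estimates with physical unit mapping.

Everything user-facing takes or returns tidy tibbles, with `autoplot()`
methods for flow fields and deflection series and broom-style
`tidy()`/`glance()` for runs. Intended users: people who model cell-surface
polymer layers and near-wall microcirculation and want a small, hackable,
fully scripted simulator rather than a LAMMPS deployment.

## Worked example

A complete run of the baseline case at the desk "micro" scale (720 beads,
5 τ equilibration + 16 τ production; geometric ratios of the full 432,000
bead system preserved, see the vignette):

```r
library(glycodpd)

cfg <- case_config("A", scale = "micro", seed = 101)
sys <- build_case(cfg)      # chains + solvent at density 3
sys <- equilibrate(sys)     # thermostat only, drives held
run <- run_production(sys)  # drive 0.05 r_c/tau on the upper anchors
glance(run)
#> # A tibble: 1 x 7
#>   case  n_beads n_chains n_frames production mean_kBT n_events
#>   <chr>   <int>    <int>    <int>      <dbl>    <dbl>    <int>
#> 1 A         720        8       64         16     1.00        0

# streamwise tip deflection of the four tethered chains, in r_c,
# relative to the end of equilibration
td <- tip_deflection(run)
dplyr::filter(td, time == 16)
#> # A tibble: 4 x 5
#>    time chain    dx     dy released
#>   <dbl> <int> <dbl>  <dbl> <lgl>
#> 1    16     1 1.07  -0.797 FALSE
#> 2    16     2 1.89   0.235 FALSE
#> 3    16     3 0.657 -1.64  FALSE
#> 4    16     4 0.343 -0.390 FALSE

# binned near-field flow and its orientation statistics
g <- bin_velocities(run, grid = c(16, 9, 1), window = c(2, 16))
orientation_stats(g)
#> # A tibble: 1 x 4
#>       n mean_theta resultant_length circ_sd
#>   <int>      <dbl>            <dbl>   <dbl>
#> 1   144   -0.00507           0.0382    2.56
```

`mean_kBT` is the production kinetic temperature (target 1); positive `dx`
is deflection in the drive direction; `circ_sd` is the circular standard
deviation of the per-bin flow orientations (higher = more disordered flow).
The same pipeline with `scale = "full"` reproduces the published geometry
(432,000 beads, 200 + 1600 τ) and is sized for a cluster, not a desk.

Physical anchoring:

```r
eg_bending_stiffness(kE_half = 231, b0 = 0.5)   # ~494 pN nm
to_physical(0.05, "velocity", unit_map())       # drive speed in nm/us
```

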