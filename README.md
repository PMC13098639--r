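# necrotherm

Pulsed near-infrared lasers used for photoacoustic imaging and surgical
guidance can thermally damage the organs they illuminate, and regulatory
exposure limits exist only for skin and eyes. necrotherm is an R package
for researchers assessing laser safety in internal tissues (liver in its
defaults). It does two things:

1. **Predicts** the percentage of necrotic tissue produced by a given
   laser exposure, by chaining three physical models;
2. **Measures** necrosis from digitized cleaved Caspase-3
   immunohistochemistry (IHC) sections — maps, areas and reconstructed
   volumes — so predictions can be validated quantitatively instead of by
   categorical pathology grades.

## The models

**Photon transport.** A voxel Monte Carlo deposits laser energy in a
homogeneous tissue block: exponential free paths with
$\mu_t = \mu_a + \mu_s$, implicit capture (a fraction $\mu_a/\mu_t$ of the
packet weight absorbed per interaction), Henyey–Greenstein scattering with
anisotropy $g$, Russian roulette termination. Output is the normalized
energy density (1/m³): multiplied by a source power it is the volumetric
heat source $Q$.

**Bioheat transfer.** The Pennes equation,
$\rho c_p \,\partial T/\partial t = \nabla\cdot(k\nabla T) + Q +
\rho_b c_b \omega_b (T_b - T) + Q_{met}$, with
$Q = P \cdot \text{EnergyDensity} \cdot \text{ONOFF}(t)$, is advanced by
explicit finite differences: free convection on the irradiated face,
fixed temperature elsewhere. For minutes-long pulse trains the
time-averaged source ($E \times f_{rep}$) replaces the ns-resolved pulsed
one; the single-pulse adiabatic rise $\mu_a F/(\rho c_p) \approx 0.1$ K
justifies this.

**Damage kinetics.** The degree of injury follows
$d\alpha/dt = (1-\alpha)^n A\, e^{-\Delta E/(R T(t))}$ with liver
constants $A = 5.51\times10^{41}\,\mathrm{s^{-1}}$,
$\Delta E = 2.77\times10^{5}\,\mathrm{J/mol}$, $n = 3$; the necrotic
fraction is $\theta_d = \min(\max(\alpha,0),1)$, reported in percent.

**Histology.** Sections are tiled by the power-of-two mosaic rule (4 MiB
per tile), cells are segmented (pluggable segmenter with a classical
default) and classified blue/brown by RGB box rules, and each 200 µm
patch is scored $\Gamma e^{-100\rho} \times 100\%$, where $\Gamma$ is the
blue area fraction among classified cells and $\rho$ the brown area
fraction of the patch. Artifacts are removed by two-stage multilevel-Otsu
/ solidity filtering; serial sections are rigidly registered, maps are
warped, depth-interpolated (40 µm → 4 µm) and reduced to volume,
area-vs-depth and percent-vs-depth metrics. A synthetic-fixture module
generates IHC-like sections and stacks with analytic ground truth.

## Worked example

```r
library(necrotherm)

peakPower(0.073, 5e-9)   # 1.46e7  W   (73 mJ / 5 ns pulse)
fluence(73, 5)           # 371.79  mJ/cm2 (5 mm flat-top beam)

## photon transport on a 20 mm liver cube, 0.5 mm voxels
grid <- voxelGrid(20, 0.5)
dens <- runPhotonTransport(opticalProperties(), beamSpec(grid = grid),
                           grid, n_photons = 2e5, seed = 1)
dens
#> EnergyDensityGrid: 40 x 40 x 40 voxels (0.5 mm), 200000 photons,
#> escaped fraction 0.3261

## bioheat + damage for three exposure cases
rep <- predictNecrosis(
  data.frame(energy_mJ = c(73, 73, 30), duration_min = c(10, 20, 20)),
  boundary = boundarySpec(h_conv = 5), density = dens)
#> 73 mJ, 10 min: plateau 330.34 K, necrosis 67.72%
#> 73 mJ, 20 min: plateau 330.34 K, necrosis 77.67%
#> 30 mJ, 20 min: plateau 317.24 K, necrosis 12.18%
```

The probe trace climbs fast while conduction and perfusion are cold,
slows as the perfusion sink engages, and plateaus; the Arrhenius integral
along that trace gives the necrosis percentage. A 73 mJ exposure is
predicted to cause severe necrosis at 10–20 min while 30 mJ stays mild —
the basis for exposure-time safety limits at these beam parameters.

On the histology side, against a synthetic section with known geometry:

```r
p  <- synthSectionParams(canvas_um = 1000, um_per_px = 0.5,
                         radius_um = 300, ring_width_um = 60)
fx  <- genSection(p, seed = 7)          # section + analytic ground truth
map <- quantifySection(fx$section)      # segment -> classify -> patches
round(values(map))
#>      [,1] [,2] [,3] [,4] [,5]
#> [1,]   38    5    0    9   20
#> [2,]   10    0   66    0   15
#> [3,]    0   49  100   47    0
#> [4,]    5    0   43    7   20
#> [5,]   30    7    0   12   32
mean(abs(values(map) - values(fx$truth)))  # 1.9 percentage points
```

The central patch inside the lesion scores 100 % (blue-only: the
apoptosis marker is absent where tissue is necrotic); patches on the
brown ring collapse toward 0; peripheral patches carry moderate artifact
scores that the two-stage filter (`stage1Centroid()`, `stage2Filter()`)
removes before volumetry (`registerStack()`, `interpolateStack()`,
`volumeMetrics()`).

A thin CLI over the same functions is installed at
`inst/scripts/necrotherm.R` (subcommands `mc`, `bioheat`, `damage`,
`simulate`, `quantify`, `reconstruct`, `synth`).

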