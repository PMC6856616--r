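# mitovolt

Quantification of **intramitochondrial membrane-potential heterogeneity**
from two-channel live-cell fluorescence imaging — for cell biologists and
microscopists measuring ΔΨ differences *within* single mitochondria:
cristae versus inner boundary membrane (IBM), detached hyperpolarized
vesicles, flickering, and wave-like laser-induced depolarization.

## The model

Monovalent cationic potentiometric dyes (TMRE/TMRM/Rho123) partition
Nernstianly, so a potential difference between two compartments follows
from their fluorescence intensities:

    Δψ(a−b) = κ · ln(F_a / F_b),   κ = 1000·R·T/F ≈ 26.73 mV at 310.15 K

The package converts compartment intensities into mV tables
(`nernst_delta_psi()`, `compartment_potentials()`, `delta_psi_cr_ibm()`),
after rolling-ball background subtraction, segmentation on a structural
membrane dye channel (NAO/MitoTracker Green), axis extraction, crista peak
detection and pixel classification. Time-domain tools track per-crista
potentials, decompose flickers into potential-dependent and bound-dye
components, separate within- from between-crista variability, and measure
depolarization-wave fronts and speeds.

Because such studies publish values but not images, the package includes a
**ground-truthed forward simulator** (`sim_scenario()`, `preset_scenario()`,
`simulate_timelapse()`): capsule geometry, Nernstian dye partitioning with a
potential-independent bound fraction, Gaussian PSF, Poisson + read noise,
and events (flicker / wave / partial depolarization). Every pipeline stage
is validated by parameter recovery against simulator ground truth.

## Worked example

```r
library(mitovolt)

sc  <- preset_scenario("control", seed = 7)   # true ΔΨ(Cr−IBM) = 10.11 mV
sim <- simulate_timelapse(sc)                 # 10 frames, 2 channels + truth
res <- analyze_stack(sim$stack)

aggregate(delta_psi_cr_ibm_mv ~ crista_id, res$cristae, mean)
#>   crista_id delta_psi_cr_ibm_mv
#> 1         1               10.55
#> 2         2                9.50
#> 3         3                9.72
#> 4         4                9.19
#> 5         5                9.75
#> 6         6                9.75
#> 7         7               10.16
#> 8         8               10.40
```

The eight detected cristae recover the simulated 10.11 mV crista–IBM
difference to within ~1 mV each (mean 9.88 mV here). The raw intensity
ratio would read ~26 mV — PSF mixing around sub-resolution membranes biases
raw ratios, and the pipeline corrects it with a simulator-derived contrast
calibration (see the methods vignette; `delta_psi_raw_mv` keeps the
uncorrected value). `res$morphometrics` carries shape statistics (this
object: area 5.39 µm², circularity 0.38, aspect ratio 6.5) and
`res$potentials` per-compartment mV against the whole-organelle or IBM
reference.

Dynamics, e.g. a depolarization wave:

```r
resw <- analyze_stack(simulate_timelapse(preset_scenario("wave", seed = 2))$stack)
analyze_wave(resw, site_um = 0.5, t0_s = 3)$speed_um_per_s  # ~5 µm/s, class "wavelike"
```

## Command line

```sh
Rscript inst/cli/mitovolt simulate --preset control --seed 7 --out sim/
Rscript inst/cli/mitovolt analyze  --in sim/ --out results/ [--config cfg.json]
Rscript inst/cli/mitovolt batch    --in sims/ --out results/
Rscript inst/cli/mitovolt report   --in results/
```

`simulate` writes per-channel multi-page TIFFs, a JSON metadata sidecar and
ground truth; `analyze` writes `morphometrics.csv`, `potentials.csv`,
`cristae.csv`, `events.csv`, a run manifest and a pseudo-colour LUT render.

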