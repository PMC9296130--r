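---
title: "Models and methods behind slimsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slimsep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimsep)
```

`slimsep` characterizes high-resolution traveling-wave ion mobility (IM)
separations on structures for lossless ion manipulation (SLIM): long
serpentine tracks of printed-circuit-board electrodes on which a stepped
potential waveform propels ions through a buffer gas. This vignette
documents the models the package implements, the tunable parameters and
their defaults, and the design decisions taken where the underlying
science leaves room for choice.

## Track geometry and waveform

One cycle of the drive waveform spans `pads_per_cycle` conveyor pads
(default 8) of pitch `pad_pitch_mm` (default 1.125 mm: a 1.0 mm pad plus a
0.125 mm gap), giving a 9.0 mm wavelength. The wave advances one
wavelength per switching cycle, so wave speed and switching frequency
interconvert through the wavelength: 5–25 kHz corresponds to 45–225 m/s.
Set counting uses floor division — a partial set at the track end is not
counted — so a 13 m path holds 1444 complete sets per row, and with the
5 conveyor rows per board, 57 760 pad electrodes. Whether a set count
should be quoted per row or across rows is ambiguous in common usage; the
package exposes the per-row count with `n_rows` as an explicit multiplier
in `conveyor_pad_count()`.

`waveform_potentials()` returns instantaneous pad potentials. The sine
drive places `(A/2)·sin(2πft − i·45°)` on pad *i*; the square drive is the
stepped two-level realization (four pads at `+A/2`, four at `−A/2`, the
block advancing one pad per switching step), which is the digital
approximation historically used to emulate a traveling sinusoid.

## Transport model: surfing and roll-over

The generator's backbone is a deterministic mean-speed law. An ion of
low-field mobility `K` in a traveling sinusoidal potential is
characterized by the dimensionless ratio

> c = K · E_eff / v_wave,

the ion's maximum field-driven drift speed over the wave speed. For
`c ≥ 1` the ion locks into a wave trough and *surfs* at exactly the wave
speed — no mobility selectivity. For `c < 1` it repeatedly rolls over wave
crests and advances at the mean speed

> v̄ = v_wave · (1 − sqrt(1 − c²)),

which is monotone in `c` and quadratic in mobility for small `c`. This
closed form is a model choice, not a measured transport law: it is the
standard mean velocity of an overdamped particle in a traveling sinusoidal
field, and it reproduces the qualitative surfing-to-drift transition that
traveling-wave instruments exhibit.

Two physically motivated factors enter `E_eff`:

* **Field attenuation.** The drive is applied at the board surfaces, 3 mm
  apart; a spatially periodic surface potential decays away from its plane
  as `exp(−2πy/λ)`. At the midplane (`y = 1.5 mm`, `λ = 9 mm`) this gives
  0.351, the default `field_attenuation`. Without this factor every
  tune-mix ion would surf at all surveyed speeds and amplitudes, which is
  plainly not how the instruments behave.
* **Square-wave fundamental.** A square drive is represented by its
  fundamental Fourier harmonic, whose amplitude is 4/π times that of the
  sine of equal peak-to-peak span. The square drive therefore pushes more
  ions into surfing at equal settings — reproducing the observation that
  fewer species separate under square-wave operation (58% vs 69% of grid
  cells under the package defaults).

Mobilities come from the Mason–Schamp relation at the configured gas
state (default 2.5 Torr N₂; temperature is rarely quoted for such
instruments, so the default is 300 K and configurable), with the
ion-neutral reduced mass computed from `m_ion = mz × z` — electron and
adduct masses are folded into the measured m/z, a documented
simplification that is negligible at these masses. Arrival time is
`L / v̄ + t0`, with `t0` (default 5 ms) covering the non-IM portions of the
flight path (transfer optics, TOF stage).

## Peak-width model

Three contributions are added in quadrature (all as fwhm, in ms):

1. **Dispersion**: spatial spread `σ = sqrt(2 D t_drift)` with
   `D = diffusion_scale · kB·T·K/q`, converted to time through the mean
   ion speed. The Einstein free-flight coefficient alone under-predicts
   the peak widths observed on 13 m SLIM tracks by roughly a factor of
   two (equivalently, over-predicts CCS-space resolving powers severalfold):
   wave-driven ion heating and intra-well mixing enhance effective axial
   dispersion. `diffusion_scale = 5` reproduces the mid-panel resolving
   power scale (about 200–320 in CCS space) that such instruments report.
2. **Instrument floor** (`fwhm_floor_ms = 2.5`): the released ion packet
   has finite temporal width set by the accumulation-gate release and
   detector response.
3. **Near-boundary intermittency**
   (`boundary_scale · c^boundary_power · (t_drift − t_surf)`, defaults 0.3
   and 20): ions traveling just below the surfing threshold intermittently
   lock to the wave, degrading their peaks. The steep `c^20` onset makes
   the term material only above roughly `c ≈ 0.85`. Without it the smooth
   roll-over law would predict the *highest* resolving powers for the
   fastest near-surfing arrivals, inverting the observed regime structure
   in which short arrival times show little useful separation.

Under these defaults the simulated benchmark grid reproduces the
characteristic three-regime structure: surfing arrivals with no
selectivity, an intermediate high-resolution band (maximum median
CCS-based resolving power in the 200–700 ms range), and a
diffusion-degraded tail with medians falling below 200 beyond about
1.2 s.

## Resolving power and separation metrics

Peak centroids and fwhm come from Gaussian (normal-distribution)
least-squares fits with a co-fitted constant baseline and no smoothing
(`fit_peaks()`, Levenberg–Marquardt via `minpack.lm`). Arrival-time widths
are carried into CCS space through a *local* linear slope between two
peaks of known CCS (`ccs_per_time_slope()`): the global time–CCS relation
of traveling-wave instruments is nonlinear, but across the width of a
single peak the linearization is accurate. The CCS-based resolving power
is `R_p = CCS / (|slope| · Δt_fwhm)`; for multi-peak spectra the average
CCS (and average width) is used.

Two-peak resolution uses the Gaussian baseline-width convention,
`R_pp = 2·Δt / (1.699·(fwhm₁ + fwhm₂))`; the 1.699 factor (width at 4σ
over fwhm) is a documented, swappable choice. It is internally consistent
with the percent-valley metric,
`V = 100·(1 − I_valley / I_lower_apex)`: equal Gaussians at `R_pp = 1.5`
give a 97.8% valley (effectively baseline-resolved), and at `R_pp = 1.1`
an 82% valley — matching the pairings quoted for ganglioside and
triglyceride isomer separations. The *lower* apex is the denominator, a
conservative choice for unequal-abundance isomer mixtures. Percent CCS
difference uses the smaller CCS as denominator.

## Reduced-CCS calibration

Reference CCS values are transformed to "reduced CCS",
`CCS′ = CCS·sqrt(μ)/z`, folding out the reduced-mass and charge
dependencies so one curve spans ions of different mass and charge (this is
distinct from the transport-theory reduced CCS that removes hard-sphere
contributions). `fit_calibration()` fits `CCS′` against arrival time with
a power law (`a·t^b`), or a second- or third-order raw polynomial, by
unweighted least squares with no arrival-time offset subtraction
(an optional refinement left to the user). Models store their valid time
range; predictions outside it require an explicit `extrapolate = TRUE`,
because polynomial calibrations extrapolate badly. Bias is the signed
percent deviation of calibrated versus reference CCS.

On synthetic tune-mix ladders generated by the transport model at
40 V_pp/180 m/s, the third-order polynomial attains `R² ≈ 1.0000` with a
mean absolute bias of about 0.02%, versus roughly 1.2% for the power fit —
the same ordering reported for real SLIM calibrations, driven by the
genuine curvature of the time–CCS′ relation.

## The synthetic tune-mix panel

`tune_mix_panel()` returns the eight singly charged fluoroalkyl
phosphazene ions (m/z 622–2722) that anchor positive-mode work. Their
reference CCS values live in instrument-lab supplementary material rather
than in any table this package could cite, so the packaged ladder is
**synthetic**: the smooth power law `6.81·mz^0.527` Å² (202–440 Å² across
the panel), monotone in m/z and of realistic magnitude for this compound
class. It is clearly labelled as such (also in
`extdata/tune_mix_synthetic_ccs.csv`) and user-supplied values override
it.

## What the generator does and does not emulate

Simulated traces are sums of ideal Gaussians on a regular grid with
seeded Gaussian (default, σ = 1% of the tallest peak) or Poisson noise.
The generator reproduces: the three arrival-time regimes, the monotone
push toward surfing with falling wave speed or rising amplitude, the
narrower separating range of the square drive, diffusion-scaled widths
growing as `sqrt(t)`, and calibration curvature. It does **not** emulate
peak tailing or fronting, space-charge effects, ion losses or
transmission rolloff, fragile-ion heating artifacts, chemical noise, or
detector saturation — so passing tests demonstrate the correctness of the
analysis chain on idealized data, not instrument fidelity. Hardware
control, RF confinement physics, vendor file formats, and multipass
designs are out of scope.

## Numerical choices

* Sampling: 0.05 ms default interval; fit windows need at least 10
  samples per expected peak.
* Fit starting values: iterative peak-pick-and-subtract with half-max
  width estimates; joint multi-Gaussian fits bounded (heights ≥ 0, widths
  between a tenth of a sample and the window span).
* Non-convergence is flagged per peak (`converged = FALSE`), never
  silently dropped; over-specified fits leave surplus components flagged
  or collapsed onto coincident centroids.
* Peaks sort by centroid; exact ties order by descending height.
* Valley detection uses observed apex positions (tallest sample within
  half a fwhm of each centroid); a merged feature — no interior minimum
  between distinct apexes — reports 0% with a `no_valley` flag.
* Seeds: every stochastic step derives deterministically from one master
  seed (kept within 32-bit integer range); generation is bit-reproducible
  and does not disturb the session RNG stream.

## Problem sizes used by the test and acceptance runs

The default benchmark grid is the full surveyed space — 8 ions × 5 wave
speeds × 3 amplitudes × 2 waveforms × 3 replicates = 720 records — and
runs in a few seconds. Monte-Carlo fit-recovery checks use 100 seeded
replicates of a single mid-panel ion. Calibration comparisons use the
8-point tune-mix ladder. These sizes were chosen as the smallest that
exercise every regime of the model.

## Known limitations

* The roll-over law is deterministic; real near-boundary transport is
  stochastic, and the intermittency width term is a phenomenological
  stand-in with a steepness (`c^20`) that was chosen, not derived.
* The synthetic CCS ladder is not literature data; absolute simulated
  resolving powers track the width-model calibration and should not be
  quoted as instrument performance.
* Windowed per-peak fitting in `run_grid()` assumes predicted centroids
  are good initializers, which holds for simulated data but would need
  peak detection for real traces.
* The calibration assumes arrival order follows CCS order within an
  acquisition; chimeric or overlapping calibrant peaks are not handled.
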