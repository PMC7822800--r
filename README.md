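# dosekit

Desk-scale Monte Carlo X-ray dose estimation on voxel phantoms, with a
filtering-based variance-reduction scheme: simulate on a down-sampled
patient model, then reconstruct the high-resolution dose distribution by
guided filtering in the photon-energy-fluence domain.

## The problem and the method

Organ dose estimation for fluoroscopically guided procedures needs smooth,
high-resolution absorbed-dose volumes `D` inside a patient model, but the
per-voxel noise of a Monte Carlo estimate falls only as `1/sqrt(N)`
histories.  `dosekit` accelerates this in two steps:

1. **Down-sample the patient model**, not the dose: each in-plane `s x s`
   neighbourhood of the label volume is replaced by its statistical mode,
   so the locally dominant tissue is preserved, and the simulation runs on
   the coarse grid (Woodcock delta-tracking photon transport, kerma
   approximation, primary/scatter separation, air-kerma normalization at
   the interventional reference point).
2. **Reconstruct in the fluence domain.**  Under charged-particle
   equilibrium, `D = psi * (muen/rho)`: the energy fluence `psi` is smooth
   across tissue boundaries while the mass energy-absorption coefficient
   `muen/rho` is piecewise constant per tissue.  The coarse dose `D_n` is
   divided by the down-sampled coefficient map, up-sampled, filtered
   slice-wise with the 2-D guided filter using the high-resolution
   `muen/rho` map as guidance (radius `r(s) = round(s/2) + 1`), and
   multiplied back:

   `D = (muen/rho) * GF( (muen/rho), D_n / mode_downsample(muen/rho), r(s) )`

Supporting modules provide a synthetic head phantom (air / scalp /
adipose / average-bone shell / brain), embedded tissue
interaction-coefficient tables over 5-150 keV, tabulated and analytic
tube spectra, C-arm beam geometry in SE(3), MHD and NIfTI volume I/O,
error metrics, slice-wise organ dose, and comparison of simulated doses
against point-dosimeter readings with 2-sigma confidence intervals.

## Worked example

```r
library(dosekit)

lib   <- build_material_library()
ph    <- make_head_phantom(64, 8, spacing = c(2.4, 2.4, 10), seed = 0)
beam  <- beam_setup(primary_angle = 0, sod = 800, sid = 1200,
                    opening_phi = 3, opening_theta = 6,
                    spectrum = load_spectrum(system.file(
                      "extdata", "spectra", "spectrum_120kvp.csv",
                      package = "dosekit")))

rec <- reconstruct_from_simulation(ph, lib, beam, downsample_spec(4),
                                   n_histories = 2e6, seed = 1,
                                   air_kerma_mGy = 49.28)
rec$coarse
#> <dose_result> 2e+06 histories (10 batches, seed 1)
#>   reference-point air kerma: 49.28 mGy
#>   max total dose: 167.9 mGy

head(slice_organ_dose(rec$dose, ph, organ_label = 4), 3)
#>   slice dose_mGy n_voxels
#> 1     3 8.007977     1100
#> 2     4 9.576355     1660
#> 3     5 9.439083     1660
```

The coarse simulation ran on a 16 x 16 x 8 grid (`s = 4`); the
reconstruction is on the full 64 x 64 x 8 grid.  The air kerma printed is
the measured value the whole volume was scaled to; the organ table is the
slice-wise brain-equivalent dose in mGy (for photons, equivalent dose
equals absorbed dose).

A YAML-driven end-to-end run (phantom, simulation, scaling,
reconstruction, metrics, JSON report, optional measurement comparison) is
available as `run_pipeline("run.yaml")` or from the shell via the thin
wrapper `inst/cli/dosekit` (`simulate`, `pipeline`, `downsample`,
`upsample` subcommands).

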