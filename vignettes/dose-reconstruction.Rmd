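---
title: "Accelerated voxel Monte Carlo dose estimation with guided-filter super-resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated voxel Monte Carlo dose estimation with guided-filter super-resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Organ dose estimation for fluoroscopically guided interventions requires
solving the photon transport problem inside a patient model.  Monte Carlo
(MC) simulation is the reference method, but the per-voxel statistical
noise of a dose estimate falls only as the square root of the number of
simulated photon histories: smooth high-resolution dose volumes are
expensive, which is a problem when the simulation is supposed to run
*alongside* an experiment (for example, to cross-validate point dosimeter
readings while the phantom is still on the table).

`dosekit` implements a desk-scale version of this workflow:

1. a voxel-phantom MC photon transport kernel with Woodcock delta-tracking
   and kerma-approximation scoring,
2. a variance-reduction scheme that simulates on a *down-sampled* patient
   model and reconstructs the high-resolution dose distribution by guided
   filtering in the photon-energy-fluence domain, and
3. evaluation utilities: air-kerma normalization, error metrics,
   slice-wise organ dose, and comparison against point measurements with
   their 2-sigma confidence intervals.

# Transport model and its assumptions

Photon histories are sampled from a discrete tube spectrum and emitted
from the focal spot uniformly over a rectangular collimation pyramid (a
flat-detector field).  Free paths are sampled by Woodcock delta-tracking:
the flight distance is drawn against the volume-wide majorant attenuation
`max_x mu(x, E)` and a candidate collision at a voxel with attenuation
`mu` is accepted as real with probability `mu / mu_maj`, otherwise the
photon continues unchanged.  This avoids per-voxel boundary crossings
entirely; because the majorant is evaluated per photon energy (and linear
interpolation of a pointwise maximum dominates the interpolated
coefficients), the acceptance ratio never exceeds one.

Real interactions are selected from tabulated per-material interaction
fractions:

* **photoelectric** — the full photon energy is deposited in the voxel and
  the history ends;
* **Compton** — the scattered energy and angle are sampled from the
  Klein-Nishina distribution with Kahn's rejection method; the electron
  recoil energy is deposited in the voxel (kerma approximation: no
  secondary-electron transport, adequate in the diagnostic energy range
  where electron ranges are below the voxel size);
* **Rayleigh** — elastic scattering with the Thomson angular shape
  (`1 + cos^2`), with no atomic form factors.

Photons are terminated below 5 keV (local absorption).  Characteristic
X-rays, bremsstrahlung from secondaries, bound-Compton/Doppler effects and
polarization are not modelled; the package targets relative dose
distributions and their reconstruction, not Geant4-grade absolute physics.

A photon counts as **primary** until its first Compton or Rayleigh event;
the energy it transfers at that first event is still scored as primary
dose, everything afterwards as scatter.  Primary dose is therefore exactly
zero outside the collimation pyramid while scatter is not.

Absolute normalization follows the clinical convention: the free-in-air
collision kerma of primary photons is scored with a track-length estimator
in a 1 cm^3 air cell at the interventional reference point (by default 150
mm from the isocenter toward the source, the IEC convention), and all dose
grids are scaled by the ratio of the machine-reported air kerma to this
simulated value.

The random stream is a counter-based generator seeded per history index,
so results are bit-reproducible for a given seed, independent of the batch
decomposition used for uncertainty estimation, and uncoupled from R's RNG.

# Fluence-domain guided-filter super-resolution

The variance-reduction scheme rests on two observations:

* Down-sampling the label volume in-plane by a factor `s` (axial slices
  are kept) and simulating on the coarse grid concentrates the same number
  of interaction events in `s^2`-fold larger voxels, cutting the per-voxel
  noise accordingly, at the cost of spatial resolution.  The coarse label
  of each `s x s` window is its **statistical mode**, so the locally
  dominant tissue is always represented; ties break deterministically to
  the denser tissue, then to the lower label id.
* Under charged-particle equilibrium the absorbed dose factorizes as
  `D = psi * (muen/rho)` into the photon energy fluence `psi` — smooth
  across tissue boundaries — and the mass energy-absorption coefficient —
  piecewise constant per tissue.  Dividing a dose volume by a
  spectrum-averaged `muen/rho` map therefore moves it into a domain where
  smoothing does not blur anatomy.

The reconstruction of a high-resolution dose from a coarse one proceeds
slice by slice: divide the coarse dose by the coarse guidance map
(`muen/rho` of the coarse labels), replicate each coarse voxel to its
`s x s` window (nearest neighbour; the edge-aware filter supplies all
smoothing), apply the 2-D guided filter with the high-resolution guidance
image, and multiply by the high-resolution guidance map.  Negative filter
output is clamped to zero.  The guided filter is the standard box-window
algorithm: a local linear model of the output on the guidance image,
ridge-regularized by `eps`, with model coefficients averaged over all
windows covering a pixel; border windows use their valid (shrunken) area.

Tunable parameters:

| parameter | default | meaning |
|---|---|---|
| `s` | — | in-plane down-sampling window (voxels) |
| `radius` | `round(s/2) + 1` | guided-filter box radius (high-resolution pixels); tracks the window size so the filter support just bridges one coarse block |
| `eps` | `(0.01 * range(guidance))^2` | ridge regularizer; small relative to the squared guidance contrast between tissues, so tissue edges are preserved while flat regions are smoothed |
| energy cutoff | 5 keV | photon termination |
| reference offset | 150 mm | air-kerma scoring point |

The `eps` default follows common guided-filter practice (a percent of the
guidance dynamic range, squared).  Because the guidance map contains only
a handful of distinct tissue values, the filter behaves like an
edge-stopped box smoother: within one tissue the local guidance variance
vanishes and the output is iterated box averaging; across a tissue edge
the linear model transfers the fluence level without blurring the edge.

Two design points were settled empirically during development and are
worth recording.  First, replicating the coarse fluence by nearest
neighbour before filtering outperformed bilinear interpolation on a
noise-free analytic test field at every scale; bilinear interpolation
pre-blurs across tissue boundaries in exactly the places where the filter
could otherwise exploit the guidance edge, so nearest-neighbour
replication is used.  Second, the fraction-of-mass (FoM) weighted-mean
down-sampling is retained as a comparison arm operating on dose volumes
(its mass-weighted window total is conserved exactly, which the test suite
asserts); the simulation path always uses the statistical mode, because a
weighted-mean label has no material meaning for transport.

# The synthetic head phantom

Real studies use segmented CT scans of anthropomorphic phantoms.  The
package ships a parametric stand-in, `make_head_phantom()`: an axial slab
through an ellipsoidal head with an air background, a brain, a cranial
bone shell built by morphological dilation of the brain (guaranteeing that
every axis-aligned ray leaving the brain crosses bone), a soft-tissue
scalp, and a few adipose pockets.  Shell thicknesses are anatomical
(about 6 mm of "average bone" — the whole-skeleton tissue class used in
four-tissue dosimetry, not cortical bone — and 5 mm of scalp) and adapt to
the voxel spacing.  The tissue set matches the four-class simplification
common in dosimetry (air / soft tissue / adipose / bone) plus an explicit
brain label so organ-dose summaries have a target.

What the phantom does *not* emulate: anatomical texture and fine bone
structure (trabecular detail, facial bones, sinuses), partial-volume
mixtures, and the large body cross-section of a torso slab.  Passing the
reconstruction benchmarks on this phantom therefore demonstrates the
mechanics and scaling of the method, not its error level on real anatomy;
in particular the phantom's smooth interior is *easier* to reconstruct
than textured anatomy, while its proportionally large head rim (grazing
X-ray incidence) and thin bone shell are *harder* than a torso interior.

# Embedded material data

No cross-section library is assumed at run time.  The package ships CSV
tables per tissue (air, soft tissue, adipose, average bone, brain,
inflated lung, water, plus aluminium and copper for filtration) on a 5-150
keV grid: total mass attenuation and mass energy-absorption coefficients
from standard compilations, with interaction-type fractions derived from
the Klein-Nishina cross section (Compton) and an energy/Z-dependent split
of the remainder between photoelectric absorption and Rayleigh scattering.
Coefficients are log-log interpolated between grid points.  These tables
are accurate to a few percent, which suffices for the package's relative
reconstruction experiments; they are not a dosimetric reference.

Tube spectra are either loaded from two-column CSVs or generated by an
analytic fallback (Kramers-shaped bremsstrahlung hardened by 2.3 mm
aluminium-equivalent inherent filtration plus optional added filtration).
The shipped `spectrum_*.csv` tables were produced with this generator and
are labelled by their peak voltage.

# The reconstruction benchmark

`benchmark_reconstruction()` is the package's headline experiment and the
basis of `scripts/acceptance.R`.  Conditions (chosen once, as the study
conditions of the package):

* phantom: `make_head_phantom(128, 8, spacing = c(1.2, 1.2, 10), seed = 0)`
  — a 154 mm field of view with in-plane resolution close to a clinical
  head protocol and thick axial slices;
* beam: 120 kVp tabulated spectrum, posteroanterior, SOD 800 mm /
  SID 1200 mm, half-openings chosen so that the primary field lies inside
  the head laterally (a neuro-interventional field targeting the brain);
  all doses scaled to a 49.28 mGy reference-point air kerma;
* statistics: a full-resolution reference with `n_ref = 2.4e8` histories
  and coarse simulations with `n_ref / 2`, which places the median in-beam
  relative 2-sigma uncertainty of the reference in the range reported for
  full-scale reference simulations (roughly 3-14 %); the low-statistics
  arm repeats the coarse simulations with 100-fold fewer histories;
* evaluation: mean absolute percentage error over in-beam, in-body voxels
  with positive reference dose, for `s` in {2, 4, 8, 16}.

These sizes keep the full benchmark at a few minutes on one CPU.  The
known failure modes concentrate exactly where theory predicts: at the
tangential rim of the head, where the fluence changes by large factors
between neighbouring columns and any local model mis-extrapolates, and at
`s = 16`, where a 6 mm bone shell can no longer be the modal tissue of a
19 mm window, so the coarse phantom loses its skull and the transported
fluence inside is biased high.  Both effects grow as the object shrinks
relative to the window; they are intrinsic to mode down-sampling at
aggressive scales on a small head, and the benchmark reports them rather
than masking them.

# Numerical choices and degenerate inputs

* Trailing windows when `s` does not divide the in-plane extent keep their
  actual (smaller) size; anatomy is never cropped.
* Mode ties: highest density, then lowest label id — fully deterministic.
* Division by the guidance map floors it at its smallest positive value;
  air carries its own small positive `muen/rho`, so the fluence transform
  is defined everywhere.
* Zero-mass FoM windows (pure vacuum) fall back to the unweighted mean
  with a warning.
* Voxel world convention: `origin` is the grid corner; the centre of voxel
  `(i, j, k)` (0-based) is `origin + (index + 0.5) * spacing`, in mm.
* Batch uncertainty uses the batch-means estimator; voxels with zero dose
  are flagged at 100 %.  Histories divide across batches as evenly as
  possible; the counter-based stream makes the estimate independent of the
  batch count.
* An empty beam-phantom intersection yields a warning and an all-zero
  patient dose rather than an error, so parameter sweeps do not abort.

# Limitations

* Kerma approximation and free (unbound) Compton electrons: no electron
  transport, no Doppler broadening, no form factors; absolute doses are
  not reference-grade even though relative distributions are sound.
* Analog scoring only (besides delta-tracking): no track-length kerma
  estimator for patient dose, so deep low-dose regions stay noisy.
* 2-D slice-wise filtering: axial resolution is never reconstructed.
* Aggressive down-sampling (`s = 16`) on head-sized objects deletes thin
  bone from the coarse model; the reconstruction inherits the resulting
  fluence bias.  Use moderate scales for small anatomy.
* The synthetic phantom's limitations listed above.
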