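---
title: "Methods: bilayer observables and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilayer observables and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayr)
```

`bilayr` analyses trajectories of two-leaflet lipid bilayers in
orthorhombic periodic boxes, with the membrane normal fixed to the
z-axis. This vignette records the model behind each observable, the
numerical choices the implementation makes where the literature is
silent, what the synthetic-bilayer generator does and does not emulate,
and the known limitations.

## Data model

A **topology** is an atom table (0-based `atom_id`, lipid membership,
species, a role in `{head, sn1, sn2, other}` with a 1-based carbon index
for chain atoms, a partial charge in elementary-charge units, and a
free-form selector label) plus a per-lipid table carrying the leaflet
assignment. Two invariants are enforced at construction: chain carbon
indices are strictly increasing and contiguous within each tail, and
each lipid is net-neutral to 1e-6 e, matching the usual setup of
ionizable-lipid simulations at neutral-pH protonation states where no
counterions are present.

A **trajectory** is an ordered list of frames (time in ps, N x 3
coordinates in nm, box lengths in nm) with an analysis window; by
convention only the equilibrated tail of a production run is analysed,
so every observable averages over the window, which defaults to the full
range and is set with `set_window()`. Coordinates are stored wrapped
into the primary box, as coordinate formats deliver them; the explicit
unwrapping step `unwrap_lateral()` reconstructs continuous tracks where
dynamics require them. Atom indices are 1-based in all file I/O (the
GRO/PDB convention) and 0-based in memory.

Leaflets are assigned geometrically: the midplane is the mean z of all
lipid atoms in the first analysis frame, and a lipid joins the upper or
lower leaflet according to the mean z of its head atoms. This is
invariant to global z-translations. Lipids without head atoms stay
unassigned with a warning, and a structure whose lipids all land on one
side is flagged as probably not a bilayer.

## Density profiles and thickness

`z_profile()` slices the box into slabs of width `bin_width` (default
0.05 nm) and accumulates either atom counts or summed partial charges
per slab volume, averaged over frames. Two numerical choices matter:

- **Midplane centering** (default on): each frame's coordinates are
  re-centered on that frame's bilayer midplane before binning. Over long
  windows the bilayer drifts along z; in box-fixed coordinates this
  drift convolves the profile and flattens the headgroup peaks, so
  centering is required for a sharp peak-to-peak thickness. A box-fixed
  mode (`center = FALSE`) remains available for absolute-coordinate
  constructions.
- **The bin grid lives on the mean box** over the window. Under a
  semi-isotropic barostat the box breathes; re-gridding per frame would
  make bins incommensurable across frames, so per-frame data are mapped
  into the mean-box grid by midplane centering only. A `bin_width` that
  does not divide the box height loses the remainder, with a warning.

`bilayer_thickness()` takes the headgroup number-density profile,
smooths it with a centered moving average (default 5 bins), and reports
the distance between the maximum below and the maximum above the
midplane. Peaks are bin-resolved argmaxes — no sub-bin interpolation —
so the resolution is one bin (0.05 nm), chosen to support values
reported to 0.01-nm precision without noise blow-up at typical
sampling. Two guards refuse non-lamellar structures with a "no bilayer
peaks" error: each peak must exceed twice the profile mean (heads
scattered through the box fail this), and the two maxima must be farther
apart than the smoothing kernel (a single layer straddling the midplane
fails that). The uncertainty is a block estimate: the window is split
into 5 contiguous blocks, the thickness recomputed per block, and the
block spread propagated.

## Electrostatic potential

For the laterally averaged 1-D Poisson equation, the potential is the
double cumulative trapezoidal integral of the charge density over bin
centers,

$$V(z) = -\frac{1}{\varepsilon_0}\int_0^z dz' \int_0^{z'} \rho(z'')\,dz'',$$

anchored at V = 0 at the profile origin. Charge densities in e·nm⁻³ are
converted to SI (ε₀ = 8.8541878128e-12 F/m, e = 1.602176634e-19 C) so
the output is in volts. The implementation is validated against the
parallel-plate closed form |ΔV| = σd/ε₀ (two opposite uniform surface
charges, σ = 0.05 e/nm², centers 2 nm apart, 1.810 V) to better than 1%
at 0.01-nm bins, and against the analytic plateau of the generator's
dipole layers.

The single number "potential difference across the bilayer" is not
uniquely defined; `potential_difference()` offers two conventions and
labels every report with the one used. `center_vs_bulk` (default)
compares the midplane potential with the mean over the outer 1 nm of
each side; `max_minus_min` takes the profile range. For symmetric
charge distributions the two agree; both are reported as magnitudes.

## Order parameters

`scd_profile()` computes, for every interior chain carbon n, the
deuterium order parameter S_CD = ½⟨3cos²θ − 1⟩ with θ the angle between
z and the minimum-image vector from carbon n−1 to n+1 — the standard
united-atom estimator that avoids reconstructing C–H vectors. Terminal
carbons are omitted rather than extrapolated. S is reported exactly as
defined (1 aligned, 0 isotropic, −0.5 in-plane); no sign flip or
absolute value is applied, since plotting conventions vary and a caller
comparing against −S_CD curves can negate. Averaging is over lipids
within each frame first, then block statistics over the per-frame means:
lipids within a frame are mutually correlated, and blocks absorb time
correlation.

## Packing and diffusion

Packing density is `n_leaflet / ⟨lx·ly⟩`, the reciprocal of the area per
lipid; the identity `packing x APL = 1` is exact by construction and
tested to 1e-12.

Lateral diffusion uses the 2-D Einstein relation. Lipid positions are
centers of mass (species-map masses, unit mass if absent) with
intra-lipid offsets unwrapped around a reference atom, so molecules
straddling the box edge get correct centers. Tracks are unwrapped by
accumulating minimum-image frame-to-frame displacements, which requires
frame spacing fine enough that no lipid moves half a box edge between
frames (violations are an error, not silent wrap-around). Per-leaflet
center-of-mass drift is removed per frame by default — box drift
otherwise inflates D; with N lipids per leaflet the removal biases the
MSD by the usual factor (1 − 1/N), below 2% for the systems analysed
here. The MSD averages over all sliding origins, and D is the
least-squares slope over a lag window of 10–50% of the maximum lag
(default: half the window) divided by 4, avoiding the short-lag regime
and the noisy long-lag tail. A negative fitted slope is reported
as-is with a warning rather than clamped, so a pathological input stays
visible. The estimator is verified to equal a brute-force double loop
over origins and lags exactly, and to recover generator diffusion
coefficients of 0.05, 0.1 and 0.17 x 10⁻⁷ cm²/s within 10% at 100
lipids x 1000 frames.

## Chain distances and RDFs

Intramolecular pair distances use the minimum image even within a
molecule (wrapped coordinates can split a lipid across the box) and
average per lipid per frame, with block uncertainties. Selectors resolve
through the species map — label strings such as `"N1"` or
role/carbon pairs — and must match exactly one atom per lipid;
ambiguity is an error naming the lipid and selector, because a silent
first-match would corrupt distance tables.

`rdf()` builds intermolecular pair histograms (same-lipid pairs
excluded by definition) under the minimum image, normalized by the
exact shell measure — spherical shells in `3d` mode, annuli in
`lateral` mode — and by the ideal-gas expectation for the same valid
pair set, so g → 1 for homogeneous systems even with exclusions. In
lateral mode only same-leaflet pairs are counted: in-plane packing
correlations are a per-leaflet property, and cross-leaflet pairs sit at
arbitrary small xy separations. The default bin width is 0.002 nm,
fine enough for distance tables reported to 0.01 nm.

The "average intermolecular chain distance from the RDF" is read as the
position of the first local maximum of the smoothed g(r) above 1 — the
nearest-neighbor shell. A plateau of tied bins resolves to its lowest
bin, so the tie-break is deterministic. A weighted first-shell mean
(`first_shell_mean_distance()`) is provided as the alternative reading;
neither is asserted to be the unique convention in the literature.
Structureless (monotone) RDFs are an error, not a number.

## The synthetic generator

`generate_bilayer()` exists so that every estimator can be validated by
parameter recovery: each lipid is a rigid body — one head bead at
z = ±d/2 and two bead tails built so the carbon-(n−1) → carbon-(n+1)
vector at carbon n has exactly the prescribed tilt θ(n) — placed on a
jittered square lattice per leaflet, moving laterally as a 2-D Gaussian
walk of variance 2·D·dt per coordinate, bobbing vertically with
per-frame N(0, σ) excursions, and carrying a dipole charge layer (−q at
the head, +q/2 on each first carbon, arm = the 0.2 nm head offset).
Because no force field acts, thickness (= d), packing (= n/lx·ly),
S_CD(k) (= ½(3cos²θ(k) − 1)), D, the dipole plateau ΔV
(= packing·q·arm/ε₀), and all constructed pair distances are known
exactly; true unwrapped tracks are stored alongside.

Defaults were fixed once to emulate a realistic ionizable-lipid bilayer
study: 75 lipids per leaflet in a 6.1 x 6.1 x 24.1 nm box, 6.3 nm head
separation, 12 carbons per tail with tilt rising linearly 10°→50° (so
the order parameter decays along the chain, as observed for lipids whose
headgroup region is motion-restricted), frames every 50 ps, lateral
D = 0.1e-7 cm²/s (mid-range for ionizable lipids with aromatic esters),
jitter σ = 0.1 nm, and q = 0.07 e, which puts ΔV near 0.5 V — inside
the 0.3–0.9 V range typical of such bilayers.

What the generator does **not** emulate — and hence what passing
recovery tests cannot show about real data: no internal chain dynamics
(S_CD uncertainties on synthetics are near zero), no area fluctuations
or undulations (the packing uncertainty is degenerate), no
force-field-driven correlations between observables, no water structure
(solvent is zero-charge filler used only for invariance tests), and
Gaussian displacements with no sub-diffusive regime, so the 10–50% fit
window is not stress-tested against a ballistic/cage crossover. The
`nonlamellar_variant()` scatters lipid z-positions uniformly every frame
as a negative control for the thickness guards.

## Uncertainties

`block_error()` splits a correlated per-frame series into contiguous
blocks (default 5) and reports the population standard deviation of the
block means over √n_blocks. Replicate production runs, where available,
are treated as additional independent blocks rather than concatenated in
time, since concatenation would fake continuity across a restart.

## Problem sizes

The shipped tests and the acceptance script size their simulations for
laptop-scale runs: 150-lipid systems with 10–200 frames for structural
observables, 100 lipids x 1000 frames for diffusion recovery, 1e5
segments for the isotropic order-parameter null, and ≤ 20 atoms /
≤ 10 frames where brute-force oracles (27-image distances, all-pairs
RDF, double-loop MSD) must match exactly. These sizes make every
stochastic tolerance (10% on D, one bin on thickness, 0.02 on isotropic
S) comfortable at fixed seeds.

## Known limitations

- Orthorhombic boxes only; the membrane normal is fixed to z. Tilted or
  curved membranes and triclinic cells are out of scope.
- Frame sources are GRO (optionally multi-frame) and PDB; compressed
  binary trajectory formats are not read.
- No finite-size hydrodynamic corrections to D, no anomalous-diffusion
  exponents, no electron-density or dipole-decomposed potentials.
- Leaflet assignment is geometric and static (first analysis frame);
  flip-flop events are not tracked.
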