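---
title: "poreflux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poreflux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

## What this package computes

Non-equilibrium molecular dynamics of a biological nanopore embedded in a
membrane and bathed in electrolyte produces, per applied voltage and per
replica, a trajectory of ion and water positions. `poreflux` post-processes
such trajectories into the transport observables nanopore work cares
about: the ionic current and its cation/anion decomposition, the
electroosmotic water flux (EOF), electrolyte conductivity from
current-voltage curves, time-averaged cylindrical density maps, and an
L2 map-distance statistic used to compare replicate ensembles (for
example, the same pore simulated under different force fields).

Everything runs in one unit system: angstrom, picosecond, elementary
charge, millivolt; currents in nA (1 e/ps = 160.2176634 nA), EOF in
molecules/ns, conductance in nS, conductivity in S/m.

## The charge-displacement current estimator

With frames saved every $\tau$ ps in a periodic box of height $L_z$, the
average current in a window $[t, t+\tau]$ is

$$I(t) = \frac{1}{\tau L_z} \sum_i q_i\,[z_i(t+\tau) - z_i(t)],$$

summed over the mobile charge carriers. This displacement form needs no
velocities and is exact for any sampling interval over which particles
move less than $L_z/2$. Practical points:

* **Wrapped coordinates.** MD engines usually emit coordinates folded
  into the box. The estimator applies the minimum-image correction to
  every *consecutive-frame* displacement and then sums the corrected
  pairs to span $\tau$, rather than correcting only the endpoint pair —
  robust to particles that cross the boundary repeatedly inside one
  window. A corrected displacement exactly equal to $L_z/2$ is refused
  as ambiguous (save frames more densely).
* **Which charges enter the sum.** By default only cations and anions
  (the mobile carriers); charged "other" particles (protein, lipids —
  typically restrained in these simulations) can be included with a
  flag. The per-window identity $I_{all} = I_{cation} + I_{anion}$ then
  holds to round-off by construction and is asserted in the tests.
* **EOF.** The same windowed estimator applied to water-oxygen particles
  with unit weight: molecules are counted, not charge-weighted. Positive
  flux means net water motion toward $+z$; the cis/trans orientation is
  a reporting convention, recorded in report headers, not hard-coded.

## Error model

Windowed currents are strongly autocorrelated, so the naive standard
error of the mean underestimates. Two estimators are provided and
composed by the pipeline:

* **Block averaging** (`block_error`): after discarding the
  equilibration stretch, the trace is cut into blocks (default 10 ns);
  the error is the sample (n−1) standard deviation of complete-block
  means over $\sqrt{n_{blocks}}$; an incomplete trailing block is
  dropped from the error (the mean uses all retained windows).
* **Replica aggregation** (`replica_aggregate`): the final estimate over
  independent replicas is the mean of replica means, with error
  $\mathrm{sd}(\text{replica means})/\sqrt{n}$.

Sample (n−1) standard deviations are used throughout; with 3–4 blocks or
~10 replicas the distinction matters and the unbiased choice is the
defensible one.

Selectivity is reported primarily as the current *difference*
$I_+ - I_-$ with quadrature errors; the ratio $|I_+|/|I_-|$ is also
computed but flagged unreliable when either current is statistically
indistinguishable from zero (below).

## Conductivity

A uniform field $E_z = \Delta V / L_z$ applied along a triperiodic
electrolyte box is equivalent to a voltage drop $\Delta V$. Per voltage
the mean current is measured as above; the conductance $G$ is the
weighted least-squares slope of $I$ vs $\Delta V$, and

$$\sigma = \frac{G\,L_z}{L_x L_y}.$$

Design choices:

* The fit is **through the origin by default** (bulk electrolyte boxes
  are symmetric, so $I(0)=0$ physically); a free-intercept fit is one
  flag away and both are exercised in tests.
* When per-point errors are available they act as $1/\sigma_i^2$ weights
  and the slope error is the **analytic WLS parameter error with errors
  taken as known** (not rescaled by residuals). Sweeps routinely fit two
  points through the origin; a residual-based error with one degree of
  freedom would be noise. Without point errors the residual-based
  estimate is used.
* Concentration is computed from ion counts and box volume (mol/L) and
  only labels the sweep output; no activity or Kohlrausch modelling is
  attempted — the package measures concentration dependence, it does not
  model it.

## Density maps and the map distance

The box is divided into cubic cells (default 1 Å); per-cell
time-averaged number density conserves mass exactly (density × cell
volume sums to the mean per-frame count). The Cartesian grid is then
angularly averaged about a z-aligned axis into an $(r,z)$ map: each bin
value is the volume-weighted mean of the Cartesian cells whose centres
fall in the annulus. Volume weighting (rather than count weighting) is
what makes an exactly uniform input exactly uniform in $(r,z)$,
independent of binning — the Jacobian test in the suite. Each bin also
records its contributing volume, so conservation through the transform
is exact whenever the radial range covers the whole lateral grid; the
default range is the inscribed circle, which excludes corner cells from
the map (documented, and the conservation test uses full coverage).
Empty annuli are `NA`, never zero. An optional lateral subcell
refinement (`subdivide`) reduces annulus discretisation error if finer
radial bins than Cartesian cells are requested.

Two maps on the same bins are compared over a region of interest by the
discrete L2 distance

$$d_{ij}^2 = \int_{ROI} [f_i - f_j]^2\,dr\,dz .$$

Conventions that needed a decision:

* **Mirrored area.** An $(r,z)$ map stands for its mirrored display
  ($\pm r$), and ROIs are stated as full widths (e.g. "40 Å × 70 Å
  centred at r = 0" means $r \in [0,20]$). The integral therefore counts
  both signed halves — area element $2\,dr\,dz$ — so that two maps
  differing by a constant $c$ over a 40 × 70 ROI are at distance
  $c\sqrt{2800}$. A `mirror = FALSE` switch restores the bare
  half-plane integral.
* **Missing bins** are excluded pairwise, with their area removed from
  the integral, rather than imputed as zero.
* **Units.** For cross-species comparability maps can be normalised to
  relative concentration (local/bulk, `normalize_map`); the distance is
  then dimensionally stable across species. Raw densities are the
  default output.

Group comparison is all-against-all: $n(n-1)/2$ intra-group pairs and
$n_a n_b$ inter-group pairs, each set reported as mean ± sd/√(count).
The distance satisfies the metric axioms on shared-geometry maps
(property-tested on random maps).

## Rescaling and the negligibility rule

Water models differ in shear viscosity (TIP3P 0.32 mPa·s, OPC
0.80 mPa·s, real water 0.90 mPa·s), and force-field/ion-model
combinations differ in bulk conductivity. To ask whether pore transport
differences are *merely* bulk-transport differences, flows are rescaled:

$$EOF_{x,r} = \frac{\mu_x}{\mu_{TIP3P}}\,EOF_x, \qquad
  I_{x,r} = \frac{\sigma_{ref}}{\sigma_x}\,I_x,$$

errors scaling by the same factor. The constants live in a user-editable
plain-text config with the standard viscosities pre-filled; measured
conductivities must share one concentration or the rescaling refuses.

Ratios of estimates carry first-order (delta-method) errors. An estimate
is **negligible** when $|\text{mean}| < 2\,\text{error}$ — statistically
indistinguishable from zero at the implied threshold — with a strict
inequality at the boundary. Any ratio whose numerator or denominator is
negligible is flagged unreliable: its propagated error is huge and the
number carries no information. (The prose this rule descends from can be
read in either direction; only this direction is consistent with "the
propagated error on the ratio is extremely large", which is why the
package implements it this way.)

## The synthetic generator: what a green test establishes

`generate()` realises exactly the statistical model the estimators
assume: independent charged point particles with per-species drift $v$
(or mobility $\mu$ with $v = \mu E_z$) and diffusion $D$, evolved by
Euler–Maruyama in a periodic box, with closed-form expectations

$$\langle I \rangle = \sum_s \frac{N_s q_s v_s}{L_z}, \qquad
  \langle \Phi_w \rangle = \frac{N_w v_w}{L_z}, \qquad
  \sigma = \sum_s n_s q_s \mu_s e .$$

It deliberately has **no** inter-particle forces, no hydrodynamics, no
membrane geometry and no thermostat physics: its job is known ground
truth at desk scale, not physics. Radial placement profiles (uniform,
annular Gaussian, wall-accumulated) emulate the radially structured
densities of nanopore electrolytes for the density-map tests; i.i.d.
per-frame sampling (`generate_density_fixture`) gives the map pipeline an
analytic target. Consequently a green suite establishes estimator
*correctness on the stated model* — unbiasedness, unit chains,
conservation identities, error calibration — and says nothing about
force-field physics, ion–ion correlations, or finite-size effects in
real MD.

Default scales mirror the real protocol: frames every 20 ps, boxes of
order 100–190 Å, blocks of 10 ns, 10 ns discard, currents of order
0.1–10 nA and EOF of order tens of molecules/ns. Test runs shorten
durations (1–20 ns equivalents, 50–400 particles) because the
closed-form oracles make small systems sufficient; the paper-scale runs
differ only in cost.

### Fixed-point coordinates

One invariant is stronger than floating-point arithmetic can deliver for
free: wrapped and unwrapped twins of the same trajectory must give
*bitwise identical* traces. Box wrapping (`%%`), minimum-image
correction and differencing round differently along the two paths, so
generic doubles agree only to ~1 ulp. The generator therefore emits
coordinates on a fixed-point lattice with quantum $2^{-20}$ Å (~1 µÅ,
five orders of magnitude below per-frame thermal displacements). All
coordinate arithmetic — wrap, minimum image, window sums — is then exact
integer arithmetic carried in doubles, and the invariant holds exactly.
Two visible consequences, both documented where they bite:

* the realised per-frame drift is $\mathrm{round}(v\,\Delta t\,Q)/Q$,
  within $1/(2Q\Delta t)$ of the requested $v$ (relative ~$10^{-6}$ at
  typical speeds); `ground_truth()` reports the lattice drift, so the
  $D=0$ estimator equals the closed form exactly;
* noise increments are quantised separately from drift, keeping the
  rounding unbiased by symmetry.

## Numerical choices and degenerate inputs

* $\tau$ must be a positive integer multiple of the frame interval;
  windows are consecutive and non-overlapping.
* Fewer than two complete blocks, a single replica, an empty species
  class, a missing water selection, mismatched map binning, all-equal
  voltages: each is an explicit error or warning with the remedy named,
  never a silent NA.
* Negligibility boundary: $|\text{mean}| = 2\,\text{error}$ is *not*
  negligible (strict inequality), frozen in a test.
* A zero denominator in a ratio yields `NA` flagged unreliable rather
  than `Inf`.
* DCD files are written NAMD-style (unit-cell records, float32
  coordinates) and read in either endianness; round trips are exact to
  float32 precision. XTC is refused with an explanatory error: no
  decoder for its compressed-coordinate codec exists in this toolchain,
  and the TSV table dialect covers text fixtures.

## Known limitations

* No topology parsing (PSF/PRMTOP): species and charges come from a
  plain table, by design.
* The angular average assigns Cartesian cells by centre; very fine
  radial bins against coarse cells need `subdivide` to keep annulus
  volumes honest.
* Map comparison requires identical bin geometry; there is no
  registration or regridding between differently set-up systems.
* The generator's conductivity closed form ignores ion–ion correlations
  because the generator has none; real electrolytes do, and their
  conductivity is not Nernst–Einstein.
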