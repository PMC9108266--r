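---
title: "helixmech: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixmech: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixmech)
```

# Scope

`helixmech` is the analysis layer for studies of double-stranded DNA
confined in cylindrical nanopores (single-walled carbon nanotubes, SWCNTs):
structural integrity observables (hydrogen bonds, non-native contacts,
RMSD/RMSF), hydration observables (shell counts, axial density, potential
of mean force), worm-like-chain elasticity estimators, nanotube
chirality-diameter geometry, and a synthetic-data layer that makes every
estimator testable against known ground truth. It does not run molecular
dynamics, assign force-field parameters, or compute reciprocal-space
electrostatics; it consumes coordinates and base-pair-step parameters that
an MD + helix-analysis toolchain produces.

# Nanotube geometry

The diameter of an SWCNT with chirality indices $(p, q)$ is
$d = 0.0783\sqrt{p^2 + q^2 + pq}$ nm, the standard rolled-graphene
relation with prefactor $a_{cc}\sqrt{3}/\pi$ ($a_{cc} = 1.421$ Å). For
armchair tubes this reduces to $0.0783\,p\sqrt{3}$. Published diameter
tables for armchair series mix rounding and truncation at two decimals
(e.g. $(26,26)$ computes to 3.526 nm but is conventionally printed 3.52),
so tests compare at an absolute tolerance of 0.01 nm rather than by string
equality. `chiralityDiameter()` returns full precision; rounding is the
caller's concern.

# The discrete worm-like chain and its estimators

## Model

A duplex of $n$ base pairs is reduced to $n$ origins (centres of mass) and
unit tangents. Three global coordinates summarize each frame:

* bending angle $\theta = \cos^{-1}(\vec t_1 \cdot \vec t_n)$,
* contour length $L = \sum_i \lVert o_{i+1} - o_i \rVert$, with time
  average $L_0$,
* cumulative twist $\phi = \sum_i \tau_i$ over the step twists, summed
  without wrapping (for a 16-bp duplex $\phi \approx 515^\circ$, so
  wrapped-angle variance would be meaningless).

In the weakly bending regime ($L_0 \ll l_p$, amply satisfied at 16 bp)
each coordinate is Gaussian with

$$\langle\theta^2\rangle = \frac{2L_0}{l_p}, \qquad
  \mathrm{Var}(L) = \frac{L_0 k_BT}{\gamma}, \qquad
  \mathrm{Var}(\phi) = \frac{k_BT\, L_0}{C},$$

for persistence length $l_p$ (nm), stretch modulus $\gamma$ (pN) and
torsional stiffness $C$ (pN nm$^2$). $k_BT$ is carried in pN nm
(4.1419 pN nm at 300 K), which keeps all three constants in their
conventional units.

## Slope estimators

Following standard practice, $l_p$ and $\gamma$ are extracted from
histogram slopes: $\ln P(\theta)$ against $(1-\cos\theta)$ gives
$l_p = -\mathrm{slope}\times L_0$, and $\ln P(L)$ against $(L/L_0-1)^2$
gives $\gamma = -2\,\mathrm{slope}\,k_BT/L_0$. $C$ is obtained directly
from the twist variance, $C = k_BT L_0/\sigma_\phi^2$, and the torsional
persistence length is $L_0/\sigma_\phi^2 = C/k_BT$; with the bulk-DNA
value $C = 473.84$ pN nm$^2$ this is $\approx 114$ nm at 300 K.

Histogramming uses 40 uniform bins over the sample range; bins with fewer
than 5 counts are dropped (sparse tails destabilize the log); the linear
fit is weighted least squares with weights equal to bin counts (Poisson
heteroscedasticity). At least 3 usable bins are required, otherwise the
fit errors rather than extrapolating. Below 1000 samples a warning is
issued. No $\theta$-range cut is applied: the small-angle mapping
$(1-\cos\theta) \approx \theta^2/2$ is already accurate to a few percent at
the bend amplitudes a 16-bp duplex reaches.

## The sin(theta) Jacobian

This is the one place where a naive reading of the fitting recipe is
provably biased, so the design deserves its own section. Bend angles
extracted from a 3D trajectory are *magnitudes*: the tangent deflects by
two independent transverse components, and $\theta \ge 0$ carries the
planar geometric factor, $P(\theta) \propto \theta
e^{-\theta^2/2\sigma_c^2}$ (Rayleigh) rather than a plain Gaussian. In the
small-angle limit $u = 1-\cos\theta$ is then exponentially distributed, and
a count-weighted fit of $\ln P$ on $u$ has expected slope $-1/2\sigma_c^2$
— exactly half the Gaussian value. The consequence is not subtle:
simulation at $5\times10^4$ samples recovers half the true persistence
length, deterministically (the package's test suite asserts this factor).

`fitPersistenceLength(..., jacobian = TRUE)` (the default) therefore
divides the histogram density by $\sin\theta$ before fitting, after which
the slope estimator is consistent; the residual
$\ln(\theta/\sin\theta) \approx \theta^2/6$ bias is a few percent at these
amplitudes. `jacobian = FALSE` remains available for series that are
genuinely signed one-dimensional Gaussian deflections (where the
correction would itself be wrong). The moment companion follows the same
convention: $2L_0/\langle\theta^2\rangle$ for magnitudes,
$L_0/\mathrm{Var}(\theta)$ for signed series. Companion moment estimators
are always reported; a slope/moment discrepancy above 20% triggers a
warning, as it indicates non-Gaussian sampling.

## Degenerate inputs

Zero-variance series signal *infinite stiffness* (estimate `Inf`) for the
stretch and torsion estimators rather than erroring — a perfectly rigid
synthetic chain is a legitimate limit — while a constant bending-angle
series errors, since a histogram slope is undefined there. Bootstrap
standard errors (`bootstrapSE()`, default 200 resamples, seeded) refuse to
report if the estimator fails on more than 20% of resamples.

# The synthetic chain generator

`sampleChainFrames()` draws, independently per step and per frame: step
length $\sim N(r_0,\ r_0 k_BT/\gamma)$, two transverse tilt components
$\sim N(0,\ r_0/l_p)$ applied as tangent rotations with parallel transport
of the transverse frame, and step twist $\sim N(\tau_0,\ k_BT r_0/C)$.
Independence of bend, stretch and twist mirrors the independent treatment
the estimators assume; twist variance is allocated uniformly across steps
(only the sum is constrained by the model); bends use two Gaussian tilt
components (small-angle discrete WLC) rather than spherical-cap sampling,
because that realizes exactly the Gaussian statistics the estimators
invert. Identical seeds give bit-identical trajectories.

Defaults are the reference study conditions throughout the package: 16 bp,
rise 0.34 nm, twist 34.3°/step (a conventional B-DNA helical repeat —
helix-analysis conventions differ, so it is exposed as a parameter), 300 K,
and the bulk-DNA elastic constants $l_p = 51.21$ nm, $\gamma = 1181.09$ pN,
$C = 473.84$ pN nm$^2$. Parameter-recovery tests run at $5\times10^4$
frames, where variance estimators carry sub-percent sampling error and the
slope estimators a few percent; the acceptance tolerances (10% slope, 5%
variance) leave honest headroom above that.

What the generator does *not* emulate: sequence-dependent stiffness,
bend–twist or stretch–twist coupling, anharmonicity at large bends,
end-fraying, and autocorrelation in time (frames are i.i.d.). Passing
recovery tests therefore demonstrates estimator correctness under the
model's own assumptions, not robustness to real-DNA anharmonicity.

# The idealized duplex and hydrogen-bond detection

`detectHBonds()` applies the two-part geometric criterion: donor–acceptor
heavy-atom distance $\le$ 3.5 Å and donor–hydrogen–acceptor angle $\ge$
120° (the angle at the hydrogen; collinear D–H···A is 180°). The
heavy-atom distance convention (rather than H···A) matches common practice
for the 3.5 Å cutoff, and the D–H···A angle is the IUPAC-style reading of
the angular criterion. Canonical accounting (`canonicalHbondCount()`)
is 3 bonds per G·C and 2 per A·T.

`buildIdealDuplex()` provides the geometry target: base pairs stacked at
3.4 Å rise and 36° twist, with each pair carrying donor/hydrogen/acceptor
triplets at ideal geometry (D···A 2.9 Å, collinear) on lateral tracks at
−4.5, 0, +4.5 Å, with alternating bond polarity, plus one backbone P marker
per residue at 8.9 Å radius. Track spacing and radii were chosen so that
the detector finds *exactly* the canonical bonds — no spurious intra-pair
or cross-step hits — which the test suite verifies for G-only, A·T-only,
mixed and reverse-complemented sequences. The model intentionally carries
only hydrogen-bond participants and P markers: sufficient for every
detector, contact and RMSD test in scope, without embedding a fiber-model
library. For the 16-bp reference sequence d[GTCGCGAATTCGCGAC] with one
base pair trimmed from each end, both the canonical count and the geometric
detector give 36 bonds over the central 14 bp (2.6 per bp).

One base pair is trimmed from each duplex end before analyses by default
(`trim = 1` throughout), the standard guard against end effects; the
per-bp divisor of 14 in hydration and energy reporting is the trimmed bp
count of the 16-bp reference duplex and is configurable.

# Hydration and the axial PMF

`shellWaterCount()` counts water oxygens within a cylindrical shell of
thickness 3 Å around the duplex. The duplex axis is the principal axis of
the base-pair origins anchored at their centroid; the duplex radius
$R_{dna}$ is the 95th percentile of DNA-atom radial distances from that
axis — a percentile beats the maximum because frayed ends would otherwise
inflate the shell — and waters count if $r \le R_{dna} + 3$ Å within the
axial span of the origins. Groove waters ($r < R_{dna}$) are included,
since excluding them would require a solvent-accessibility model well
beyond a shell count; the choice is documented here and the quantile is a
parameter.

`axialDensity()` bins water oxygens along the tube axis and converts
counts to g/cm$^3$ via $\rho = N m_w / (\pi r_{\mathrm{eff}}^2 \Delta z)$
with $m_w = 2.9915\times10^{-23}$ g and $r_{\mathrm{eff}}$ the tube radius
minus a 1.7 Å carbon van-der-Waals exclusion, so the density refers to the
water-accessible volume (the visible water–wall gap in confined systems).
Since bulk water is 1 g/cm$^3$, values double as relative densities, and
`pmfFromDensity()` applies $\mathrm{PMF} = -k_BT\ln\varrho$ in $k_BT$
units. Zero-density bins are *masked*, not set to $+\infty$; downstream
logic ignores masked bins. `barrierHeight()` reports the window maximum
minus the median PMF of bins outside the tube — a median, because the
reference region is narrow and Poisson-noisy — and is exactly invariant
under uniform density rescaling, so the absolute normalization (and hence
$r_{\mathrm{eff}}$) cancels out of barrier estimates. The
generation–analysis round trip (thin water to a profile with an
$e^{-0.5}$ mouth dip, recover a 0.5 $k_BT$ barrier) is tested at
$10^5$ samples with $\pm 0.1\ k_BT$ tolerance.

# Structure metrics and energetics

RMSD implements the bare formula
$\sqrt{N^{-1}\sum_i \lVert x_i - x_i^{ref}\rVert^2}$ with superposition
*off* by default — the formula as usually printed contains no fit, and the
flag makes the choice explicit; `superpose = TRUE` performs a Kabsch
least-squares fit via `bio3d::fit.xyz()`. RMSF is the fluctuation about
the time-averaged position per atom. Non-native contacts are
frame-minus-reference contact counts at a 3.0 Å cutoff and may be
negative. All pair searches are exact (no cell lists): in-scope systems
are small enough that the $O(N^2)$ scan is instantaneous, and the same
code path is what the brute-force oracle tests certify.

`pairEnergy()` is a generic truncated-cutoff (default 10 Å, no shift or
switch) Lennard-Jones 12-6 plus Coulomb sum with Lorentz–Berthelot
combination and $k = 332.0636$ kcal Å/(mol e$^2$); at $r = r_{min}$ the LJ
term is exactly $-\epsilon$, and a charge-neutral partner (a nanotube)
contributes zero electrostatics. Force-field parameter assignment is the
caller's input; the package neither types atoms nor computes bonded terms.

# File formats and units

Multi-model PDB reading goes through `bio3d::read.pdb()`; writing uses a
small deterministic fixed-width formatter (one MODEL/ENDMDL block per
frame) since the upstream writer covers single models only. Round trips
preserve coordinates at the format's 1e-3 Å precision. The base-pair-step
table is a deliberately strict, explicitly documented dialect (`#` comments, a
named header with at least `rise` (Å), `twist`, `roll` (deg), fixed
steps-per-frame blocks): a strict parser with an explicit schema beats
fuzzy auto-detection of the many helix-analysis output layouts.

Unit discipline: atomic-scale quantities (coordinates, cutoffs, shell
thicknesses) are Å, the native unit of PDB files and of every cutoff
convention; polymer-scale quantities (origins, contour and persistence
lengths) are nm; angles are degrees in files and at step level, radians
inside the estimators; energies kcal/mol; $k_BT$ pN nm. Conversions happen
at module boundaries (`framesFromAtoms()`, `readBpStepTable()`), never
implicitly.

Tangents from atomic coordinates use central differences
($t_i \propto o_{i+1} - o_{i-1}$, one-sided at the ends): the tangent is
defined only as "the local unit vector along the contour", and central
differences are the lowest-noise local estimate. Centre-of-mass grouping
defaults to unit masses (helix-analysis tools differ on mass weighting);
masses are an optional argument. Step twists cannot be derived from plain
coordinates and are zero in `framesFromAtoms()` output — torsion analyses
need a step-parameter table.

# Interfaces

The package's surface is its exported functions plus `scripts/acceptance.R`;
there is no shell executable, as the intended user drives analyses from R.
S4 classes with validity checks (`DuplexTrajectory`, `WCDuplex`,
`DensityProfile`, `PMFProfile`, `ElasticFit`) carry the central data;
accessors (`nFrames()`, `origins()`, `trimEnds()`, ...) are the supported
way in.

# Known limitations

* The elasticity estimators assume Gaussian, uncoupled fluctuations; on
  strongly anharmonic or coupled real-DNA ensembles the slope/moment
  discrepancy warning is the only built-in diagnostic.
* Frames are treated as independent; no autocorrelation correction is
  applied to bootstrap errors, which therefore understate uncertainty on
  correlated MD series (choose an analysis stride accordingly).
* The idealized duplex is a hydrogen-bond geometry target, not a
  structural model: RMSD/RMSF on it exercise bookkeeping, not DNA
  mechanics.
* `framesFromAtoms()` yields no twist; bend/stretch only.
* Binary trajectory formats (DCD/XTC) are out of scope; convert to
  multi-model PDB or step tables upstream.
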