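---
title: "Helicity-resolved backscattering: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helicity-resolved backscattering: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliscat)
```

`heliscat` models what a camera sees when a circularly polarized laser
beam is backscattered by a suspension of dielectric microspheres: two
co-registered images, one per circular analyzer orientation, holding the
helicity-flipped and helicity-preserved photon sub-populations. This
vignette explains the physics implemented in each layer, the tunable
parameters and their defaults, and the design decisions taken where the
problem is genuinely open.

## Single-sphere optics

For a homogeneous sphere the far-field Mueller matrix is block-diagonal,

$$
M(\theta)=\begin{pmatrix}
M_{11}&M_{12}&0&0\\ M_{12}&M_{11}&0&0\\
0&0&M_{33}&M_{34}\\ 0&0&-M_{34}&M_{33}
\end{pmatrix},
$$

with elements built from the complex scattering amplitudes
$S_1(\theta), S_2(\theta)$ of the Lorenz–Mie series:
$M_{11}=\tfrac12(|S_1|^2+|S_2|^2)$, $M_{12}=\tfrac12(|S_2|^2-|S_1|^2)$,
$M_{33}=\mathrm{Re}(S_2S_1^*)$, $M_{34}=\mathrm{Im}(S_2S_1^*)$.
`solve_mie()` evaluates the series with the logarithmic-derivative
downward recurrence and the Wiscombe truncation
$N = x + 4x^{1/3} + 2$ (community standard for the size parameters
$x \approx 1\text{–}10$ relevant here), returning the four elements on a
uniform angular grid (default step 0.1°, because the backward lobes of
the 1.04 µm reference spheres are narrow) together with the unpolarized
scattering efficiency $Q$ and asymmetry parameter
$g = \langle\cos\theta\rangle$. Only real refractive indices are
accepted: the intended targets are non-absorbing polystyrene/water
phantoms, and rejecting complex indices loudly is safer than silently
ignoring absorption.

For circular incidence the signed degree of circular polarization
reduces to $M_{33}(\theta)/M_{11}(\theta)$: positive where the
handedness is preserved, negative where it flips. For all three
reference diameters (0.20, 0.58, 1.04 µm at 635 nm) flipping is confined
to backward angles; `flip_onset_angle()` locates the boundary of the
contiguous negative lobe containing 180° by a grid scan refined with
bisection on the exact amplitudes (0.01° tolerance). For the 1.04 µm
configuration the onset is 131.1°.

The handedness convention is $V = I_{RCP} - I_{LCP}$ from the
receiver's point of view, so the incident left-circular beam has
$V=-I$. Every flip/preserve decision in the package uses only *sign
agreement* between two $V$ values, which is convention-invariant, so
the choice is global and cosmetic.

## Photon transport

`run_simulation()` drives a compiled Stokes-vector Monte Carlo:

* **Geometry.** A box of depth 2.2 cm and lateral width 2.2 cm (the
  cuvette), entered through the $z=0$ face. The entry face is treated as
  refractive-index matched — the experiment this emulates deliberately
  rejects specular reflections, and a window-free geometry is the
  cleaner model — so there is no Fresnel step. Photons reaching the side
  or bottom walls are terminated and tallied.
* **Beam.** Entry positions are drawn from the 2-D Gaussian beam profile
  (FWHM 3 mm); initial direction is the inward normal; the initial
  Stokes state is pure left-circular.
* **Free paths** are exponential with mean $1/\mu_s$.
* **Scattering angles** are drawn from the polarization-dependent
  single-scattering probability
  $p(\theta,\phi)\propto M_{11}I + M_{12}(Q\cos2\phi + U\sin2\phi)$
  by rejection against the envelope $M_{11}(I+\sqrt{Q^2+U^2})$, with
  $\theta$ proposed by inverse-CDF sampling of the tabulated
  $M_{11}\sin\theta$ distribution. Because $|M_{12}|\le M_{11}$ the
  acceptance probability is always valid. An unpolarized-sampling mode
  with intensity-weight correction exists purely for cross-validation.
* **Polarization bookkeeping.** The Stokes vector is carried in a local
  orthonormal frame (direction plus parallel/perpendicular reference
  vectors). Each event rotates the frame about the propagation direction
  by the azimuth (a $2\phi$ rotation of $Q,U$), applies $M(\theta)$, and
  renormalizes intensity — algebraically identical to classical
  meridian-plane tracking, with the frame re-orthonormalized every event
  to suppress drift.
* **Detection.** A photon re-exiting the entry face deposits
  $(I+V)/2$ into the flipped image and $(I-V)/2$ into the preserved
  image at its exit pixel (400 × 400 grid, 53 µm pitch, so the field is
  ~21 mm and the 15-pixel averaging disk is ~0.8 mm). All exit angles
  are accepted by default; an acceptance-cone option
  (`acceptance_cone_deg`) emulates a finite collection aperture — in our
  sensitivity checks it changes profiles and statistics by only a few
  percent, so the simpler accept-all default stands. Exits outside the
  grid go to an overflow tally.
* **Termination.** There is no absorption and no Russian roulette; a
  hard event cap (default 10,000) bounds the unbounded path-length tail
  of non-absorbing media, with capped photons tallied and a warning if
  they exceed 1% of the launched weight (at the default settings the
  truncated fraction is below 0.1%).
* **Randomness.** Each photon derives an independent `splitmix64`
  substream from (seed, photon index), so runs are bit-identical for a
  given seed regardless of execution order. Launched weight is conserved
  exactly: detected + overflow + side/bottom + truncated = launched.

The engine's correctness anchors are (i) exact agreement of the
single-scatter limit with the Mie signed-DOCP curve as a function of
exit angle, (ii) exact energy conservation, and (iii) the relaxation of
every per-photon statistic to its phase-function average deep in the
multiple-scattering regime.

## Per-photon statistics and the g-factor convention

Alongside the two images the engine accumulates, per pixel and per
helicity channel, intensity-weighted sums of three *per-photon*
quantities: the event count $N$, the photon's mean scattering angle, and
the photon's mean event cosine. The channel statistic at a pixel is
therefore an average over photons of each photon's own path average,
with each photon weighted by the intensity it deposits in that channel.
This is how an image-forming detector mixes sub-populations, and it is
the reading under which the photon-path anisotropy
(`mean_angle_profile()$g`, the weighted mean of per-photon mean
cosines) has the correct fully-depolarized limit: far from the beam the
channel mix samples the unpolarized phase function and g relaxes to the
Mie asymmetry parameter (0.92 for the reference spheres), which our
simulations reproduce. The cosine of the mean angle is also reported
(`g_of_mean_angle`), but note the two conventions differ for any
non-degenerate angle distribution (for the reference phase function
$\cos\langle\theta\rangle = 0.95$ while $\langle\cos\theta\rangle =
0.92$); the mean-of-cosines is the one consistent with the
pathway-mixture arithmetic below. A second bookkeeping
(`weighting = "class"`) assigns each photon wholly to the channel
matching the sign of its exit $V$, treating "flipped photons" as a
discrete sub-population; both weightings give similar in-region
g-values.

`pathway_g_mixture()` implements the illustrative decomposition of a
channel's g-factor into pathway types: each component contributes the
event-weighted mean of its per-event cosines (near-forward events at
`g_forward` each, backward events at $\cos$ of the backward angle), and
components combine by population fraction. The canonical example — 90%
of photons with 19 near-forward events (0.92 each) plus one 180° flip,
10% singly backscattered — evaluates to 0.64, close to the ~0.7 the
in-region flipped channel shows in simulation.

## Radial profiles and the convergence distance

`radial_profile()` bins pixels into 1-pixel annuli by rounded
pixel-center distance; all pixels within the central 15-pixel disk are
averaged together and reported as a constant plateau (~0.8 mm at 53 µm
pitch), suppressing the shot noise of the innermost annuli. The binning
is deliberately the simplest reproducible rule and is tested against a
brute-force per-pixel oracle for exact equality.

The **convergence distance** is the radius beyond which the flipped and
preserved profiles stay indistinguishable — the signature of complete
circular depolarization. "Indistinguishable" needs a definition, and
the choice matters more than it seems. The default
(`mode = "peak"`) requires the absolute difference to stay below 1% of
the summed-profile peak (after a 5-annulus moving average to damp shot
noise, and only over annuli fully inside the detector field): this is
the level at which two curves on a common peak-normalized linear plot
genuinely cannot be told apart. A relative criterion
($|f-p|/(f+p) < 5\%$, `mode = "relative"`) is also provided, but it is
far more demanding in the dim outer tail: a faithful transport keeps a
20–30% *relative* helicity imbalance alive at radii where both curves
are at a few percent of peak, so under the relative rule profiles never
formally converge inside the field even though they overlap on any
plot. With the peak criterion the 1.04 µm reference suspensions
converge at ≈9.4 mm for $\mu_s = 50\,\mathrm{cm}^{-1}$ and ≈4.4 mm for
$200\,\mathrm{cm}^{-1}$, with the expected ordering: higher turbidity
means more events per millimetre of radial excursion, hence faster
helicity randomization in space.

Mechanistically, helicity decays per scattering event by the
phase-function average $\langle M_{33}/M_{11}\rangle \approx 0.986$ for
the reference spheres — a 1/e constant of ~70 events — which is why
photons tallied by the depolarization diagnostic (default threshold 400
events, several decay constants) split evenly between channels to
within Monte Carlo error.

## SHRM

`compute_triple()` condenses one channel's profile into
$\{I_{in}, I_{out}, R_{out}\}$: the profile sum from 0 to 3 mm, the
distance from 3 mm to where the profile "reaches zero", and the sum over
that outer region. Sums are over annulus means (a pixel-count-weighted
variant is available via `pixel_weighted = TRUE`). "Reaches zero" is
operationalized as a sustained drop to `zero_frac` of the profile peak:
0.5% by default, suitable for well-converged simulation output; for
noisy profiles (measured images, or reduced photon counts) the crossing
should sit above the noise floor — we use 2% in the trend analyses, and
an absolute `zero_level` (e.g. background mean + 2 SD) is accepted for
measured data. $R_{out}$ is truncated at the field edge with a flag if
the threshold is never reached. The inner bound is fixed at 3 mm — twice
the illuminated-region radius of the 3 mm beam — and kept conceptually
separate from the IR edge marker (1.5 mm) used for the in-region
statistics.

The composite metric

$$\mathrm{SHRM} = \left\{\frac{I_{in}}{I_{out}}R_{out}\right\}_{flipped}
\times \left\{\frac{I_{in}}{I_{out}}R_{out}\right\}_{preserved}$$

is invariant to uniform rescaling of both images (camera gain) and, in
our simulations, monotone in both medium parameters: it *decreases*
with sphere diameter (the decay of $I_{in}/I_{out}$ outweighs the
growth of $R_{out}$) and *increases* with turbidity. `normalize_set()`
scales a sample collection by a designated reference (by convention the
smallest spheres at the highest turbidity), `build_response_surface()`
assembles the normalized values into a bilinear
(diameter, $\mu_s$) surface — bilinear because the diameter dependence
is close to linear and no model form is warranted — and
`invert_surface()` maps a measured SHRM back to candidate
(diameter, $\mu_s$) loci, flagging the ambiguity that appears at low
turbidity and clearing it when $\mu_s$ can be restricted (most
mammalian tissues have $\mu_s > 100\,\mathrm{cm}^{-1}$).

## The synthetic-image generator

`generate_synthetic_pair()` builds radially symmetric analytic image
pairs — a flat central plateau with an exponential tail, independently
controllable per channel, plus an optional noise floor and
Poisson-like shot noise. It emulates the *geometry* of backscattered
helicity images (plateau ≈ illuminated region, tail ≈ diffuse halo)
well enough to give every analysis and metric operation a closed-form
oracle: $I_{in}$, $R_{out}$, the convergence distance and the SHRM of a
generated pair are all known analytically. It does **not** emulate the
physics — no event statistics, no helicity cross-talk, no
radius-dependent depolarization — so tests that pass on synthetic pairs
validate the *operators*, while claims about the physics rest on the
Monte Carlo and its Mie anchors.

## Problem sizes

The bundled test suite runs the transport at 3 × 10⁵ photons
($\mu_s=50$), 1.2 × 10⁵ ($\mu_s=200$) and 6 × 10⁴ (trend sweeps), sizes
at which the seed-to-seed scatter of the convergence radii and
in-region g-values is a few percent — comfortably inside the 15% bands
used for the stochastic checks. The acceptance script uses 5 × 10⁵ and
2 × 10⁵ photons for the two reference turbidities. All runs are exactly
reproducible from their seeds.

## Known limitations

* The mean event count at the convergence radius is much larger here
  (~160 at $\mu_s=50$, ~480 at $200\,\mathrm{cm}^{-1}$) than the ~80
  reported for the measurement campaign this package models, and it is
  not turbidity-independent: in an open non-absorbing box the intensity
  at large radius is dominated by long diffuse paths. A mean of 80
  events at $r=4$ mm and $\mu_s=200\,\mathrm{cm}^{-1}$ would imply a
  nearly straight 4 mm path, so matching that figure would require some
  suppression of the deep diffuse tail (detection geometry or path
  truncation) that we chose not to guess at. The affected quantity is
  reported as computed.
* For the same reason the in-region ordering of per-channel event
  counts comes out with the flipped channel slightly *higher* (~38 vs
  ~31 at $\mu_s=50$): the flipped channel inherits intensity from the
  large depolarized population rather than being dominated by shallow
  single-flip paths.
* The 0.20 µm configuration is much more diffusive (g = 0.31); at the
  default event cap a percent-level fraction of photons is truncated
  and runs are several times slower. Trend checks at that diameter use
  the 2% zero threshold.
* Coated or absorbing spheres, polydisperse mixtures, Fresnel boundary
  physics, coherent backscattering and time-resolved detection are out
  of scope.
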