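# heliscat

Helicity-resolved backscattering polarimetry of turbid media in R.

When circularly polarized light is shone onto a scattering suspension, the
backscattered photons split into two sub-populations: **helicity-flipped**
photons whose circular handedness reversed (at least one large-angle
scattering event) and **helicity-preserved** photons that kept the incident
handedness (gentle multiple forward scattering along arc-like paths). The
intensities and spatial spreads of the two populations respond differently
to the average scatterer size and to the scattering coefficient
μ<sub>s</sub> of the medium, which makes co-registered flipped/preserved
images a practical probe of both quantities — relevant, for example, to
optical detection of the enlarged nuclei and increased cell density of
malignant tissue.

`heliscat` implements the full computational chain for this measurement on
polystyrene-microsphere phantoms:

* **Mie optics** — exact single-sphere Mueller matrix elements
  M11, M12, M33, M34 versus scattering angle, scattering efficiency *Q*
  and anisotropy *g* (Wiscombe-truncated Bohren–Huffman series), the
  signed degree of circular polarization
  CP = (V<sub>s</sub>/I<sub>s</sub>) · sign(V<sub>i</sub>), and the onset
  angle of the backward helicity-flipping lobe.
* **Stokes-vector Monte Carlo** — a compiled (Rcpp) photon-packet
  transport of a circularly polarized Gaussian beam (FWHM 3 mm) through a
  non-absorbing suspension in a 2.2 cm cuvette, with meridian-plane
  polarization bookkeeping, polarization-dependent rejection sampling of
  scattering angles, and per-pixel helicity-resolved detection on a
  400 × 400 grid (53 μm pitch).
* **Helicity analysis** — azimuthally averaged radial profiles (with the
  15-pixel central averaging disk), the convergence distance at which the
  two channels become indistinguishable (complete circular
  depolarization), per-channel mean event counts and mean scattering
  angles, and the illustrative pathway-mixture g-factor.
* **SHRM metrics** — the spatial helicity response metric

  SHRM = {I<sub>in</sub>/I<sub>out</sub> × R<sub>out</sub>}<sub>flipped</sub> × {I<sub>in</sub>/I<sub>out</sub> × R<sub>out</sub>}<sub>preserved</sub>

  computed from the radial profiles (I<sub>in</sub>: profile sum to 3 mm;
  R<sub>out</sub>: distance from 3 mm to where the profile reaches the
  zero threshold; I<sub>out</sub>: sum over that region), plus
  normalization, (diameter, μ<sub>s</sub>) response surfaces with bilinear
  interpolation, and iso-SHRM surface inversion with ambiguity flagging.

## Worked example

```r
library(heliscat)

# reference spheres: 1.04 um polystyrene in water at 635 nm
optics <- optical_config(wavelength_nm = 635, diameter_um = 1.04,
                         n_medium = 1.33, n_sphere = 1.59)
sol <- solve_mie(optics)
sol
#> <mie_solution> d=1.04 um, lambda=635 nm | X=6.843 M=1.195 | Q=2.7135 g=0.9190 (17 terms, 1801 angles)
flip_onset_angle(sol)$onset_deg
#> [1] 131.1406

# transport 10^5 photons through a mu_s = 50 cm^-1 suspension
cfg <- simulation_config(medium_spec(mu_s_cm = 50, optics),
                         n_photons = 1e5, seed = 42)
run <- run_simulation(cfg)
pair <- run$pair
pf <- radial_profile(pair$flipped,  pair$beam_center, pair$pixel_pitch_um)
pp <- radial_profile(pair$preserved, pair$beam_center, pair$pixel_pitch_um)
convergence_distance(pf, pp)
#> [1] 9.646
compute_shrm(pair)
#> <shrm_result> SHRM=641.4 mm^2 | flipped: Iin/Iout=2.34 Rout=11.6 mm | preserved: Iin/Iout=2.07 Rout=11.4 mm
```

The Mie block says the spheres scatter 2.71 times their geometric
cross-section and are strongly forward-scattering (g = 0.92), with
helicity flipping confined to scattering angles above ≈131°. In the
simulation, the flipped and preserved images become indistinguishable
≈9.6 mm from the beam axis — the radius of complete circular
depolarization at this turbidity — and the SHRM condenses both images
into one number that rises with turbidity and falls with sphere size.

A command-line front end wraps the same functions:

```sh
exec/heliscat mie      --config inst/extdata/demo_config.toml
exec/heliscat simulate --config inst/extdata/demo_config.toml --seed 7 --out-dir out/
exec/heliscat analyze  --in-dir out/ --out-dir out/
exec/heliscat shrm     --in-dir out/
```

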