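# 1.04 um polystyrene spheres in water, 635 nm illumination
[optics]
wavelength_nm = 635
diameter_um = 1.04
n_medium = 1.33
n_sphere = 1.59

[medium]
mu_s_cm = 50        # scattering coefficient; mean free path = 0.2 mm
depth_cm = 2.2
lateral_cm = 2.2

[beam]
fwhm_mm = 3

[detector]
n_pixels = 400
pitch_um = 53

[run]
n_photons = 100000
seed = 1
max_events = 10000
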