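# Frozen reference values from an independent Mie computation built on
# library spherical Bessel functions (not the package's recurrences):
# polystyrene (n = 1.59) in water (n = 1.33) at 635 nm.
mie_reference <- list(
  d0.20 = list(x = 1.31600574, Q = 0.07752149256, g = 0.3133146365),
  d0.58 = list(x = 3.81641665, Q = 1.035280833, g = 0.8497674015),
  d1.04 = list(x = 6.84322986, Q = 2.713520869, g = 0.9189532801)
)

# Mueller elements from the same independent implementation at selected
# angles (deg): 0, 30, 90, 120, 150, 180.
mueller_reference <- list(
  angles = c(0, 30, 90, 120, 150, 180),
  d0.20 = list(
    m11 = c(0.0969920716, 0.0776740315, 0.0225690999, 0.0178688536,
            0.0181631477, 0.0185030484),
    m12 = c(0, -0.0103315344, -0.0224863019, -0.0115557032,
            -0.00287783, 0),
    m33 = c(0.0969920716, 0.0769838576, 0.0019295992, -0.0136292581,
            -0.0179336948, -0.0185030484),
    m34 = c(0, -1.5450288197e-05, -8.4541129487e-05, -7.0561358810e-05,
            -2.4907295662e-05, 0)),
  d1.04 = list(
    m11 = c(1488.5261282, 30.256592336, 0.68545477449, 0.57235137069,
            1.4031816717, 0.050573742449),
    m12 = c(0, 4.7325377907, 0.2798144292, -0.2756904346,
            -1.3148983324, 0),
    m33 = c(1488.5261282, 29.689685091, 0.60145580990, 0.49852479487,
            -0.46621749683, -0.050573742449),
    m34 = c(0, 3.4039778269, -0.17263557521, 0.055262145202,
            0.15034102907, 0))
)

paper_optics <- function(diameter_um = 1.04) {
  optical_config(635, diameter_um, 1.33, 1.59)
}
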