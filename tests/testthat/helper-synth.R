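# Shared study-condition constants for recovery tests: the measured
# interfacial-tension scale (0.22 mN/m), a tissue-medium density difference
# of 40 kg/m^3, and an apex radius chosen so the reference drop sits at
# Bond number ~ 1.
GAMMA_REF <- 0.22e-3     # N/m
DRHO_REF <- 40           # kg/m^3
G_STD <- 9.80665         # m/s^2
R0_REF <- 7.5e-4         # m

# density difference giving an exact target Bond number at (GAMMA_REF, R0_REF)
drho_for_bond <- function(Bo, gamma = GAMMA_REF, R0 = R0_REF, g = G_STD) {
  Bo * gamma / (g * R0^2)
}

# synthetic blurred disk image, the analytic oracle for extraction tests
disk_image <- function(r = 50, n = 160, blur = 2, pixel_scale = 1e-6) {
  gx <- rep(seq_len(n) - 0.5, times = n)
  gz <- rep(seq_len(n) - 0.5, each = n)
  m <- matrix(as.numeric((gx - n / 2)^2 + (gz - n / 2)^2 <= r^2), n, n)
  if (blur > 0) m <- EBImage::gblur(m, blur)
  image_stack(m, pixel_scale)
}
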