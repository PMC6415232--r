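# SI defining constants (2019 redefinition; exact values).
.const <- list(
  e_charge  = 1.602176634e-19,   # C
  eps0      = 8.8541878128e-12,  # F / m
  kB        = 1.380649e-23,      # J / K
  avogadro  = 6.02214076e23      # 1 / mol
)

# mol/L -> number density in nm^-3
.molar_to_nm3 <- function(conc_molar) {
  conc_molar * .const$avogadro * 1e-24
}
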