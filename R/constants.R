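# Internal unit system: Angstrom, kcal/mol, elementary charge, radian,
# picosecond, atomic mass unit.

# Coulomb constant in kcal * Angstrom / (mol * e^2)
K_COULOMB <- 332.06371

# Boltzmann constant in kcal/(mol K)
K_BOLTZ <- 0.0019872041

# Gas constant, identical numeric value in kcal/(mol K)
R_GAS <- K_BOLTZ

# Acceleration conversion: (kcal/mol/Angstrom)/amu -> Angstrom/ps^2
ACC_CONV <- 418.4

# Pressure conversion: kcal/(mol Angstrom^3) -> bar
PRESS_CONV <- 69476.95

# kcal -> J
KCAL_TO_J <- 4184

# Atomic masses (amu) for the elements this package models
ELEMENT_MASSES <- c(H = 1.008, C = 12.011)

# Pauling electronegativities, used only for the CMD sign-rule anchor
PAULING_EN <- c(
  H = 2.20, Li = 0.98, Be = 1.57, B = 2.04, C = 2.55, N = 3.04, O = 3.44,
  F = 3.98, Na = 0.93, Mg = 1.31, Al = 1.61, Si = 1.90, P = 2.19, S = 2.58,
  Cl = 3.16, K = 0.82, Ca = 1.00
)
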