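#' Physical constants used in mobility and cross-section arithmetic
#'
#' CODATA values for the elementary charge, Boltzmann constant, atomic mass
#' unit, and the Loschmidt number density (ideal-gas number density at
#' 273.15 K and 760 torr). The Loschmidt density is the correct buffer-gas
#' density to pair with a *reduced* mobility in the Mason-Schamp relation,
#' because the multi-field regression already standardises the mobility to
#' 273.15 K / 760 torr.
#'
#' @format Named list with elements `e_C`, `kB_J_per_K`, `N0_per_m3`,
#'   `amu_kg`.
#' @export
physical_constants <- list(
  e_C        = 1.602176634e-19,
  kB_J_per_K = 1.380649e-23,
  N0_per_m3  = 2.686780111e25,
  amu_kg     = 1.66053906892e-27
)

# Monoisotopic atom masses (Da) and isotope patterns (IUPAC 2021 standard
# atomic weights tables). Each element maps to parallel vectors of isotope
# masses and fractional abundances, lightest first; the lightest isotope is
# also the most abundant for every element carried here.
.isotope_table <- list(
  H  = list(mass = c(1.0078250319, 2.0141017781),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.0033548351),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740044, 15.0001088989),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317565, 17.9991596129),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.9737619984, abundance = 1.0),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.9678670040,
                     35.9670807100),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = list(mass = 22.9897692820, abundance = 1.0),
  Cl = list(mass = c(34.9688526820, 36.9659026020),
            abundance = c(0.7576, 0.2424)),
  F  = list(mass = 18.9984031627, abundance = 1.0),
  K  = list(mass = c(38.9637064864, 39.9639982, 40.9618252579),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Br = list(mass = c(78.9183376, 80.9162897),
            abundance = c(0.5069, 0.4931)),
  I  = list(mass = 126.9044719, abundance = 1.0)
)

# Mean spacing between successive isotopomer aggregate peaks (Da); the
# 13C-12C difference, which dominates CHNOPS envelopes.
.isotopomer_spacing_da <- 1.00335483778

.mass_H_atom  <- 1.0078250319
.mass_Na_atom <- 22.9897692820
.mass_proton  <- 1.007276466879
.mass_electron <- 0.000548579909
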