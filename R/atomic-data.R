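# Pinned IUPAC 2013 atomic data. Bundled (rather than taken from a library)
# so that masses, ppm errors and isotope patterns never drift with an
# upstream update. Monoisotopic mass = mass of the most abundant isotope.

.isotope_table <- list(
  H  = list(mass = c(1.00782503207, 2.01410177785),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088982),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.97376163, abundance = 1.0),
  S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  F  = list(mass = 18.99840322, abundance = 1.0),
  Cl = list(mass = c(34.96885268, 36.96590259),
            abundance = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183371, 80.9162906),
            abundance = c(0.5069, 0.4931)),
  I  = list(mass = 126.904473, abundance = 1.0),
  Na = list(mass = 22.9897692809, abundance = 1.0),
  K  = list(mass = c(38.96370668, 39.96399848, 40.96182576),
            abundance = c(0.932581, 0.000117, 0.067302))
)

# most-abundant-isotope mass per element
.monoisotopic <- vapply(
  .isotope_table,
  function(el) el$mass[which.max(el$abundance)],
  numeric(1)
)

#' Physical constants used in mass arithmetic
#'
#' The proton mass (1.00727646 Da) is used for protonation/deprotonation
#' arithmetic, i.e. `[M+H]+` adds a proton, not a hydrogen atom. The electron
#' mass is provided for completeness.
#'
#' @format Named numeric vector with entries `proton`, `electron`, `h_atom`.
#' @export
mass_constants <- c(
  proton = 1.00727646688,
  electron = 0.00054857991,
  h_atom = 1.00782503207
)

# elements counted as halogens in RDBE arithmetic
.halogens <- c("F", "Cl", "Br", "I")
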