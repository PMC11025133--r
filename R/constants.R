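# Internal unit system: kJ/mol, nm, ps, amu, elementary charge (GROMACS-style).
# In these units 1 kJ/mol == 1 amu nm^2 ps^-2, so no mass/energy conversion
# factors appear in the equations of motion.

#' Physical constants and unit conversions
#'
#' Constants used throughout the package, exposed so that analysis scripts can
#' reproduce every conversion.  `kB` is the molar Boltzmann constant in
#' kJ mol^-1 K^-1; `f_coulomb` is the Coulomb prefactor
#' 1/(4 pi eps0) in kJ mol^-1 nm e^-2; `mpa_to_internal` converts a stress in
#' MPa to kJ mol^-1 nm^-3; `ms_to_nmps` converts a velocity in m/s to nm/ps.
#'
#' @return A named list of constants.
#' @export
#' @examples
#' cg_constants()$kB * 300  # thermal energy at 300 K, kJ/mol
cg_constants <- function() {
  list(
    kB              = 0.0083144621,
    f_coulomb       = 138.935458,
    mpa_to_internal = 0.602214076,
    ms_to_nmps      = 1e-3,
    amu_nm3_to_gcm3 = 1.66053907e-3,
    avogadro_nm3_M  = 0.602214076   # molecules per nm^3 at 1 mol/L
  )
}

.kB       <- 0.0083144621
.FCOUL    <- 138.935458
.MPA      <- 0.602214076
.GCM3     <- 1.66053907e-3
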