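#' Unit conversion constants
#'
#' All geometry is in nanometres, energies and frequencies in wavenumbers
#' (cm^-1), and time in femtoseconds, with hbar = 1. A quantity of E cm^-1
#' advances its phase by `E * cm1_to_radfs * t` radians after t fs.
#'
#' @format A list with elements:
#' \describe{
#'   \item{c_cm_per_fs}{speed of light, cm/fs}
#'   \item{cm1_to_radfs}{angular frequency (rad/fs) per cm^-1, i.e. 2*pi*c}
#'   \item{nm_per_cm}{nanometres per centimetre}
#' }
#' @examples
#' # the 1670 cm^-1 phonon has a ~20 fs period
#' 2 * pi / (1670 * exciton_units$cm1_to_radfs)
#' @export
exciton_units <- list(
  c_cm_per_fs   = 2.99792458e-5,
  cm1_to_radfs  = 2 * pi * 2.99792458e-5,
  nm_per_cm     = 1e7
)

#' Convert an energy in cm^-1 to an angular frequency in rad/fs
#' @param e energy or frequency, cm^-1
#' @return angular frequency, rad/fs
#' @export
cm1_to_radfs <- function(e) e * exciton_units$cm1_to_radfs

#' Convert a vacuum wavelength in nm to a transition energy in cm^-1
#' @param lambda_nm wavelength, nm
#' @return energy, cm^-1
#' @export
nm_to_cm1 <- function(lambda_nm) 1e7 / lambda_nm
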