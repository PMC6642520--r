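#' Physical constants and unit conversion
#'
#' Energy unit policy: orbital energies and descriptors are carried in
#' electron-volts (eV); total electronic energies in hartree (au).  All
#' conversions go through the single constant used here.
#'
#' @param x numeric vector of energies in hartree.
#' @return `hartree_to_ev()` returns energies in eV.
#' @examples
#' hartree_to_ev(-0.5)   # -13.6057 eV
#' @export
hartree_to_ev <- function(x) x * .ev_per_hartree

#' @rdname hartree_to_ev
#' @export
ev_to_hartree <- function(x) x / .ev_per_hartree

# 1 hartree in eV (CODATA, truncated to the precision carried throughout)
.ev_per_hartree <- 27.211386

# hc in eV * nm, for converting an electronic gap to a wavelength
.hc_ev_nm <- 1239.841984

# bohr radius in Angstrom (cube files are in bohr)
.bohr_angstrom <- 0.52917721
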