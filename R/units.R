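#' Unit conventions
#'
#' The simulator follows a mixed-unit scheme: protein species are tracked as
#' molecule counts in a fixed outer-segment volume of 1 pL, while the two
#' diffusible second messengers (cGMP and free Ca2+) are tracked in micromolar
#' concentration. Conversion between the two representations uses
#' `MOLEC_PER_UM`, the number of molecules corresponding to 1 uM in 1 pL:
#' N_A x 1e-12 L x 1e-6 mol/L = 6.02214e5 molecules per uM per pL.
#'
#' @name units
#' @keywords internal
NULL

#' Molecules per micromolar per picoliter
#'
#' Avogadro's number times 1e-12 L times 1e-6 mol/L.
#' @export
MOLEC_PER_UM <- 6.02214e5

#' Convert a micromolar concentration to a molecule count
#'
#' @param conc_um Concentration in uM (non-negative).
#' @param volume_pl Compartment volume in pL (default 1).
#' @return Molecule count (real-valued; not rounded).
#' @examples
#' umolar_to_molecules(63.4) # about 3.82e7, the dark arrestin monomer pool
#' @export
umolar_to_molecules <- function(conc_um, volume_pl = 1) {
  stopifnot(is.numeric(conc_um), is.numeric(volume_pl))
  if (any(conc_um < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (any(volume_pl <= 0)) stop("volume must be positive", call. = FALSE)
  conc_um * volume_pl * MOLEC_PER_UM
}

#' Convert a molecule count to a micromolar concentration
#'
#' @param n Molecule count (non-negative).
#' @param volume_pl Compartment volume in pL (default 1).
#' @return Concentration in uM.
#' @export
molecules_to_umolar <- function(n, volume_pl = 1) {
  stopifnot(is.numeric(n), is.numeric(volume_pl))
  if (any(n < 0)) stop("molecule count must be non-negative", call. = FALSE)
  if (any(volume_pl <= 0)) stop("volume must be positive", call. = FALSE)
  n / (volume_pl * MOLEC_PER_UM)
}
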