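#' Arrestin storage oligomers
#'
#' Visual arrestin self-associates into homodimers and homotetramers that act
#' as storage forms: two monomers bind reversibly to a dimer and two dimers to
#' a tetramer, both steps sharing the same forward (`kA4`) and reverse
#' (`kA5`) constants. The ratio `kA5/kA4`, converted to concentration at
#' 1 pL, equals the imposed 60 uM dissociation constant.
#'
#' @name arrestin_oligomerization
NULL

#' Oligomerization reaction set
#'
#' Forward rates are `kA4 * pool^2` (so the monomer pool changes by 2 per
#' dimerization event), reverse rates `kA5 * product`.
#'
#' @param kA4 Self-association constant (per molecule per s).
#' @param kA5 Self-dissociation constant (s^-1).
#' @return List of [reaction()] objects.
#' @export
oligomer_reactions <- function(kA4 = default_params()$kA4,
                               kA5 = default_params()$kA5) {
  stopifnot(kA4 >= 0, kA5 >= 0)
  list(
    mass_action("Arr_dimerize", kA4, c(Arr = 2), c(Arr_di = 1), k_name = "kA4"),
    mass_action("Arr_didissoc", kA5, c(Arr_di = 1), c(Arr = 2), k_name = "kA5"),
    mass_action("Arr_tetramerize", kA4, c(Arr_di = 2), c(Arr_tetra = 1),
                k_name = "kA4"),
    mass_action("Arr_tetradissoc", kA5, c(Arr_tetra = 1), c(Arr_di = 2),
                k_name = "kA5")
  )
}

#' Analytic dark equilibrium of the arrestin pools
#'
#' Solves the unique non-negative equilibrium of the two-step self-association
#' chain: `Arr_di = q Arr^2`, `Arr_tetra = q Arr_di^2` (with `q = kA4/kA5`)
#' under the closure `Arr + 2 Arr_di + 4 Arr_tetra = total`. The closure is
#' strictly increasing in the monomer count, so the root is bracketed and
#' found to near machine precision.
#'
#' @param total_molecules Total arrestin molecules (monomer equivalents).
#' @param kA4,kA5 Oligomerization constants.
#' @return Named vector `c(Arr, Arr_di, Arr_tetra)` of molecule counts.
#' @export
arr_equilibrium_pools <- function(total_molecules,
                                  kA4 = default_params()$kA4,
                                  kA5 = default_params()$kA5) {
  stopifnot(total_molecules >= 0, kA4 >= 0, kA5 > 0)
  if (total_molecules == 0 || kA4 == 0)
    return(c(Arr = total_molecules, Arr_di = 0, Arr_tetra = 0))
  q <- kA4 / kA5
  closure <- function(a) a + 2 * q * a^2 + 4 * q^3 * a^4 - total_molecules
  root <- stats::uniroot(closure, c(0, total_molecules), tol = 1e-14 * total_molecules)$root
  a <- root
  c(Arr = a, Arr_di = q * a^2, Arr_tetra = q^3 * a^4)
}

#' Optional Ca2+-dependent self-association rate
#'
#' A variant mechanism multiplies the forward oligomerization constant by an
#' exponential factor in the free-Ca2+ fraction of its dark value, normalized
#' so the dark-state factor is exactly 1:
#' `kA4 * exp(omega_Arr * (Ca_free/Ca_dark - 1))`. The exact exponent form in
#' the source description is ambiguous; this normalized form is the package's
#' resolution and the mechanism is OFF (`omega_Arr = 0`) by default, where it
#' returns `kA4` unchanged.
#'
#' @param kA4 Base self-association constant.
#' @param omega_Arr Dimensionless exponent (0 disables the mechanism).
#' @param Ca_free Free Ca2+ (uM).
#' @param Ca_dark Dark free Ca2+ (uM, positive).
#' @return Modified forward rate constant.
#' @export
ca_dependent_forward_rate <- function(kA4, omega_Arr, Ca_free, Ca_dark) {
  if (Ca_dark <= 0) stop("Ca_dark must be positive", call. = FALSE)
  kA4 * exp(omega_Arr * (Ca_free / Ca_dark - 1))
}
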