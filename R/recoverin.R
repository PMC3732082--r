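#' Calcium/recoverin feedback on rhodopsin kinase
#'
#' Two elementary reversible reactions replace the earlier quasi-steady-state
#' Hill form: (1) tense recoverin binds one free Ca2+ ion and relaxes
#' (`RecT + Ca2+ <-> RecR_Ca`), consuming free Ca2+ explicitly so that Rec
#' acts as a Ca2+ buffer; (2) relaxed recoverin sequesters the kinase
#' (`RecR_Ca + RK <-> RecR_Ca.RK`). Because Rec is counted in molecules while
#' Ca2+ is tracked in uM, the Ca2+ increment of reaction (1) carries the
#' molecule-to-micromolar conversion at 1 pL.
#'
#' @name recoverin_feedback
NULL

#' Recoverin reaction set
#'
#' @param params Parameter list from [default_params()].
#' @return List of [reaction()] objects.
#' @export
rec_reactions <- function(params = default_params()) {
  p <- params
  conv <- 1 / (MOLEC_PER_UM * p$volume_pl)
  list(
    # RecT + Ca -> RecR_Ca ; rate in molecules/s = kRec1 * RecT * [Ca]
    reaction("Rec_relax", p$kRec1, c("RecT", "Ca"),
             c(RecT = -1, RecR_Ca = 1, Ca = -conv), k_name = "kRec1"),
    reaction("Rec_tense", p$kRec2, "RecR_Ca",
             c(RecR_Ca = -1, RecT = 1, Ca = conv), k_name = "kRec2"),
    mass_action("RecRK_bind", p$kRec3, c(RecR_Ca = 1, RK = 1),
                c(RecRK = 1), k_name = "kRec3"),
    mass_action("RecRK_unbind", p$kRec4, c(RecRK = 1),
                c(RecR_Ca = 1, RK = 1), k_name = "kRec4")
  )
}

#' Dark free Ca2+ implied by the recoverin conformational equilibrium
#'
#' Rearranges the reaction-(1) equilibrium: `Ca = kRec2 * RecR_Ca /
#' (kRec1 * RecT)`. With the printed dark pools this lands at ~0.6 uM, the top
#' of the physiological dark range.
#'
#' @param recT,recRCa Dark molecule counts of the tense and relaxed pools.
#' @param kRec1 Forward constant (uM^-1 s^-1).
#' @param kRec2 Reverse constant (s^-1).
#' @return Free Ca2+ concentration in uM.
#' @export
implied_dark_calcium <- function(recT, recRCa,
                                 kRec1 = default_params()$kRec1,
                                 kRec2 = default_params()$kRec2) {
  if (any(recT <= 0)) stop("tense recoverin pool must be positive", call. = FALSE)
  kRec2 * recRCa / (kRec1 * recT)
}

#' Reduce the anonymous buffer capacity for explicit recoverin buffering
#'
#' Recoverin binds one Ca2+ per molecule in this model, so making it an
#' explicit buffer requires removing an equivalent amount of the anonymous
#' buffer pool `eT` to preserve total dark buffering capacity.
#'
#' @param eT_prev Previous total buffer concentration (uM).
#' @param rec_total_concentration Total recoverin concentration (uM).
#' @return Adjusted buffer concentration (uM).
#' @export
adjust_buffer_capacity <- function(eT_prev, rec_total_concentration) {
  if (eT_prev <= rec_total_concentration)
    stop("buffer capacity would be non-positive after the recoverin adjustment",
         call. = FALSE)
  eT_prev - rec_total_concentration
}
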