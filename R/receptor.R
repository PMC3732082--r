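#' Linear affinity schedules for rhodopsin kinase and arrestin
#'
#' The affinity of activated rhodopsin (R*) for its shutdown partners depends
#' on the number of phosphates `n` (0..6) attached to its C-terminus. RK
#' binding decreases linearly with `n` and is extinguished at five phosphates;
#' Arr binding increases linearly over the first four phosphates and plateaus
#' for five or six. Both schedules replace earlier exponential forms.
#'
#' @name affinity_schedules
NULL

check_phospho <- function(n) {
  if (any(n != floor(n)) || any(n < 0) || any(n > 6))
    stop("phosphorylation count must be an integer in 0..6", call. = FALSE)
}

#' RK binding rate as a function of phosphorylation state
#'
#' `kRK1(0) = kRK1_0`; for 1 <= n <= 5, `kRK1_0 - m_RK * n` clamped at zero;
#' `kRK1(6) = 0`. With the default slope `m_RK = kRK1_0 / 5` the rate reaches
#' zero at n = 5, one step before the maximum phosphorylation state.
#'
#' @param n Integer phosphorylation count (0..6, vectorized).
#' @param kRK1_0 Basal binding rate (s^-1 per molecule).
#' @param m_RK Slope (s^-1 per phosphate); default `kRK1_0 / 5`.
#' @return Binding rate in s^-1 per molecule of free RK.
#' @export
rk_binding_rate <- function(n, kRK1_0 = default_params()$kRK1_0,
                            m_RK = kRK1_0 / 5) {
  check_phospho(n)
  out <- pmax(kRK1_0 - m_RK * n, 0)
  out[n >= 6] <- 0
  out
}

#' Arr binding rate as a function of phosphorylation state
#'
#' Zero for unphosphorylated R*; `kArr + m_Arr * (n - 1)` for 1 <= n <= 4;
#' constant at the n = 4 value for n >= 5.
#'
#' @param n Integer phosphorylation count (0..6, vectorized).
#' @param kArr Binding rate to singly-phosphorylated R*.
#' @param m_Arr Increase per additional phosphate over the first four.
#' @return Binding rate in s^-1 per molecule of monomeric Arr.
#' @export
arr_binding_rate <- function(n, kArr = default_params()$kArr,
                             m_Arr = default_params()$m_Arr) {
  check_phospho(n)
  out <- kArr + m_Arr * (pmin(n, 4) - 1)
  out[n == 0] <- 0
  out
}

#' Receptor shutdown reactions
#'
#' Emits, for each phosphorylation state `n`: RK binding at
#' [rk_binding_rate()], the phosphoryl-transfer step within the R*.RK complex
#' (n -> n+1), RK release, Arr binding at [arr_binding_rate()], reversible Arr
#' release while R* is still active (`kA2`), and the irreversible quench that
#' produces deactivated rhodopsin (opsin) and frees monomeric Arr (`kA3`).
#' R* complexed with RK or Arr does not activate transducin.
#'
#' @param params Parameter list from [default_params()].
#' @return List of [reaction()] objects.
#' @export
receptor_reactions <- function(params = default_params()) {
  p <- params
  out <- list()
  add <- function(r) out[[length(out) + 1]] <<- r
  for (n in 0:5) {
    add(mass_action(sprintf("RK_bind_%d", n), rk_binding_rate(n, p$kRK1_0, p$m_RK),
                    c(stats::setNames(1, sprintf("Rst%d", n)), RK = 1),
                    stats::setNames(1, sprintf("RKpre%d", n)), k_name = "kRK1"))
    add(mass_action(sprintf("RK_unbind_%d", n), p$kRK2,
                    stats::setNames(1, sprintf("RKpre%d", n)),
                    c(stats::setNames(1, sprintf("Rst%d", n)), RK = 1),
                    k_name = "kRK2"))
    add(mass_action(sprintf("RK_phos_%d", n), p$kRK3,
                    stats::setNames(1, sprintf("RKpre%d", n)),
                    stats::setNames(1, sprintf("RKpost%d", n + 1)),
                    k_name = "kRK3"))
  }
  for (n in 1:6) {
    add(mass_action(sprintf("RK_release_%d", n), p$kRK4,
                    stats::setNames(1, sprintf("RKpost%d", n)),
                    c(stats::setNames(1, sprintf("Rst%d", n)), RK = 1),
                    k_name = "kRK4"))
    add(mass_action(sprintf("Arr_bind_%d", n), arr_binding_rate(n, p$kArr, p$m_Arr),
                    c(stats::setNames(1, sprintf("Rst%d", n)), Arr = 1),
                    stats::setNames(1, sprintf("ArrB%d", n)), k_name = "kA1"))
    add(mass_action(sprintf("Arr_unbind_%d", n), p$kA2,
                    stats::setNames(1, sprintf("ArrB%d", n)),
                    c(stats::setNames(1, sprintf("Rst%d", n)), Arr = 1),
                    k_name = "kA2"))
    add(mass_action(sprintf("Arr_quench_%d", n), p$kA3,
                    stats::setNames(1, sprintf("ArrB%d", n)),
                    c(Ops = 1, Arr = 1), k_name = "kA3"))
  }
  out
}
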