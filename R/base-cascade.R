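#' Backbone cascade assembly and the full rod model
#'
#' The backbone comprises: photoactivation of free and transducin-precoupled
#' rhodopsin; phosphorylation-indexed R*-Gt binding with exponentially
#' decaying affinity `kG1(n) = kG1_0 exp(-omega n)`; lumped GDP/GTP exchange
#' and Galpha release; two-step PDE effector activation; RGS-mediated and
#' spontaneous effector shutdown; Ca2+-inhibited cGMP synthesis (implicit
#' GCAP Hill form), hydrolysis by dark and activated effector; Ca2+ influx
#' through the CNG channels, exchanger extrusion and buffering; and the
#' normalized photocurrent observable.
#'
#' @name base_cascade
NULL

phospho_range <- 0:6

rod_species_names <- function() {
  c("R", "R_Gt",
    sprintf("Rst%d", phospho_range),
    sprintf("RGt%d", phospho_range),
    "Gt", "Ga_GTP", "Ga_GDP", "Gbg",
    "PDE", "PDE_Ga", "Ga_PDE_Ga", "RGS", "RGS_PDE_Ga", "RGS_Ga_PDE_Ga",
    "RK", sprintf("RKpre%d", 0:5), sprintf("RKpost%d", 1:6),
    "RecT", "RecR_Ca", "RecRK",
    "Arr", "Arr_di", "Arr_tetra", sprintf("ArrB%d", 1:6),
    "Ops", "cGMP", "Ca", "Ca_buff", "Bfree")
}

rod_conservation <- function() {
  w1 <- function(x) stats::setNames(rep(1, length(x)), x)
  list(
    rhodopsin_total = w1(c("R", "R_Gt", sprintf("Rst%d", 0:6),
                           sprintf("RGt%d", 0:6), sprintf("RKpre%d", 0:5),
                           sprintf("RKpost%d", 1:6), sprintf("ArrB%d", 1:6), "Ops")),
    G_total = c(w1(c("Gt", "R_Gt", sprintf("RGt%d", 0:6), "Ga_GTP", "Ga_GDP",
                     "PDE_Ga", "RGS_PDE_Ga")),
                Ga_PDE_Ga = 2, RGS_Ga_PDE_Ga = 2),
    PDE_total = w1(c("PDE", "PDE_Ga", "Ga_PDE_Ga", "RGS_PDE_Ga", "RGS_Ga_PDE_Ga")),
    RGS_total = w1(c("RGS", "RGS_PDE_Ga", "RGS_Ga_PDE_Ga")),
    Arr_total = c(Arr = 1, Arr_di = 2, Arr_tetra = 4,
                  w1(sprintf("ArrB%d", 1:6))),
    Rec_total = w1(c("RecT", "RecR_Ca", "RecRK")),
    RK_total = w1(c("RK", "RecRK", sprintf("RKpre%d", 0:5),
                    sprintf("RKpost%d", 1:6))),
    buffer_total = w1(c("Ca_buff", "Bfree"))
  )
}

#' Backbone reaction set
#'
#' Assembles the non-novel backbone reactions listed in [base_cascade].
#' Photoactivation is represented by two time-gated reactions (free and
#' precoupled rhodopsin) whose rate coefficient and window are installed by
#' the stimulus machinery; they are inert (k = 0) in the dark network.
#'
#' @param params Parameter list from [default_params()].
#' @return List of [reaction()] objects.
#' @export
assemble_base_reactions <- function(params = default_params()) {
  p <- params
  need <- c("kpre1", "kpre2", "omega", "kG1_0", "kG2", "kG3", "kGrecyc",
            "kP1", "kP2", "kRGS1", "kRGS2", "kPDE_shutoff", "cG_dark",
            "beta_dark", "beta_sub", "n_channel", "Kc", "m_cyc", "Ca_dark",
            "Ca_min", "gamma_ex", "k_buf_on", "k_buf_off")
  miss <- need[!vapply(need, function(nm) !is.null(p[[nm]]), logical(1))]
  if (length(miss))
    stop("missing backbone constants: ", paste(miss, collapse = ", "), call. = FALSE)
  out <- list()
  add <- function(r) out[[length(out) + 1]] <<- r

  # photoactivation placeholders (flash + background window)
  add(reaction("Photo_R", 0, "R", c(R = -1, Rst0 = 1), law = "gated"))
  add(reaction("Photo_RGt", 0, "R_Gt", c(R_Gt = -1, RGt0 = 1), law = "gated"))
  add(reaction("Photo_R_bg", 0, "R", c(R = -1, Rst0 = 1), law = "gated"))
  add(reaction("Photo_RGt_bg", 0, "R_Gt", c(R_Gt = -1, RGt0 = 1), law = "gated"))

  # dark precoupling of rhodopsin and transducin
  add(mass_action("pre_bind", p$kpre1, c(R = 1, Gt = 1), c(R_Gt = 1), k_name = "kpre1"))
  add(mass_action("pre_unbind", p$kpre2, c(R_Gt = 1), c(R = 1, Gt = 1), k_name = "kpre2"))

  # transducin activation, indexed by phosphorylation state
  for (n in phospho_range) {
    kg1 <- p$kG1_0 * exp(-p$omega * n)
    add(mass_action(sprintf("G_bind_%d", n), kg1,
                    c(stats::setNames(1, sprintf("Rst%d", n)), Gt = 1),
                    stats::setNames(1, sprintf("RGt%d", n)), k_name = "kG1"))
    add(mass_action(sprintf("G_unbind_%d", n), p$kG2,
                    stats::setNames(1, sprintf("RGt%d", n)),
                    c(stats::setNames(1, sprintf("Rst%d", n)), Gt = 1),
                    k_name = "kG2"))
    add(mass_action(sprintf("G_exchange_%d", n), p$kG3,
                    stats::setNames(1, sprintf("RGt%d", n)),
                    c(stats::setNames(1, sprintf("Rst%d", n)),
                      Ga_GTP = 1, Gbg = 1), k_name = "kG3"))
  }
  add(mass_action("G_recycle", p$kGrecyc, c(Ga_GDP = 1, Gbg = 1), c(Gt = 1),
                  k_name = "kGrecyc"))

  # R* complexed with RK keeps activating transducin (the kinase docks at the
  # phosphorylated C-terminus, not the G-protein interface); represented as a
  # single catalytic exchange step at the phosphorylation-indexed rate times
  # the exchange yield kG3/(kG2 + kG3). Arr-capped R* is silent.
  p_exch <- p$kG3 / (p$kG2 + p$kG3)
  for (n in 0:5) {
    add(reaction(sprintf("G_cat_pre_%d", n),
                 p$kG1_0 * exp(-p$omega * n) * p_exch,
                 c(sprintf("RKpre%d", n), "Gt"),
                 c(Gt = -1, Ga_GTP = 1, Gbg = 1), k_name = "kG1"))
  }
  for (n in 1:6) {
    add(reaction(sprintf("G_cat_post_%d", n),
                 p$kG1_0 * exp(-p$omega * n) * p_exch,
                 c(sprintf("RKpost%d", n), "Gt"),
                 c(Gt = -1, Ga_GTP = 1, Gbg = 1), k_name = "kG1"))
  }

  # effector activation (two catalytic subunits) and shutdown
  add(mass_action("E_act1", p$kP1, c(PDE = 1, Ga_GTP = 1), c(PDE_Ga = 1),
                  k_name = "kP1"))
  add(mass_action("E_act2", p$kP2, c(PDE_Ga = 1, Ga_GTP = 1), c(Ga_PDE_Ga = 1),
                  k_name = "kP2"))
  add(mass_action("RGS_bind1", p$kRGS1, c(PDE_Ga = 1, RGS = 1),
                  c(RGS_PDE_Ga = 1), k_name = "kRGS1"))
  add(mass_action("RGS_hydrolyze1", p$kRGS2, c(RGS_PDE_Ga = 1),
                  c(PDE = 1, RGS = 1, Ga_GDP = 1), k_name = "kRGS2"))
  add(mass_action("RGS_bind2", p$kRGS1, c(Ga_PDE_Ga = 1, RGS = 1),
                  c(RGS_Ga_PDE_Ga = 1), k_name = "kRGS1"))
  add(mass_action("RGS_hydrolyze2", p$kRGS2, c(RGS_Ga_PDE_Ga = 1),
                  c(PDE_Ga = 1, RGS = 1, Ga_GDP = 1), k_name = "kRGS2"))
  add(mass_action("E_spont1", p$kPDE_shutoff, c(PDE_Ga = 1),
                  c(PDE = 1, Ga_GDP = 1), k_name = "kPDE_shutoff"))
  add(mass_action("E_spont2", p$kPDE_shutoff, c(Ga_PDE_Ga = 1),
                  c(PDE_Ga = 1, Ga_GDP = 1), k_name = "kPDE_shutoff"))

  # cGMP synthesis (Ca2+-inhibited, implicit GCAP) and hydrolysis
  alpha_max <- p$beta_dark * p$cG_dark * (1 + (p$Ca_dark / p$Kc)^p$m_cyc)
  add(reaction("cG_synthesis", alpha_max, "Ca", c(cGMP = 1),
               law = "hill_inhib", p1 = p$Kc, p2 = p$m_cyc, k_name = "alpha_max"))
  add(mass_action("cG_dark_hydrolysis", p$beta_dark, c(cGMP = 1), k_name = "beta_dark"))
  act <- c(PDE_Ga = 1, Ga_PDE_Ga = 2, RGS_PDE_Ga = 1, RGS_Ga_PDE_Ga = 2)
  for (sp in names(act)) {
    add(reaction(sprintf("cG_hydrolysis_%s", sp), p$beta_sub * act[[sp]],
                 c(sp, "cGMP"), c(cGMP = -1), k_name = "beta_sub"))
  }

  # Ca2+ influx (channel-gated), extrusion and buffering
  j_in <- p$gamma_ex * (p$Ca_dark - p$Ca_min) / p$cG_dark^p$n_channel
  add(reaction("Ca_influx", j_in, "cGMP", c(Ca = 1),
               law = "power", p1 = p$n_channel, k_name = "gamma_ex"))
  add(mass_action("Ca_extrusion", p$gamma_ex, c(Ca = 1), k_name = "gamma_ex"))
  add(reaction("Ca_exchanger_floor", p$gamma_ex * p$Ca_min, character(),
               c(Ca = 1), law = "constant", k_name = "gamma_ex"))
  add(mass_action("Ca_buffer_on", p$k_buf_on, c(Ca = 1, Bfree = 1),
                  c(Ca_buff = 1), k_name = "k_buf_on"))
  add(mass_action("Ca_buffer_off", p$k_buf_off, c(Ca_buff = 1),
                  c(Ca = 1, Bfree = 1), k_name = "k_buf_off"))
  out
}

solve_dark_recrk <- function(p) {
  r <- p$kRec1 * p$Ca_dark / p$kRec2         # RecR_Ca / RecT at dark Ca
  K2 <- p$kRec3 / p$kRec4                    # RecRK / (RecR_Ca * RK)
  if (p$Rec_total == 0)
    return(list(RecT = 0, RecR_Ca = 0, RecRK = 0, RK = p$RK_total))
  if (p$RK_total == 0)
    return(list(RecT = p$Rec_total / (1 + r), RecR_Ca = p$Rec_total * r / (1 + r),
                RecRK = 0, RK = 0))
  f <- function(u) {
    recrk <- p$RK_total - u
    recr <- recrk / (K2 * u)
    recr * (1 + 1 / r) + recrk - p$Rec_total
  }
  u <- stats::uniroot(f, c(p$RK_total * 1e-12, p$RK_total * (1 - 1e-12)),
                      tol = 1e-12 * p$RK_total)$root
  recrk <- p$RK_total - u
  recr <- recrk / (K2 * u)
  list(RecT = recr / r, RecR_Ca = recr, RecRK = recrk, RK = u)
}

#' Analytic dark steady state
#'
#' Computes the dark fixed point module by module: rhodopsin-transducin
#' precoupling (quadratic), the coupled Rec/RK equilibrium at dark Ca2+
#' (one-dimensional root), the arrestin oligomer equilibrium, the Ca2+ buffer
#' equilibrium and the cGMP synthesis/hydrolysis balance. All cascade
#' intermediates are zero in darkness.
#'
#' @param params Parameter list (with `eT_adj` already present or derivable).
#' @param oligomerization_off If TRUE all arrestin is placed in the monomer
#'   pool (paired with `kA4 = 0`).
#' @return Named dark state vector over [rod_species_names()].
#' @keywords internal
dark_state <- function(params, oligomerization_off = FALSE) {
  p <- params
  y <- stats::setNames(numeric(length(rod_species_names())), rod_species_names())
  # precoupling: Kp (Rtot - x)(Gtot - x) = x
  Kp <- p$kpre1 / p$kpre2
  if (Kp > 0 && p$R_total > 0 && p$Gt_total > 0) {
    a <- Kp
    b <- -(Kp * (p$R_total + p$Gt_total) + 1)
    cc <- Kp * p$R_total * p$Gt_total
    x <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  } else x <- 0
  y["R_Gt"] <- x
  y["R"] <- p$R_total - x
  y["Gt"] <- p$Gt_total - x
  y["PDE"] <- p$PDE_total
  y["RGS"] <- p$RGS_total
  rec <- solve_dark_recrk(p)
  y["RecT"] <- rec$RecT; y["RecR_Ca"] <- rec$RecR_Ca
  y["RecRK"] <- rec$RecRK; y["RK"] <- rec$RK
  if (oligomerization_off) {
    y["Arr"] <- p$Arr_total
  } else {
    y[c("Arr", "Arr_di", "Arr_tetra")] <-
      arr_equilibrium_pools(p$Arr_total, p$kA4, p$kA5)
  }
  y["cGMP"] <- p$cG_dark
  y["Ca"] <- p$Ca_dark
  KDb <- p$k_buf_off / p$k_buf_on
  y["Ca_buff"] <- p$eT_adj * p$Ca_dark / (KDb + p$Ca_dark)
  y["Bfree"] <- p$eT_adj - y["Ca_buff"]
  y
}

#' Build the full rod phototransduction model
#'
#' Composes the backbone with the receptor-shutdown, recoverin-feedback and
#' arrestin-oligomerization modules, computes the analytic dark steady state
#' and returns the executable network. The dark state is the network's initial
#' state, so with no stimulus the model sits at a fixed point.
#'
#' @param params Parameter list from [default_params()].
#' @param oligomerization_off Disable arrestin self-association (`kA4 = 0`)
#'   and start with an all-monomer dark arrestin pool.
#' @param omega_Arr Exponent of the optional Ca2+-dependent self-association
#'   variant (0 = off, the default).
#' @return A `rod_network` whose species table holds the dark state.
#' @export
build_rod_model <- function(params = default_params(),
                            oligomerization_off = FALSE,
                            omega_Arr = params$omega_Arr %||% 0) {
  p <- params
  if (is.null(p$eT_adj))
    p$eT_adj <- adjust_buffer_capacity(
      p$eT_prev, p$Rec_total / (MOLEC_PER_UM * p$volume_pl))
  if (oligomerization_off) p$kA4 <- 0
  reactions <- c(assemble_base_reactions(p),
                 receptor_reactions(p),
                 rec_reactions(p),
                 oligomer_reactions(p$kA4, p$kA5))
  if (omega_Arr != 0) {
    # replace the two forward oligomerization steps with the Ca2+-modulated law
    for (i in seq_along(reactions)) {
      r <- reactions[[i]]
      if (r$name %in% c("Arr_dimerize", "Arr_tetramerize")) {
        reactions[[i]] <- reaction(r$name, r$k, c(r$rate_species, "Ca"),
                                   r$changes, law = "mass_exp",
                                   p1 = omega_Arr, p2 = p$Ca_dark,
                                   k_name = r$k_name)
      }
    }
  }
  y0 <- dark_state(p, oligomerization_off = oligomerization_off)
  species <- tibble::tibble(
    name = rod_species_names(),
    initial = unname(y0),
    unit = ifelse(rod_species_names() %in%
                    c("cGMP", "Ca", "Ca_buff", "Bfree"), "uM", "count"))
  net <- rod_network(species, reactions, params = p, volume_pl = p$volume_pl,
                     conservation = rod_conservation())
  net$oligomerization_off <- oligomerization_off
  net
}

#' Normalized photocurrent suppression
#'
#' The fractional suppression of the circulating dark current,
#' `deltaJ/J_dark = 1 - (cGMP / cGMP_dark)^n_channel`: 0 at the dark state and
#' 1 at full channel closure.
#'
#' @param state Named state vector or trajectory tibble containing `cGMP`.
#' @param params Parameter list of the network that produced the state.
#' @return Numeric suppression value(s).
#' @export
photocurrent <- function(state, params = default_params()) {
  cg <- if (is.data.frame(state)) state$cGMP else state[["cGMP"]]
  1 - (pmax(cg, 0) / params$cG_dark)^params$n_channel
}

`%||%` <- function(a, b) if (is.null(a)) b else a
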