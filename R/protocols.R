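#' Stimulus protocols and the in-silico mutant engine
#'
#' Stimuli are described as photoisomerization (R*) production: brief flashes
#' (default 24 ms) delivering a stated number of R* per flash, 60-s steps
#' delivering R* per second, or a flash on top of a steady adapting
#' background. A protocol is converted at run time to a first-order
#' photoactivation coefficient applied to the dark rhodopsin pools (free and
#' transducin-precoupled alike) inside the stimulus window.
#'
#' @name protocols
NULL

#' Describe a stimulus protocol
#'
#' @param kind `"flash"`, `"step"`, or `"background_flash"`.
#' @param strength R* per flash (flash kinds) or R* per second (step).
#' @param flash_duration Flash width in seconds (default 0.024).
#' @param step_duration Step width in seconds (default 60).
#' @param onset Stimulus onset in seconds (default 1 so traces begin at rest).
#' @param background Background intensity in R* per second
#'   (`background_flash` only; the background runs from t = 0 to the horizon,
#'   with the flash delivered at `onset` after the cell has adapted).
#' @return A `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(kind = c("flash", "step", "background_flash"),
                              strength, flash_duration = 0.024,
                              step_duration = 60, onset = 1, background = 0) {
  kind <- match.arg(kind)
  stopifnot(strength >= 0, background >= 0, flash_duration > 0, step_duration > 0,
            onset >= 0)
  structure(list(kind = kind, strength = strength,
                 flash_duration = flash_duration,
                 step_duration = step_duration, onset = onset,
                 background = background),
            class = "stimulus_protocol")
}

#' Convert photon flux density to photoisomerizations per flash
#'
#' `photons x collecting area x species factor`. The species factor is 2 for
#' protocols adapted from mouse experiments (to account for the sensitivity
#' difference between the amphibian-parameterized model and mouse rods) and 1
#' otherwise.
#'
#' @param photons_per_um2 Photon flux density (photons per um^2 per flash).
#' @param collecting_area Effective collecting area in um^2 (default 0.4).
#' @param species_factor Species intensity factor (default 1; use 2 for
#'   mouse-derived protocols).
#' @return R* per flash.
#' @export
photons_to_isomerizations <- function(photons_per_um2, collecting_area = 0.4,
                                      species_factor = 1) {
  stopifnot(photons_per_um2 >= 0, collecting_area >= 0, species_factor >= 0)
  photons_per_um2 * collecting_area * species_factor
}

#' Describe an in-silico mutant
#'
#' @param ... Named fold-expression factors for protein totals, e.g.
#'   `RK = 2.4`, `RGS = 0.2`, `Arr = 0.5`, `Rec = 0`. Recognized names:
#'   `RK`, `RGS`, `Arr`, `Rec`, `Gt`, `PDE`, `R`. A factor of 0 is a
#'   knockout; 1 is wild type.
#' @param oligomerization_off Disable arrestin self-association (`kA4 = 0`
#'   with an all-monomer dark arrestin pool).
#' @param omega_Arr Exponent of the Ca2+-dependent self-association variant
#'   (default 0 = off).
#' @return A `mutant_spec` list.
#' @export
mutant_spec <- function(..., oligomerization_off = FALSE, omega_Arr = 0) {
  factors <- c(...)
  if (length(factors)) {
    known <- c("RK", "RGS", "Arr", "Rec", "Gt", "PDE", "R")
    bad <- setdiff(names(factors), known)
    if (length(bad))
      stop("unknown protein name(s) in mutant spec: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(factors < 0)) stop("expression factors must be >= 0", call. = FALSE)
  }
  structure(list(factors = factors, oligomerization_off = oligomerization_off,
                 omega_Arr = omega_Arr),
            class = "mutant_spec")
}

#' Apply a mutant specification to the model
#'
#' Scales each named protein's total pool, applies mechanism switches, and
#' re-solves the dark steady state before any stimulus, so all dark pools of a
#' scaled protein change proportionally through the equilibria rather than
#' being scaled independently. The anonymous-buffer adjustment for explicit
#' recoverin buffering is kept at its wild-type value (the mutant machinery
#' scales protein totals only).
#'
#' @param network A `rod_network` from [build_rod_model()] (used for its
#'   parameter set), or a parameter list.
#' @param spec A [mutant_spec()].
#' @return A re-equilibrated `rod_network`.
#' @export
apply_mutant <- function(network, spec) {
  p <- if (inherits(network, "rod_network")) network$params else network
  if (is.null(p$eT_adj))
    p$eT_adj <- adjust_buffer_capacity(
      p$eT_prev, p$Rec_total / (MOLEC_PER_UM * p$volume_pl))
  map <- c(RK = "RK_total", RGS = "RGS_total", Arr = "Arr_total",
           Rec = "Rec_total", Gt = "Gt_total", PDE = "PDE_total", R = "R_total")
  for (nm in names(spec$factors)) {
    p[[map[[nm]]]] <- p[[map[[nm]]]] * spec$factors[[nm]]
  }
  build_rod_model(p, oligomerization_off = isTRUE(spec$oligomerization_off),
                  omega_Arr = spec$omega_Arr %||% 0)
}

stimulus_windows <- function(protocol, rho_pool) {
  # returns list(flash = c(k, on, off), background = c(k, on, off))
  pr <- protocol
  fl <- c(0, 0, 0); bg <- c(0, 0, 0)
  if (pr$kind == "flash") {
    fl <- c(pr$strength / pr$flash_duration / rho_pool,
            pr$onset, pr$onset + pr$flash_duration)
  } else if (pr$kind == "step") {
    fl <- c(pr$strength / rho_pool, pr$onset, pr$onset + pr$step_duration)
  } else {
    fl <- c(pr$strength / pr$flash_duration / rho_pool,
            pr$onset, pr$onset + pr$flash_duration)
    bg <- c(pr$background / rho_pool, 0, Inf)
  }
  list(flash = fl, background = bg)
}

with_stimulus <- function(network, protocol) {
  y0 <- initial_state(network)
  rho_pool <- y0[["R"]] + y0[["R_Gt"]]
  w <- stimulus_windows(protocol, rho_pool)
  for (i in seq_along(network$reactions)) {
    r <- network$reactions[[i]]
    v <- switch(r$name, Photo_R = , Photo_RGt = w$flash,
                Photo_R_bg = , Photo_RGt_bg = w$background, NULL)
    if (!is.null(v)) {
      r$k <- v[1]; r$p1 <- v[2]; r$p2 <- min(v[3], 1e9)
      network$reactions[[i]] <- r
    }
  }
  network
}

#' Run a stimulus protocol
#'
#' Integrates the dark-equilibrated network under the given stimulus and
#' returns a response trace: the normalized photocurrent suppression
#' `deltaJ` on a 1-ms grid, together with `Ca_uM`, `cGMP_uM` and (optionally)
#' the full species trajectories. For saturating stimuli the horizon is
#' extended automatically until the response has recovered below 10%
#' suppression.
#'
#' @param network A dark-equilibrated `rod_network`.
#' @param protocol A [stimulus_protocol()].
#' @param horizon Simulation end time in seconds (default 60 for flashes,
#'   90 for steps).
#' @param keep_species Keep all species columns in the result (default TRUE).
#' @param dt Output grid spacing in seconds (default 1 ms).
#' @param auto_extend Extend the horizon (up to `max_horizon`) until
#'   `deltaJ` has fallen below 0.1 after the stimulus.
#' @param max_horizon Hard cap for automatic extension (s).
#' @param ... Passed to [integrate_network()].
#' @return A `response_trace` tibble with columns `time`, `deltaJ`, `Ca_uM`,
#'   `cGMP_uM`, then species counts.
#' @export
run_protocol <- function(network, protocol,
                         horizon = if (protocol$kind == "flash") 60 else 90,
                         keep_species = TRUE, dt = 1e-3,
                         auto_extend = TRUE, max_horizon = 600, ...) {
  stim_end <- if (protocol$kind == "step")
    protocol$onset + protocol$step_duration
  else protocol$onset + protocol$flash_duration
  if (horizon <= stim_end)
    stop("horizon (", horizon, " s) must exceed the stimulus end (",
         stim_end, " s)", call. = FALSE)
  net <- with_stimulus(network, protocol)
  # the stimulus gates are step discontinuities: restart the solver there
  y00 <- initial_state(net)
  rho_pool <- y00[["R"]] + y00[["R_Gt"]]
  w <- stimulus_windows(protocol, rho_pool)
  repeat {
    cuts <- c(w$flash[2:3], w$background[2:3])
    cuts <- sort(unique(pmin(pmax(cuts[is.finite(cuts)], 0), horizon)))
    bounds <- unique(c(0, cuts[cuts > 0 & cuts < horizon], horizon))
    segs <- vector("list", length(bounds) - 1)
    y <- y00
    for (i in seq_len(length(bounds) - 1)) {
      tg <- unique(c(seq(bounds[i], bounds[i + 1], by = dt), bounds[i + 1]))
      seg <- integrate_network(net, y, t_grid = tg, ...)
      # solver guarantees states >= -atol; clamp the hand-off to non-negative
      y <- pmax(unlist(seg[nrow(seg), -1]), 0)
      segs[[i]] <- if (i > 1) seg[-1, ] else seg
    }
    traj <- dplyr::bind_rows(segs)
    dj <- photocurrent(traj, network$params)
    if (!auto_extend || horizon >= max_horizon ||
        min(dj[traj$time > stim_end]) < 0.1 || utils::tail(dj, 1) < 0.1)
      break
    horizon <- min(horizon * 2, max_horizon)
  }
  out <- tibble::tibble(time = traj$time, deltaJ = dj,
                        Ca_uM = traj$Ca, cGMP_uM = traj$cGMP)
  if (keep_species) out <- dplyr::bind_cols(out, traj[setdiff(names(traj), "time")])
  attr(out, "protocol") <- protocol
  attr(out, "params") <- network$params
  class(out) <- c("response_trace", class(out))
  out
}

#' Catalog of simulated-experiment recipes
#'
#' Named bundles of stimulus families and mutant specifications covering the
#' simulated experiments: flash/step validation families, RK and RGS dosage
#' series, recoverin knockout/overexpression, arrestin under/overexpression,
#' the saturating-flash molecular-class run, the light-adaptation and
#' RGS-knockout checks, and the dominant-time-constant genotype sweep.
#'
#' @return Named list; each element holds `mutant` (a [mutant_spec()]),
#'   `protocols` (list of [stimulus_protocol()]) and a `note`.
#' @export
recipe_catalog <- function() {
  flashes <- function(strengths)
    lapply(strengths, function(s) stimulus_protocol("flash", s))
  steps <- function(strengths)
    lapply(strengths, function(s) stimulus_protocol("step", s))
  wt <- mutant_spec()
  out <- list(
    flash_family = list(
      mutant = wt,
      protocols = flashes(c(1.5, 15, 150, 1500, 15000, 118000)),
      note = "dark-adapted flash responses over five orders of magnitude"),
    step_family = list(
      mutant = wt, protocols = steps(c(48, 220, 450)),
      note = "60-s steps of light"),
    rk_ox_2.4x = list(
      mutant = mutant_spec(RK = 2.4),
      protocols = flashes(pepperberg_strengths()),
      note = "2.4x RK overexpression, saturating-flash ladder"),
    rgs_ox_2.3x = list(
      mutant = mutant_spec(RGS = 2.3),
      protocols = flashes(pepperberg_strengths()),
      note = "2.3x RGS overexpression (caption label; 2x appears in the sweep)"),
    rk_dosage_nonsat = list(
      mutant = wt,
      protocols = flashes(135),
      note = "non-saturating 135 R* flash for tau_rec vs RK dosage (0.3x / WT / 3x)"),
    rec_ko_family = list(
      mutant = mutant_spec(Rec = 0),
      protocols = flashes(c(10.24, 17.92, 37.2, 65.12, 120.8, 438.4, 768,
                            1472, 2584, 5360, 9360)),
      note = "recoverin knockout flash family"),
    wt_rec_family = list(
      mutant = wt,
      protocols = flashes(c(9.44, 16.48, 34.24, 59.92, 111.2, 194.4, 403.2,
                            705.6, 1352)),
      note = "wild-type companion family to the recoverin knockout"),
    rk_ux_0.4x = list(
      mutant = mutant_spec(RK = 0.4),
      protocols = flashes(c(3.2, 13.6, 34.4, 127.2, 362.4, 690.4, 1496.8)),
      note = "0.4x RK underexpression flash family"),
    wt_rk_family = list(
      mutant = wt,
      protocols = flashes(c(3.2, 13.6, 34.4, 127.2, 362.4, 896)),
      note = "wild-type companion family to the RK/RGS dosage runs"),
    rgs_ox_6x = list(
      mutant = mutant_spec(RGS = 6),
      protocols = flashes(c(13.6, 34.4, 127.2, 362.4, 516.8, 694.4, 896, 1496.8)),
      note = "6x RGS overexpression flash family"),
    rk_ux_rgs_ox_double = list(
      mutant = mutant_spec(RK = 0.4, RGS = 6),
      protocols = flashes(c(3.2, 13.6, 34.4, 127.2, 362.4, 896)),
      note = "0.4x RK / 6x RGS double mutant"),
    rec_ox_4x = list(
      mutant = mutant_spec(Rec = 4),
      protocols = flashes(c(3, 6, 15, 29, 70, 157, 317, 570)),
      note = "4x recoverin overexpression (dialysis-excess analogue)"),
    rgs_ux_rk_ox_double = list(
      mutant = mutant_spec(RGS = 0.2, RK = 3),
      protocols = flashes(pepperberg_strengths()),
      note = "hypothetical 0.2x RGS / 3x RK double mutant"),
    arr_ux_0.5x = list(
      mutant = mutant_spec(Arr = 0.5),
      protocols = flashes(c(4.8, 19.2, 76.8, 307.2, 1228.8, 4915.2)),
      note = "0.5x arrestin underexpression"),
    arr_ox_2x = list(
      mutant = mutant_spec(Arr = 2),
      protocols = flashes(c(4.8, 19.2, 76.8, 307.2, 1228.8, 4915.2)),
      note = "hypothetical 2x arrestin overexpression"),
    wt_arr_family = list(
      mutant = wt,
      protocols = flashes(c(4.8, 19.2, 76.8, 307.2, 1228.8, 4915.2)),
      note = "wild-type companion family to the arrestin dosage runs"),
    class_tracking_sat = list(
      mutant = wt,
      protocols = flashes(118000),
      note = "saturating 118,000 R* flash with molecular-class tracking"),
    class_tracking_sat_oligo_off = list(
      mutant = mutant_spec(oligomerization_off = TRUE),
      protocols = flashes(118000),
      note = "saturating flash with arrestin oligomerization disabled"),
    light_adaptation = list(
      mutant = wt,
      protocols = list(stimulus_protocol("background_flash", 118000,
                                         background = 48, onset = 30)),
      note = "saturating flash on a non-saturating adapting background"),
    rgs_ko = list(
      mutant = mutant_spec(RGS = 0),
      protocols = flashes(c(150, 1500, 15000)),
      note = "RGS knockout: severely prolonged recovery"),
    table1_sweep = list(
      mutant = wt,
      protocols = flashes(pepperberg_strengths()),
      note = "genotype sweep for normalized tau_D",
      genotypes = table1_genotypes())
  )
  out
}

#' Standardized half-log Pepperberg flash ladder
#'
#' The same half-log-decade ladder is used for every dominant-time-constant
#' measurement, regardless of the stimuli of the original experiments.
#'
#' @param from,to log10 range of flash strengths (R* per flash).
#' @return Numeric vector of flash strengths.
#' @export
pepperberg_strengths <- function(from = 2.5, to = 6) {
  10^seq(from, to, by = 0.5)
}

#' Genotypes of the dominant-time-constant sweep
#'
#' @return Named list of [mutant_spec()] objects, in printed-table order.
#' @export
table1_genotypes <- function() {
  list(
    "WT" = mutant_spec(),
    "0.3x RK UX" = mutant_spec(RK = 0.3),
    "0.4x RK UX" = mutant_spec(RK = 0.4),
    "2x RK OX" = mutant_spec(RK = 2),
    "3x RK OX" = mutant_spec(RK = 3),
    "Rec KO" = mutant_spec(Rec = 0),
    "4x Rec OX" = mutant_spec(Rec = 4),
    "0.2x RGS UX" = mutant_spec(RGS = 0.2),
    "2x RGS OX" = mutant_spec(RGS = 2),
    "4x RGS OX" = mutant_spec(RGS = 4),
    "6x RGS OX" = mutant_spec(RGS = 6),
    "0.4x RK/6x RGS" = mutant_spec(RK = 0.4, RGS = 6),
    "3x RK/0.2x RGS" = mutant_spec(RK = 3, RGS = 0.2)
  )
}
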